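---
title: "Graph-theoretic analysis of tractography connectomes with tractgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of tractography connectomes with tractgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractgraph)
```

## The analysis problem

Probabilistic tractography turns diffusion-weighted MRI into, per subject
and hemisphere, a directed matrix of streamline counts between regions of
interest (ROIs): entry $(i, j)$ is the number of sampled trajectories
seeded in ROI $i$ that reached ROI $j$. `tractgraph` implements the graph
workflow that turns a cohort of such matrices into interpretable
statements about parieto-premotor connectivity: which thresholded group
networks are trustworthy, which connections are strongest, which nodes act
as hubs, and which connections differ between hemispheres.

The package works with a 37-ROI configuration per hemisphere (23 parietal,
14 premotor/prefrontal), so the analyzed parieto-premotor edge set has
$23 \times 14 = 322$ pairs. Any other ROI table with `parietal`/`premotor`
lobe labels works the same way.

## From counts to a weighted-undirected group graph

1. **Waytotal normalization.** Each row $i$ of a count matrix is divided by
   that seed's *waytotal* (the total number of streamlines generated from
   seed $i$), giving connection probabilities $P_{ij} \in [0, 1]$. Waytotals
   come from a sidecar table or a configured constant; entries that exceed
   their waytotal are reported with a warning rather than silently clipped,
   because they indicate a data error upstream.
2. **Directional averaging.** Diffusion cannot distinguish afferent from
   efferent paths, so the two directed weights of each pair are averaged:
   $P_{ij} \leftarrow (P_{i \to j} + P_{j \to i})/2$. The graph is then
   weighted-undirected with a zero diagonal.
3. **Group aggregation.** The default group edge weight is the edgewise
   mean across subjects, the field-standard consensus matrix. The variant
   `mean_plus_2sd` (mean plus two sample standard deviations) is also
   provided: group matrices are occasionally summarized by that expression,
   but it is ambiguous whether it denotes the group weight itself or an
   inclusion cutoff, so the package implements both and defaults to the
   mean. Sample SD (divisor $n-1$) is used everywhere an SD appears,
   because subjects are a sample.

Masked (intralobar) pairs are represented as *absent* edges, never as
zero-weight edges: a zero-weight edge would corrupt the reciprocal length
transform and the density computation.

## Threshold sweep and graph admission

Weak probabilistic weights are plausible false positives, so the group
graph is swept over proportional thresholds, by default $t = 0.01$ to
$0.1$ in steps of $0.0025$ — 37 thresholded graphs per hemisphere. An edge
survives when its weight is $\geq t$; the boundary is included because the
sweep's purpose is "removing weights below a cutoff", and an explicit rule
beats an undocumented one.

Each thresholded graph must pass three goodness criteria before any
downstream statistic is computed on it:

* **Connectedness** — every node reachable from every other. A node
  isolated by thresholding fails the criterion; it is not silently
  dropped.
* **Modularity** — the maximized Newman modularity
  $Q = \frac{1}{2W}\sum_{ij}\left(w_{ij} - \frac{s_i s_j}{2W}\right)
  \delta(m_i, m_j)$
  must exceed 0.3, ensuring the graph divides into meaningful modules.
* **Small-worldness** — $S = (C/C_{rand})\,/\,(L/L_{rand}) > 1$, where $C$
  is the mean Watts–Strogatz clustering coefficient, $L$ the
  characteristic path length, and the null terms are means over
  degree-preserving rewired networks.

Three choices here were genuinely open and are worth recording:

* **Which graph the criteria see.** The parieto-premotor restriction
  defines the *analysis* edge set (distance ranking, lateralization
  tests), but the admission criteria and node metrics are computed on the
  full 37-node graph including intralobe edges. A strictly bipartite
  parietal×premotor graph contains no triangles, so its clustering
  coefficient is identically zero and small-worldness is degenerate; the
  admission screen is only meaningful on the unrestricted topology, while
  the 322-pair restriction is exactly the right population for the
  edge-level statistics.
* **Binary versus weighted $C$ and $L$.** The admission criteria use the
  binary (hop-count) forms, which is what the classical definitions of
  $C_i = 2t_i/(k_i(k_i-1))$ and small-worldness assume. Modularity and
  the node centralities use weights, since discarding weights there wastes
  exactly the information tractography provides. A binary option is kept
  for every weighted metric.
* **The null model.** "Random networks" is underspecified; the package
  uses Maslov–Sneppen degree-preserving rewiring (10 × edge-count swap
  attempts per null, 100 nulls by default, connected rewirings only, fully
  seeded), the standard null for small-worldness. A rewiring that cannot
  produce a connected null within a bounded number of retries raises an
  error rather than biasing $L_{rand}$.

### Modularity maximization

Maximization follows Newman's spectral method: recursive bisection by the
sign pattern of the leading eigenvector of the (group-restricted)
modularity matrix, each split polished by Kernighan–Lin node flips and
accepted only when it increases $Q$. Weights enter through strengths
$s_i$ and the total weight $2W$. After recursion, a generalized
Kernighan–Lin refinement runs over the whole partition — chained
single-node moves to any module (including a fresh singleton), interim
losses allowed, best state kept, plus pairwise module merges — from three
starts (spectral result, one module, all singletons). Ties break to the
lowest node index, which makes results deterministic; on graphs small
enough to enumerate (n ≤ 8), the refined result matches exhaustive
partition enumeration exactly (verified over hundreds of random graphs in
the test suite).

## Distance ranking

On the selected analysis graph — the admitted graph of highest edge
density, ties to the lowest threshold — weights become lengths by the
reciprocal transform $\ell = 1/w$ (absent edges infinite), and Dijkstra's
algorithm yields the all-pairs distance matrix. Short distances mean
strong connectivity. The 322 parieto-premotor distances of a hemisphere
are ranked against their own percentiles: a pair is classed `p15`, `p25`,
`p50`, or `p75` when its distance falls *strictly below* that percentile
(computed with linear interpolation between order statistics), tightest
class first, so the classes are nested. Infinite distances never enter
the percentile population.

## Two-stage node characterization

Stage 1 decides hub status across the admitted threshold range, each
thresholded graph using its own modularity affiliation (a consensus
partition would blur exactly the threshold dependence the two-endpoint
rule is designed to probe):

* **connector hub** — participation coefficient
  $y_i = 1 - \sum_{m}(k_i(m)/k_i)^2$ above the third quartile of its graph
  at **both** the lowest and the highest admitted threshold;
* **provincial hub** — within-module degree z-score
  $z_i = (k_i(m_i) - \bar k(m_i))/\sigma^k(m_i)$ above the third quartile
  at both endpoints;
* **nonhub** — everything else.

Requiring both endpoints (rather than either one) is the reading
consistent with excluding nodes that clear the cutoff "only in occasional
threshold graphs". A node passing both rules is assigned connector — the
two criteria are not mutually exclusive, no precedence is standard, and
the dual qualification is reported so nothing is hidden.

Stage 2 subtypes the hubs on the analysis graph by strength
$s_i = \sum_j w_{ij}$ and betweenness
$b_i = \frac{1}{(n-1)(n-2)}\sum_{h \neq j \neq i} \rho_{hj}(i)/\rho_{hj}$
(Brandes' algorithm on the length matrix; endpoints of a path do not count
as on it): above the network median in both → `rich_central`; strength
only → `rich`; betweenness only → `poor_central`; neither → `poor`.
Nonhubs with *both* strength and betweenness strictly below the first
quartile are `peripheral`; remaining nonhubs stay `unclassified`.
Quartiles are type-7 (linear interpolation), strict `>` for "up" and `≤`
for "down", matching the up/down-arrow semantics of the taxonomy.

A consequence of the strict quartile rule worth knowing: weighted
betweenness concentrates on few nodes in small dense networks, and when a
quarter or more of the nodes sit at exactly zero, the first quartile is
zero and *no* node can be strictly below it — the peripheral set is then
empty. That is the rule behaving as written, not a numerical accident; the
synthetic default cohort (below) is in this regime, so its planted
low-connectivity nodes are reported with recall 0 by the recovery report
even though their strengths are the lowest in the network.

## Hemispheric lateralization statistics

Every interlobar pair is tested with a two-sided paired-sample *t* test on
the left-minus-right subject differences of the normalized, averaged
weights (pairs absent in a subject are observed zeros, not missing data —
a probabilistic count of zero is an observation). The 322 p values are
adjusted by Benjamini–Hochberg step-up FDR; significance means adjusted
$p \leq \alpha$ (default 0.05). Degenerate edges cannot crash the
pipeline: all-zero differences give $t = 0, p = 1$; nonzero constant
differences give the smallest representable p with a `degenerate` flag.

Between-subject variability is summarized per edge and hemisphere by the
coefficient of variation (sample SD / mean; undefined and flagged when
the mean is zero) and clustered by CV quartiles: A below Q1, B below the
median, C below Q3, D the rest. The CV is the clustered quantity
throughout (the alternative reading, clustering raw SD matrices by CV
quartiles, is self-contradictory).

## The synthetic cohort generator

No public cohort ships with the package, so every claim is validated on
synthetic cohorts with planted ground truth. `synthetic_spec()` defaults
encode the study conditions the pipeline targets: 40 subjects × 2
hemispheres × 37 ROIs; four planted modules spanning both lobes
(within-module expected weight 0.05, between-module 0.005 — a 10:1
contrast); one planted connector hub (cross-module edges ×3) and one
provincial hub (within-module edges ×3) per module; two planted
low-connectivity nodes (all incident expectations ×0.25); twenty planted
lateralized interlobar edges with left/right expectation ratio
$\delta = 2$; multiplicative subject noise, lognormal with sdlog 0.2 and
unit mean.

Directed counts are drawn independently per direction as
$\mathrm{Poisson}(\text{waytotal} \times E_{ij} \times \eta)$, with
$\eta$ the lognormal subject factor — streamline counts are nonnegative
integers with multiplicative between-subject variability, which is the
simplest generative model consistent with both facts. The expectation
$E$ additionally carries per-edge lognormal heterogeneity (`weight_jitter`,
sdlog 0.4, drawn once from the spec seed, symmetric, shared across
subjects and hemispheres): real streamline weights are heavy-tailed
rather than block-constant, and without heterogeneity shortest paths
degenerate onto the hub edges. The default waytotal is $10^5$ expected
streamlines per seed, a realistic budget for a multi-voxel seed at
typical per-voxel sampling rates. Intralobe blocks are generated too, so
interlobar masking is exercised rather than assumed. A `deterministic`
mode replaces the Poisson draw by the rounded expectation for exact
ground-truth checks, and the whole cohort is bit-reproducible from the
spec seed.

What the generator does *not* emulate: spatially structured tractography
biases (gyral bias, distance decay along white matter geometry),
correlated noise between neighboring edges, and realistic degree
distributions of whole-brain connectomes. Passing recovery tests
therefore demonstrates that the pipeline's inference machinery is correct
and calibrated under a known generative model — not that any particular
anatomical claim about real data is true.

## Problem sizes and numerical choices in the test suite

The test suite validates each operation against an independent oracle:
exhaustive partition enumeration for modularity (n ≤ 8), Floyd–Warshall
for Dijkstra (n ≤ 20), exhaustive path enumeration for betweenness
(n ≤ 10), the literal step-up definition for BH-FDR, union-find for
connectedness, and triangle counting for clustering. Cohort-level checks
use 8–40 subjects and 10–100 null networks per threshold; the type-I
calibration check runs 50 cohorts of 40 subjects under $\delta = 1$ and
verifies the raw rejection rate lies within three binomial standard
errors of $\alpha$; hub-recovery pools 20 cohorts of 8 subjects. These
sizes were chosen so each property is measured with enough replication to
be meaningful while the whole suite stays comfortably interactive.

Floating-point tie-breaks are fixed throughout: quantiles are type 7,
strict comparisons follow the taxonomy's wording, thresholds include the
boundary, and every stochastic component (cohort generation, null
rewiring) is seeded explicitly, so identical configurations yield
byte-identical outputs.

## Known limitations

* Admission treats thresholds independently; no smoothing across the
  sweep is attempted.
* The peripheral rule is vacuous when betweenness has a large atom at
  zero (see above); reporting it honestly was preferred over quietly
  switching to a non-strict comparison.
* The modularity maximizer is exact only where enumeration can verify it;
  on larger graphs it is a well-refined heuristic, as all modularity
  maximizers are.
* Replication against the originally deposited matrices requires
  downloading them separately; the package reads plain CSV/TSV matrices
  and makes no attempt to fetch remote data.
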