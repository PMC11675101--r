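#' Aggregate subject connectomes into a group graph
#'
#' Edgewise aggregation across subjects, either the plain mean (default,
#' the field-standard group consensus) or mean plus two sample standard
#' deviations (`"mean_plus_2sd"`), offered because group matrices are
#' sometimes summarized that way before thresholding.
#'
#' @param subjects List of `"normalized_connectome"` objects with identical
#'   ROI sets and masks.
#' @param method `"mean"` or `"mean_plus_2sd"` (sample SD, divisor n-1).
#' @return Object of class `"group_graph"` holding the symmetric aggregated
#'   weight matrix `W`, the common retention mask, the ROI set, and the
#'   aggregation tag.
#' @export
aggregate_group <- function(subjects, method = c("mean", "mean_plus_2sd")) {
  method <- match.arg(method)
  stopifnot(length(subjects) >= 1)
  ref <- subjects[[1]]
  stopifnot(inherits(ref, "normalized_connectome"))
  for (s in subjects[-1]) {
    if (!identical(dimnames(s$weights), dimnames(ref$weights)) ||
        !identical(s$mask, ref$mask)) {
      stop("subjects have mismatched ROI sets or masks")
    }
  }
  arr <- vapply(subjects, function(s) s$weights,
                matrix(0, nrow(ref$weights), ncol(ref$weights)))
  W <- apply(arr, c(1, 2), mean)
  if (method == "mean_plus_2sd") {
    if (length(subjects) < 2) stop("mean_plus_2sd needs at least 2 subjects")
    W <- W + 2 * apply(arr, c(1, 2), sd)
  }
  dimnames(W) <- dimnames(ref$weights)
  diag(W) <- 0
  structure(
    list(W = W, mask = ref$mask, roiset = ref$roiset,
         aggregation = method, n_subjects = length(subjects)),
    class = "group_graph"
  )
}

#' @export
print.group_graph <- function(x, ...) {
  cat(sprintf("<group_graph> %d ROIs, aggregation '%s' over %d subjects\n",
              nrow(x$W), x$aggregation, x$n_subjects))
  invisible(x)
}

#' Specify a proportional threshold sweep
#'
#' Defaults follow the usual multi-threshold strategy for normalized and
#' averaged streamline weights: 0.01 to 0.1 in steps of 0.0025, i.e. 37
#' thresholds.
#'
#' @param lo,hi,step Sweep bounds and increment.
#' @return Object of class `"threshold_spec"` with the vector of thresholds.
#' @export
threshold_spec <- function(lo = 0.01, hi = 0.1, step = 0.0025) {
  if (!(lo < hi) && !isTRUE(all.equal(lo, hi))) stop("need lo <= hi")
  if (step <= 0) stop("step must be positive")
  count <- floor((hi - lo) / step + 1e-9) + 1
  structure(
    list(lo = lo, hi = hi, step = step,
         thresholds = lo + (seq_len(count) - 1) * step),
    class = "threshold_spec"
  )
}

#' Threshold a group graph over a sweep
#'
#' At each threshold t, edges with weight >= t are retained and weaker
#' edges removed (weak probabilistic connections are treated as putative
#' false positives). Sub-threshold and masked entries are absent edges,
#' not zero-weight edges.
#'
#' @param g A `"group_graph"`.
#' @param spec A [threshold_spec()].
#' @return List of `"thresholded_graph"` objects (fields `W` weighted
#'   adjacency with absent edges as 0, `A` binarized adjacency, `threshold`,
#'   `roiset`).
#' @export
apply_thresholds <- function(g, spec = threshold_spec()) {
  stopifnot(inherits(g, "group_graph"), inherits(spec, "threshold_spec"))
  lapply(spec$thresholds, function(t) {
    W <- g$W
    W[W < t] <- 0
    A <- (W > 0) * 1
    structure(list(W = W, A = A, threshold = t, roiset = g$roiset),
              class = "thresholded_graph")
  })
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> t=%.4g: %d nodes, %d edges\n",
              x$threshold, nrow(x$W), sum(x$A) / 2))
  invisible(x)
}

# coerce the graph arguments accepted across the package to a symmetric
# weight (or binary) matrix
graph_weight_matrix <- function(graph, weighted = TRUE) {
  if (inherits(graph, "thresholded_graph")) {
    if (weighted) graph$W else graph$A
  } else if (igraph::is_igraph(graph)) {
    w <- igraph::as_adjacency_matrix(
      graph, sparse = FALSE,
      attr = if (weighted && "weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL
    )
    w
  } else {
    m <- as.matrix(graph)
    stopifnot(nrow(m) == ncol(m))
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop("weight matrix must be symmetric")
    }
    if (weighted) m else (m > 0) * 1
  }
}

as_igraph_graph <- function(graph, weighted = TRUE) {
  m <- graph_weight_matrix(graph, weighted = weighted)
  diag(m) <- 0
  igraph::graph_from_adjacency_matrix(
    m, mode = "undirected",
    weighted = if (weighted) TRUE else NULL, diag = FALSE
  )
}

#' Is a graph connected?
#'
#' TRUE iff every pair of nodes is linked by a path; a node isolated by
#' thresholding therefore fails connectedness (it is not dropped).
#'
#' @param graph A `"thresholded_graph"`, igraph object, or matrix.
#' @return Logical.
#' @export
is_connected_graph <- function(graph) {
  g <- as_igraph_graph(graph, weighted = FALSE)
  if (igraph::vcount(g) == 0) stop("empty graph")
  igraph::is_connected(g)
}

#' Mean clustering coefficient (binary)
#'
#' Watts–Strogatz clustering on the binarized adjacency:
#' \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with \eqn{C_i = 0} for \eqn{k_i < 2},
#' averaged over nodes.
#'
#' @param graph Graph (binarized internally).
#' @return List with `C` (mean) and `Ci` (per node).
#' @export
clustering_coefficient <- function(graph) {
  g <- as_igraph_graph(graph, weighted = FALSE)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(ci) <- igraph::V(g)$name
  list(C = mean(ci), Ci = ci)
}

#' Characteristic path length (binary)
#'
#' Mean hop-count distance over all ordered node pairs of a connected
#' graph.
#'
#' @param graph Graph (binarized internally); must be connected.
#' @return Scalar L.
#' @export
characteristic_path_length <- function(graph) {
  g <- as_igraph_graph(graph, weighted = FALSE)
  if (!igraph::is_connected(g)) stop("graph is disconnected; L is undefined")
  d <- igraph::distances(g, weights = NA)
  mean(d[row(d) != col(d)])
}

#' Small-worldness against degree-preserving null networks
#'
#' Computes \eqn{S = (C/C_{rand}) / (L/L_{rand})} where `C` and `L` are the
#' binary clustering coefficient and characteristic path length of the
#' graph, and the `rand` terms are means over `n_null` Maslov–Sneppen
#' degree-preserving rewirings (10 x edge-count swap attempts each; only
#' connected rewirings are accepted, with a bounded number of retries).
#' A quotient above 1 is read as small-world.
#'
#' @param graph Connected graph (binarized internally).
#' @param n_null Number of null networks (default 100).
#' @param seed RNG seed; the whole null ensemble is reproducible from it.
#' @param max_tries Attempts per null to obtain a connected rewiring.
#' @return List with `S`, `C`, `L`, `C_rand`, `L_rand`.
#' @export
small_worldness <- function(graph, n_null = 100, seed = 1L, max_tries = 50L) {
  stopifnot(n_null >= 1)
  g <- as_igraph_graph(graph, weighted = FALSE)
  if (!igraph::is_connected(g)) stop("graph is disconnected; S is undefined")
  cc <- clustering_coefficient(graph)
  L <- characteristic_path_length(graph)
  n_swap <- 10 * igraph::ecount(g)
  c_rand <- numeric(n_null)
  l_rand <- numeric(n_null)
  withr::with_seed(seed, {
    for (k in seq_len(n_null)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swap))
        if (igraph::is_connected(gr)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to obtain a connected degree-preserving rewiring")
      c_rand[k] <- mean(igraph::transitivity(gr, type = "localundirected",
                                             isolates = "zero"))
      dr <- igraph::distances(gr, weights = NA)
      l_rand[k] <- mean(dr[row(dr) != col(dr)])
    }
  })
  C_rand <- mean(c_rand)
  L_rand <- mean(l_rand)
  list(S = (cc$C / C_rand) / (L / L_rand),
       C = cc$C, L = L, C_rand = C_rand, L_rand = L_rand)
}

#' Screen a threshold sweep by the three graph goodness criteria
#'
#' For every thresholded graph, records connectedness, maximized modularity
#' Q, binary clustering C and path length L, their null-model means, and the
#' small-worldness quotient S. A graph is admitted iff it is connected,
#' Q > 0.3, and S > 1. Q and S are only computed (and reported) for
#' connected graphs; disconnected thresholds are rejected outright.
#'
#' @param g A `"group_graph"`.
#' @param spec A [threshold_spec()].
#' @param n_null,seed Passed to [small_worldness()]; null ensembles at
#'   successive thresholds use seeds `seed`, `seed + 1`, ...
#' @param weighted_modularity Use weighted modularity (default).
#' @return A data frame (one row per threshold) with columns `threshold`,
#'   `connected`, `Q`, `n_modules`, `C`, `L`, `C_rand`, `L_rand`, `S`,
#'   `admitted`; the thresholded graphs are attached as attribute `graphs`
#'   and the per-threshold module affiliations as attribute `memberships`.
#' @export
admissibility_sweep <- function(g, spec = threshold_spec(), n_null = 100,
                                seed = 1L, weighted_modularity = TRUE) {
  graphs <- apply_thresholds(g, spec)
  n_t <- length(graphs)
  rec <- data.frame(
    threshold = vapply(graphs, `[[`, numeric(1), "threshold"),
    connected = FALSE, Q = NA_real_, n_modules = NA_integer_,
    C = NA_real_, L = NA_real_, C_rand = NA_real_, L_rand = NA_real_,
    S = NA_real_, admitted = FALSE
  )
  memberships <- vector("list", n_t)
  for (k in seq_len(n_t)) {
    tg <- graphs[[k]]
    rec$connected[k] <- is_connected_graph(tg)
    if (!rec$connected[k]) next
    mod <- newman_modularity(tg, weighted = weighted_modularity)
    rec$Q[k] <- mod$Q
    rec$n_modules[k] <- mod$n_modules
    memberships[[k]] <- mod$membership
    sw <- small_worldness(tg, n_null = n_null, seed = seed + k - 1L)
    rec$C[k] <- sw$C
    rec$L[k] <- sw$L
    rec$C_rand[k] <- sw$C_rand
    rec$L_rand[k] <- sw$L_rand
    rec$S[k] <- sw$S
    rec$admitted[k] <- rec$Q[k] > 0.3 && rec$S[k] > 1
  }
  attr(rec, "graphs") <- graphs
  attr(rec, "memberships") <- memberships
  rec
}

#' Admit thresholded graphs by the goodness criteria
#'
#' @param records Data frame from [admissibility_sweep()] (or any table
#'   with `connected`, `Q`, `S` columns).
#' @return The admitted subset of rows (connected, Q > 0.3, S > 1), with
#'   attributes `graphs`/`memberships` subset accordingly when present.
#' @export
admit_graphs <- function(records) {
  keep <- records$connected & !is.na(records$Q) & records$Q > 0.3 &
    !is.na(records$S) & records$S > 1
  out <- records[keep, , drop = FALSE]
  if (!is.null(attr(records, "graphs"))) {
    attr(out, "graphs") <- attr(records, "graphs")[keep]
    attr(out, "memberships") <- attr(records, "memberships")[keep]
  }
  out
}

#' Edge density of a graph
#'
#' @param graph Graph coercible by the package.
#' @return Fraction of possible unordered node pairs with an edge.
#' @export
edge_density_graph <- function(graph) {
  a <- graph_weight_matrix(graph, weighted = FALSE)
  n <- nrow(a)
  if (n < 2) return(0)
  sum(a > 0) / (n * (n - 1))
}

#' Export a thresholded graph to GraphML
#'
#' @param tg A `"thresholded_graph"`.
#' @param path Output path.
#' @export
write_graphml <- function(tg, path) {
  igraph::write_graph(as_igraph_graph(tg, weighted = TRUE), path,
                      format = "graphml")
  invisible(path)
}
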