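#' Convert connection weights to lengths
#'
#' Reciprocal transform: length = 1/weight for present edges; absent or
#' zero-weight pairs get infinite length. Stronger connections are thereby
#' strictly shorter.
#'
#' @param graph A `"thresholded_graph"`, igraph object, or weight matrix.
#' @return Symmetric length matrix with `Inf` for absent edges and zero
#'   diagonal.
#' @export
weights_to_lengths <- function(graph) {
  w <- graph_weight_matrix(graph, weighted = TRUE)
  if (any(w < 0)) stop("weights must be nonnegative")
  lm <- ifelse(w > 0, 1 / w, Inf)
  diag(lm) <- 0
  dimnames(lm) <- dimnames(w)
  lm
}

#' All-pairs shortest-path distance matrix
#'
#' Dijkstra's algorithm on a connection-length matrix. Unreachable pairs
#' keep infinite distance.
#'
#' @param lm Length matrix from [weights_to_lengths()] (finite entries are
#'   edges).
#' @return Symmetric distance matrix `D` with zero diagonal.
#' @export
dijkstra_all_pairs <- function(lm) {
  lm <- as.matrix(lm)
  stopifnot(nrow(lm) == ncol(lm))
  if (any(lm < 0)) stop("lengths must be nonnegative")
  adj <- lm
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(lm)
  D
}

#' Rank parieto-premotor pairs by distance percentile
#'
#' Percentiles are computed over the finite parieto-premotor distances of
#' one hemisphere (up to 322 values); each pair is assigned the tightest
#' cutoff it falls strictly below (`p15` < 15th percentile, then `p25`,
#' `p50`, `p75`), else `"none"`. The classes are nested by construction.
#'
#' @param D Distance matrix over the full ROI set.
#' @param roiset [roiset()] assigning lobes.
#' @param cutoffs Percentile cutoffs as fractions (default 0.15, 0.25,
#'   0.50, 0.75).
#' @return Data frame with one row per parietal x premotor pair: `parietal`,
#'   `premotor`, `distance`, `percentile_class`.
#' @export
classify_edge_percentiles <- function(D, roiset,
                                      cutoffs = c(0.15, 0.25, 0.50, 0.75)) {
  par_idx <- which(roiset$lobe == "parietal")
  pm_idx <- which(roiset$lobe == "premotor")
  pairs <- expand.grid(pi = par_idx, mi = pm_idx, KEEP.OUT.ATTRS = FALSE)
  d <- D[cbind(pairs$pi, pairs$mi)]
  finite <- d[is.finite(d)]
  if (length(finite) < 2) stop("need at least 2 finite parieto-premotor distances")
  q <- quantile(finite, probs = cutoffs, type = q_type, names = FALSE)
  labels <- paste0("p", round(cutoffs * 100))
  cls <- rep("none", length(d))
  for (k in rev(seq_along(cutoffs))) {
    cls[is.finite(d) & d < q[k]] <- labels[k]
  }
  data.frame(
    parietal = roiset$name[pairs$pi],
    premotor = roiset$name[pairs$mi],
    distance = d,
    percentile_class = factor(cls, levels = c(labels, "none")),
    stringsAsFactors = FALSE
  )
}

#' Select the analysis graph from the admitted sweep
#'
#' Returns the admitted thresholded graph with the highest edge density;
#' ties go to the lowest threshold. With the default sweep on real-world
#' group matrices this is the lowest admitted threshold.
#'
#' @param admitted Data frame from [admit_graphs()] with attached graphs.
#' @return A `"thresholded_graph"`, with its row's membership attached as
#'   attribute `"membership"` when available.
#' @export
select_analysis_graph <- function(admitted) {
  graphs <- attr(admitted, "graphs")
  if (is.null(graphs) || length(graphs) == 0) stop("no admitted graphs")
  dens <- vapply(graphs, edge_density_graph, numeric(1))
  thr <- vapply(graphs, `[[`, numeric(1), "threshold")
  best <- order(-dens, thr)[1]
  g <- graphs[[best]]
  mem <- attr(admitted, "memberships")
  if (!is.null(mem)) attr(g, "membership") <- mem[[best]]
  g
}
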