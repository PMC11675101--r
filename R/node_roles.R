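#' Participation coefficient
#'
#' \eqn{y_i = 1 - \sum_{m \in M} (k_i(m)/k_i)^2}, with \eqn{k_i(m)} the
#' connectivity of node i into module m. Weighted by default (strengths in
#' place of link counts); isolated nodes get 0. Values lie in
#' \[0, 1 - 1/|M|\]; connector hubs sit high.
#'
#' @param graph Graph coercible by the package.
#' @param membership Module id per node (e.g. from [newman_modularity()]).
#' @param weighted Use edge weights (default) or binary links.
#' @return Named numeric vector `y`.
#' @export
participation_coefficient <- function(graph, membership, weighted = TRUE) {
  w <- graph_weight_matrix(graph, weighted = weighted)
  stopifnot(length(membership) == nrow(w))
  k <- rowSums(w)
  mods <- unique(membership)
  km <- vapply(mods, function(m) rowSums(w[, membership == m, drop = FALSE]),
               numeric(nrow(w)))
  y <- 1 - rowSums((km / ifelse(k > 0, k, 1))^2)
  y[k == 0] <- 0
  setNames(y, rownames(w))
}

#' Within-module degree z-score
#'
#' Standardizes each node's within-module connectivity against the mean and
#' sample SD of its module's within-connectivity distribution:
#' \eqn{z_i = (k_i(m_i) - \bar k(m_i)) / \sigma^{k}(m_i)}. Singleton
#' modules and zero-SD modules yield 0. Provincial hubs sit high.
#'
#' @inheritParams participation_coefficient
#' @return Named numeric vector `z`.
#' @export
within_module_degree_z <- function(graph, membership, weighted = TRUE) {
  w <- graph_weight_matrix(graph, weighted = weighted)
  stopifnot(length(membership) == nrow(w))
  z <- numeric(nrow(w))
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kin <- rowSums(w[idx, idx, drop = FALSE])
    s <- if (length(idx) > 1) sd(kin) else 0
    z[idx] <- if (is.na(s) || s == 0) 0 else (kin - mean(kin)) / s
  }
  setNames(z, rownames(w))
}

#' Node strength
#'
#' Sum of the weights of all edges incident to each node (the weighted
#' degree).
#'
#' @param graph Graph coercible by the package.
#' @return Named numeric vector `s`.
#' @export
node_strength <- function(graph) {
  w <- graph_weight_matrix(graph, weighted = TRUE)
  setNames(rowSums(w), rownames(w))
}

#' Node betweenness centrality on a length matrix
#'
#' Brandes' algorithm on connection lengths, normalized by
#' \eqn{1/((n-1)(n-2))} over ordered pairs so values lie in \[0, 1\]:
#' the fraction of all shortest paths that pass through the node (path
#' endpoints are not counted as on the path).
#'
#' @param lm Length matrix from [weights_to_lengths()].
#' @return Named numeric vector `b` in \[0, 1\].
#' @export
node_betweenness <- function(lm) {
  lm <- as.matrix(lm)
  n <- nrow(lm)
  if (any(lm < 0)) stop("lengths must be nonnegative")
  adj <- lm
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (n < 3) return(setNames(numeric(n), rownames(lm)))
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight, directed = FALSE)
  # igraph counts unordered pairs; the ordered-pair formula doubles them
  setNames(2 * b / ((n - 1) * (n - 2)), rownames(lm))
}

#' Stage 1: hub status across the admitted threshold range
#'
#' A node is a connector hub if its participation coefficient exceeds the
#' third quartile (across nodes of the same graph) at both the lowest and
#' the highest admitted threshold; a provincial hub if its within-module
#' degree z-score does so at both endpoints; otherwise a nonhub. Requiring
#' both endpoints excludes nodes that clear the cutoff only in occasional
#' threshold graphs. A node qualifying both ways is assigned connector and
#' recorded in the `"dual"` attribute.
#'
#' @param y_low,y_high Participation coefficients at the lowest/highest
#'   admitted threshold.
#' @param z_low,z_high Within-module degree z-scores at the same graphs.
#' @return Factor per node with levels connector/provincial/nonhub.
#' @export
classify_stage1 <- function(y_low, y_high, z_low, z_high) {
  n <- length(y_low)
  stopifnot(length(y_high) == n, length(z_low) == n, length(z_high) == n)
  conn <- y_low > quantile(y_low, 0.75, type = q_type) &
    y_high > quantile(y_high, 0.75, type = q_type)
  prov <- z_low > quantile(z_low, 0.75, type = q_type) &
    z_high > quantile(z_high, 0.75, type = q_type)
  out <- rep("nonhub", n)
  out[prov] <- "provincial"
  out[conn] <- "connector"  # connector takes precedence on dual qualification
  out <- factor(out, levels = c("connector", "provincial", "nonhub"))
  names(out) <- names(y_low)
  attr(out, "dual") <- names(y_low)[conn & prov]
  out
}

#' Stage 2: hub subtype by strength and betweenness
#'
#' Hubs are split by the network's median (second quartile) of strength and
#' betweenness on the analysis graph: above the median ("up") versus at or
#' below it ("down"). str-up/NBC-up is `rich_central`, str-up/NBC-down
#' `rich`, str-down/NBC-up `poor_central`, both down `poor`. Nonhubs are
#' left `unclassified` here (see [identify_peripheral()]).
#'
#' @param hub_type Factor from [classify_stage1()].
#' @param s Node strengths on the analysis graph.
#' @param b Node betweenness on the analysis graph.
#' @return Factor per node with levels rich_central/rich/poor_central/
#'   poor/peripheral/unclassified.
#' @export
classify_stage2 <- function(hub_type, s, b) {
  n <- length(hub_type)
  stopifnot(length(s) == n, length(b) == n)
  q2s <- quantile(s, 0.5, type = q_type)
  q2b <- quantile(b, 0.5, type = q_type)
  sub <- rep("unclassified", n)
  hub <- hub_type %in% c("connector", "provincial")
  sub[hub & s > q2s & b > q2b] <- "rich_central"
  sub[hub & s > q2s & b <= q2b] <- "rich"
  sub[hub & s <= q2s & b > q2b] <- "poor_central"
  sub[hub & s <= q2s & b <= q2b] <- "poor"
  out <- factor(sub, levels = c("rich_central", "rich", "poor_central",
                                "poor", "peripheral", "unclassified"))
  names(out) <- names(hub_type)
  out
}

#' Peripheral nodes among the nonhubs
#'
#' Nonhubs with both strength and betweenness strictly below the first
#' quartile of the network are peripheral; other nonhubs stay
#' unclassified. Hubs are never peripheral.
#'
#' @inheritParams classify_stage2
#' @param subtype Factor from [classify_stage2()]; peripheral labels are
#'   filled into it.
#' @return The subtype factor with peripheral nonhubs marked.
#' @export
identify_peripheral <- function(hub_type, subtype, s, b) {
  q1s <- quantile(s, 0.25, type = q_type)
  q1b <- quantile(b, 0.25, type = q_type)
  peri <- hub_type == "nonhub" & s < q1s & b < q1b
  subtype[peri] <- "peripheral"
  subtype
}

#' Full two-stage node role classification
#'
#' Runs stage 1 on the endpoint graphs of the admitted threshold range
#' (each with its own modularity affiliation) and stage 2 plus peripheral
#' detection on the analysis graph.
#'
#' @param admitted Data frame from [admit_graphs()] with attached graphs
#'   and memberships; needs at least 2 admitted thresholds.
#' @param analysis_graph Graph from [select_analysis_graph()].
#' @param weighted Use weighted centralities (default).
#' @return Data frame with one row per node: `node`, `hub_type`, `subtype`,
#'   `y_low`, `y_high`, `z_low`, `z_high`, `strength`, `betweenness`.
#' @export
classify_node_roles <- function(admitted, analysis_graph, weighted = TRUE) {
  graphs <- attr(admitted, "graphs")
  mems <- attr(admitted, "memberships")
  if (is.null(graphs) || length(graphs) < 2) {
    stop("need at least 2 admitted thresholds for hub classification")
  }
  thr <- vapply(graphs, `[[`, numeric(1), "threshold")
  lo <- which.min(thr)
  hi <- which.max(thr)
  y_low <- participation_coefficient(graphs[[lo]], mems[[lo]], weighted)
  y_high <- participation_coefficient(graphs[[hi]], mems[[hi]], weighted)
  z_low <- within_module_degree_z(graphs[[lo]], mems[[lo]], weighted)
  z_high <- within_module_degree_z(graphs[[hi]], mems[[hi]], weighted)
  hub_type <- classify_stage1(y_low, y_high, z_low, z_high)
  s <- node_strength(analysis_graph)
  b <- node_betweenness(weights_to_lengths(analysis_graph))
  subtype <- classify_stage2(hub_type, s, b)
  subtype <- identify_peripheral(hub_type, subtype, s, b)
  out <- data.frame(
    node = names(y_low),
    hub_type = hub_type,
    subtype = subtype,
    y_low = unname(y_low), y_high = unname(y_high),
    z_low = unname(z_low), z_high = unname(z_high),
    strength = unname(s), betweenness = unname(b),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "dual") <- attr(hub_type, "dual")
  out
}
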