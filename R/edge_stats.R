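#' Enumerate the interlobar (parieto-premotor) pairs of an ROI set
#'
#' @param roiset A [roiset()].
#' @return Data frame with `parietal`, `premotor` labels and matrix indices
#'   `i`, `j`; rows ordered parietal-major (Table-style layout).
#' @export
interlobar_pairs <- function(roiset) {
  par_idx <- which(roiset$lobe == "parietal")
  pm_idx <- which(roiset$lobe == "premotor")
  pairs <- expand.grid(mi = pm_idx, pi = par_idx, KEEP.OUT.ATTRS = FALSE)
  data.frame(
    parietal = roiset$name[pairs$pi],
    premotor = roiset$name[pairs$mi],
    i = pairs$pi, j = pairs$mi,
    stringsAsFactors = FALSE
  )
}

#' Subject-by-edge matrix of interlobar weights
#'
#' Stacks every subject's normalized symmetric weights at the interlobar
#' pairs into a subjects x pairs matrix. Pairs absent in a subject are
#' observed zeros, not missing values.
#'
#' @param subjects List of `"normalized_connectome"` objects.
#' @param roiset A [roiset()].
#' @return Numeric matrix, one row per subject, one column per pair
#'   (named `parietal~premotor`).
#' @export
subject_edge_matrix <- function(subjects, roiset) {
  pairs <- interlobar_pairs(roiset)
  m <- t(vapply(subjects, function(s) s$weights[cbind(pairs$i, pairs$j)],
                numeric(nrow(pairs))))
  colnames(m) <- paste(pairs$parietal, pairs$premotor, sep = "~")
  rn <- vapply(seq_along(subjects), function(k) {
    id <- subjects[[k]]$subject_id
    if (is.null(id) || is.na(id)) sprintf("S%02d", k) else id
  }, character(1))
  rownames(m) <- rn
  m
}

#' Edge-wise paired t-tests between hemispheres
#'
#' Two-sided paired-sample t-test per edge on the left-minus-right subject
#' differences. Degenerate edges are handled explicitly: all-zero
#' differences give t = 0, p = 1; nonzero constant differences (zero
#' variance) give an infinite t and the smallest representable p, flagged
#' `degenerate`.
#'
#' @param left,right Subject x edge matrices with identical dimensions and
#'   subject order (see [subject_edge_matrix()]).
#' @return Data frame with `edge`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_per_edge <- function(left, right) {
  if (!all(dim(left) == dim(right))) stop("left/right dimensions differ")
  if (!is.null(rownames(left)) && !is.null(rownames(right)) &&
      !identical(rownames(left), rownames(right))) {
    stop("left/right subject sets differ")
  }
  n <- nrow(left)
  if (n < 3) stop("need at least 3 subjects for paired t-tests")
  d <- left - right
  m <- colMeans(d)
  sdv <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  tt <- ifelse(sdv > 0, m / (sdv / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(sdv > 0, 2 * pt(-abs(m / (sdv / sqrt(n))), df = n - 1),
              ifelse(m == 0, 1, .Machine$double.xmin))
  data.frame(
    edge = colnames(left),
    t = unname(tt), df = n - 1, p = unname(p),
    degenerate = unname(sdv == 0 & m != 0),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values with enforced monotonicity; an edge is
#' significant when its adjusted p is at or below `alpha`.
#'
#' @param p Raw p values in \[0, 1\].
#' @param alpha Significance level (default 0.05).
#' @return Data frame with `p`, `p_adj`, `significant`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  p_adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = p_adj, significant = p_adj <= alpha)
}

#' Coefficient of variation per edge
#'
#' Sample SD divided by mean, per column of a subject x edge matrix.
#' Edges with mean 0 get `NA` with `defined = FALSE`.
#'
#' @param values Subject x edge matrix.
#' @return Data frame with `edge`, `mean`, `sd`, `cv`, `defined`.
#' @export
coefficient_of_variation <- function(values) {
  if (nrow(values) < 2) stop("need at least 2 subjects")
  m <- colMeans(values)
  s <- apply(values, 2, sd)
  cv <- ifelse(m != 0, s / m, NA_real_)
  data.frame(
    edge = colnames(values) %||% as.character(seq_along(m)),
    mean = unname(m), sd = unname(s), cv = unname(cv),
    defined = unname(m != 0),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quartile clusters of edge variability
#'
#' Partitions the edges of a hemisphere by their CV quartiles: cluster A
#' below the first quartile, B from Q1 up to (strictly below) the median,
#' C up to Q3, D the rest. Undefined CVs get `NA`.
#'
#' @param cv Numeric CV per edge (possibly with `NA`).
#' @return Factor with levels A, B, C, D.
#' @export
cv_quartile_clusters <- function(cv) {
  ok <- !is.na(cv)
  if (sum(ok) < 4) stop("need at least 4 defined CV values")
  q <- quantile(cv[ok], c(0.25, 0.5, 0.75), type = q_type, names = FALSE)
  cl <- rep(NA_character_, length(cv))
  cl[ok] <- "D"
  cl[ok & cv < q[3]] <- "C"
  cl[ok & cv < q[2]] <- "B"
  cl[ok & cv < q[1]] <- "A"
  factor(cl, levels = c("A", "B", "C", "D"))
}

#' Hemispheric lateralization statistics for every interlobar edge
#'
#' Convenience wrapper: paired t-tests per edge, BH-FDR adjustment, and
#' per-hemisphere CV with quartile clusters.
#'
#' @param left_subjects,right_subjects Lists of `"normalized_connectome"`
#'   objects (same subjects in the same order).
#' @param roiset A [roiset()].
#' @param alpha Significance level for the FDR-adjusted p values.
#' @return List with `edges` (parietal, premotor, t, df, p, p_adj,
#'   significant) and `variability` (per hemisphere mean, sd, cv, cluster).
#' @export
edge_lateralization_stats <- function(left_subjects, right_subjects, roiset,
                                      alpha = 0.05) {
  if (length(left_subjects) != length(right_subjects)) {
    stop("left/right subject counts differ")
  }
  pairs <- interlobar_pairs(roiset)
  lm <- subject_edge_matrix(left_subjects, roiset)
  rm_ <- subject_edge_matrix(right_subjects, roiset)
  tt <- paired_t_per_edge(lm, rm_)
  fdr <- bh_fdr(tt$p, alpha = alpha)
  edges <- data.frame(
    parietal = pairs$parietal, premotor = pairs$premotor,
    t = tt$t, df = tt$df, p = tt$p,
    p_adj = fdr$p_adj, significant = fdr$significant,
    degenerate = tt$degenerate,
    stringsAsFactors = FALSE
  )
  variability <- do.call(rbind, lapply(
    list(left = lm, right = rm_), function(x) coefficient_of_variation(x)
  ))
  variability$hemisphere <- rep(c("left", "right"), each = nrow(pairs))
  cl <- lapply(c("left", "right"), function(h) {
    as.character(cv_quartile_clusters(
      variability$cv[variability$hemisphere == h]
    ))
  })
  variability$cluster <- factor(unlist(cl), levels = c("A", "B", "C", "D"))
  rownames(variability) <- NULL
  list(edges = edges, variability = variability)
}
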