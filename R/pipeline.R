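#' Configure a full pipeline run
#'
#' Input is either an in-memory cohort from [generate_cohort()] or a
#' directory layout `input_dir/left/*.csv`, `input_dir/right/*.csv` with an
#' ROI metadata table and optional waytotal sidecar (as written by
#' [write_cohort()]). All referenced paths are checked at configuration
#' time, before any computation.
#'
#' @param cohort Optional in-memory cohort (takes precedence).
#' @param input_dir,roi_path,waytotal_path On-disk cohort location.
#' @param normalize Divide counts by waytotals (`TRUE`, default) or treat
#'   the matrices as already normalized.
#' @param aggregation `"mean"` or `"mean_plus_2sd"`.
#' @param threshold_lo,threshold_hi,threshold_step Sweep parameters
#'   (defaults 0.01, 0.1, 0.0025: 37 thresholds).
#' @param n_null Null networks per threshold for small-worldness.
#' @param seed RNG seed for the null ensembles.
#' @param alpha Significance level for FDR-adjusted lateralization tests.
#' @param percentile_cutoffs Distance-ranking cutoffs as fractions.
#' @param weighted Weighted modularity/centralities (default TRUE).
#' @param out_dir Optional output directory; when given, all tables and a
#'   run manifest are written there.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL, roi_path = NULL,
                            waytotal_path = NULL, normalize = TRUE,
                            aggregation = "mean",
                            threshold_lo = 0.01, threshold_hi = 0.1,
                            threshold_step = 0.0025,
                            n_null = 100, seed = 1L, alpha = 0.05,
                            percentile_cutoffs = c(0.15, 0.25, 0.50, 0.75),
                            weighted = TRUE, out_dir = NULL) {
  if (is.null(cohort)) {
    if (is.null(input_dir)) stop("supply either a cohort or input_dir")
    if (!dir.exists(input_dir)) stop("input_dir not found: ", input_dir)
    for (h in c("left", "right")) {
      if (!dir.exists(file.path(input_dir, h))) {
        stop("input_dir misses subdirectory: ", file.path(input_dir, h))
      }
    }
    if (is.null(roi_path)) roi_path <- file.path(input_dir, "roi_table.csv")
    if (!file.exists(roi_path)) stop("ROI metadata not found: ", roi_path)
    if (is.null(waytotal_path)) {
      cand <- file.path(input_dir, "waytotal.csv")
      if (file.exists(cand)) waytotal_path <- cand
    } else if (!file.exists(waytotal_path)) {
      stop("waytotal sidecar not found: ", waytotal_path)
    }
  }
  structure(
    list(cohort = cohort, input_dir = input_dir, roi_path = roi_path,
         waytotal_path = waytotal_path, normalize = normalize,
         aggregation = match.arg(aggregation, c("mean", "mean_plus_2sd")),
         threshold_lo = threshold_lo, threshold_hi = threshold_hi,
         threshold_step = threshold_step, n_null = n_null,
         seed = as.integer(seed), alpha = alpha,
         percentile_cutoffs = percentile_cutoffs, weighted = weighted,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

load_cohort_subjects <- function(config) {
  if (!is.null(config$cohort)) {
    rs <- config$cohort$spec$roiset
    raw <- config$cohort[c("left", "right")]
  } else {
    rs <- read_roi_table(config$roi_path)
    raw <- lapply(c("left", "right"), function(h) {
      files <- sort(list.files(file.path(config$input_dir, h),
                               pattern = "\\.(csv|tsv|txt)$", full.names = TRUE))
      if (!length(files)) stop("no matrices under ", file.path(config$input_dir, h))
      lapply(files, function(f) {
        read_connectivity_matrix(
          f, rs,
          waytotal = if (!is.null(config$waytotal_path)) config$waytotal_path else NA_real_,
          subject_id = sub("\\.[^.]+$", "", basename(f)), hemisphere = h)
      })
    })
    names(raw) <- c("left", "right")
  }
  subjects <- lapply(raw, function(side) {
    lapply(side, function(s) {
      m <- if (config$normalize) normalize_by_waytotal(s) else s$counts
      nc <- symmetrize_average(m, roiset = rs)
      nc$subject_id <- s$subject_id
      nc
    })
  })
  list(roiset = rs, subjects = subjects)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full connectome analysis pipeline
#'
#' Per hemisphere: normalize and symmetrize the subject matrices, aggregate
#' them into a group graph, sweep the threshold range, screen every
#' thresholded graph by connectedness, modularity, and small-worldness,
#' select the densest admitted graph, compute its Dijkstra distance matrix
#' and distance-percentile ranking of the parieto-premotor pairs, and run
#' the two-stage hub classification over the admitted range. Across
#' hemispheres: edge-wise paired t-tests with BH-FDR adjustment and CV
#' quartile clusters over the 322 interlobar pairs.
#'
#' Identical config and seed give identical results (and byte-identical
#' output files).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a bundle: per-hemisphere `admissibility`, `admitted`
#'   thresholds, `analysis_graph`, `membership`, distance matrix `D`,
#'   `edge_classes`, `node_roles`; cross-hemisphere `edge_stats`; and the
#'   run `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  loaded <- run_stage("input", load_cohort_subjects(config))
  rs <- loaded$roiset
  tspec <- threshold_spec(config$threshold_lo, config$threshold_hi,
                          config$threshold_step)
  hemis <- list()
  for (h in c("left", "right")) {
    subs <- loaded$subjects[[h]]
    g <- run_stage(paste0("aggregate_", h),
                   aggregate_group(subs, method = config$aggregation))
    rec <- run_stage(paste0("admissibility_", h),
                     admissibility_sweep(g, tspec, n_null = config$n_null,
                                         seed = config$seed,
                                         weighted_modularity = config$weighted))
    adm <- admit_graphs(rec)
    if (!nrow(adm)) {
      stop(sprintf("pipeline stage 'admission_%s' failed: no threshold was admitted", h),
           call. = FALSE)
    }
    ag <- select_analysis_graph(adm)
    D <- run_stage(paste0("distance_", h),
                   dijkstra_all_pairs(weights_to_lengths(ag)))
    classes <- run_stage(paste0("edge_classes_", h),
                         classify_edge_percentiles(D, rs, config$percentile_cutoffs))
    roles <- run_stage(paste0("node_roles_", h),
                       classify_node_roles(adm, ag, weighted = config$weighted))
    hemis[[h]] <- list(
      group_graph = g, admissibility = rec, admitted = adm,
      analysis_graph = ag, membership = attr(ag, "membership"),
      D = D, edge_classes = classes, node_roles = roles
    )
  }
  stats <- run_stage("edge_stats",
                     edge_lateralization_stats(loaded$subjects$left,
                                               loaded$subjects$right,
                                               rs, alpha = config$alpha))
  manifest <- list(
    package_version = as.character(packageVersion("tractgraph")),
    config = list(
      input_dir = config$input_dir, roi_path = config$roi_path,
      normalize = config$normalize, aggregation = config$aggregation,
      threshold = c(lo = config$threshold_lo, hi = config$threshold_hi,
                    step = config$threshold_step),
      n_null = config$n_null, seed = config$seed, alpha = config$alpha,
      percentile_cutoffs = config$percentile_cutoffs,
      weighted = config$weighted
    ),
    n_subjects = length(loaded$subjects$left),
    n_rois = nrow(rs),
    n_interlobar_pairs = nrow(interlobar_pairs(rs)),
    n_thresholds = length(tspec$thresholds),
    n_admitted = vapply(hemis, function(x) nrow(x$admitted), numeric(1)),
    analysis_threshold = vapply(hemis, function(x) x$analysis_graph$threshold,
                                numeric(1)),
    n_significant_edges = sum(stats$edges$significant)
  )
  bundle <- list(hemispheres = hemis, edge_stats = stats, manifest = manifest,
                 roiset = rs)
  if (!is.null(config$out_dir)) {
    run_stage("report", write_pipeline_outputs(bundle, config$out_dir))
  }
  invisible(bundle)
}

pair_value_matrix <- function(values, pairs, roiset, default = NA) {
  par_names <- roiset$name[roiset$lobe == "parietal"]
  pm_names <- roiset$name[roiset$lobe == "premotor"]
  m <- matrix(default, length(par_names), length(pm_names),
              dimnames = list(par_names, pm_names))
  m[cbind(pairs$parietal, pairs$premotor)] <- values
  m
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rs <- bundle$roiset
  for (h in c("left", "right")) {
    x <- bundle$hemispheres[[h]]
    rec <- x$admissibility
    attr(rec, "graphs") <- NULL
    attr(rec, "memberships") <- NULL
    data.table::fwrite(rec, file.path(out_dir, sprintf("admissibility_%s.csv", h)))
    par_idx <- rs$lobe == "parietal"
    pm_idx <- rs$lobe == "premotor"
    write_connectivity_matrix(x$D[par_idx, pm_idx, drop = FALSE],
                              file.path(out_dir, sprintf("distance_%s.csv", h)))
    cls <- x$edge_classes
    data.table::fwrite(cls, file.path(out_dir, sprintf("edge_classes_%s.csv", h)))
    cm <- pair_value_matrix(as.character(cls$percentile_class), cls, rs, NA_character_)
    write_connectivity_matrix(cm, file.path(out_dir, sprintf("edge_class_matrix_%s.csv", h)))
    data.table::fwrite(x$node_roles, file.path(out_dir, sprintf("node_roles_%s.csv", h)))
  }
  edges <- bundle$edge_stats$edges
  data.table::fwrite(edges, file.path(out_dir, "edge_stats.csv"))
  write_connectivity_matrix(
    pair_value_matrix(edges$p_adj, edges, rs),
    file.path(out_dir, "p_adj_matrix.csv"))
  data.table::fwrite(bundle$edge_stats$variability,
                     file.path(out_dir, "cv_clusters.csv"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
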