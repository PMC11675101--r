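#' Default module plan for the 37-ROI template
#'
#' Four planted modules, each spanning both lobes, loosely mimicking
#' common parieto-frontal subdomain groupings (superior-parietal/dorsal
#' premotor, inferior-parietal/ventral premotor, anterior-IPS/inferior
#' frontal junction, IPS/medial-frontal). Purely a realistic test-bed
#' structure, not a claim about any real dataset.
#'
#' @return Named list of four character vectors partitioning the default
#'   ROI names.
#' @export
default_module_plan <- function() {
  list(
    dorso_dorsal = c("5Ci", "5L", "5M", "7A", "7M", "7P", "7PC",
                     "6d1", "6d2", "6d3"),
    ventro_dorsal = c("PF", "PFcm", "PFm", "PFop", "PFt", "PGa", "PGp",
                      "6v1", "6v2", "PMv"),
    aips_ifj = c("hIP1", "hIP2", "hIP3", "2", "IFJ1", "IFJ2", "IFS1", "IFS4"),
    ips_medial = c("hIP4", "hIP5", "hIP6", "hIP7", "hIP8",
                   "PreSMA", "SMAproper", "44", "45")
  )
}

default_lateralized_edges <- function() {
  data.frame(
    parietal = c("7A", "7PC", "5L", "PF", "PFm", "PFt",
                 "hIP1", "hIP2", "hIP3", "2",
                 "hIP4", "hIP5", "hIP6", "hIP7",
                 "5M", "PGa", "hIP8", "PFcm", "7M", "PGp"),
    premotor = c("6d1", "6d2", "6d3", "6v1", "6v2", "PMv",
                 "IFJ1", "IFJ2", "IFS1", "IFS4",
                 "PreSMA", "SMAproper", "44", "45",
                 "6v1", "6d1", "IFJ1", "44", "PMv", "PreSMA"),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic connectome cohort
#'
#' Defines the generative model for a cohort of per-subject, per-hemisphere
#' directed streamline-count matrices with known ground truth: a planted
#' modular block structure, planted connector/provincial hubs, planted
#' low-connectivity (peripheral) nodes, and planted left>right edge-weight
#' asymmetries. Directed counts are drawn independently per direction as
#' Poisson(waytotal x expected weight x lognormal noise); the lognormal
#' factor (sdlog `noise_sigma`, unit mean) models multiplicative
#' between-subject variability. Intralobe blocks are generated too, so the
#' pipeline's interlobar masking is exercised on realistic input.
#'
#' @param n_subjects Cohort size (default 40).
#' @param roiset ROI template (default [default_roiset()], 23 parietal +
#'   14 premotor).
#' @param module_plan Named list of node sets partitioning the ROIs.
#' @param weight_within,weight_between Expected normalized weight of
#'   within-/between-module edges (defaults 0.05 and 0.005, a 10:1
#'   contrast).
#' @param connector_nodes,provincial_nodes Planted hubs: connector hubs get
#'   `hub_boost` on their cross-module edges, provincial hubs on their
#'   within-module edges.
#' @param peripheral_nodes Nodes whose entire incident expectation is
#'   scaled by `peripheral_factor`.
#' @param hub_boost Multiplier for hub edges (default 3).
#' @param peripheral_factor Attenuation for peripheral nodes (default 0.25).
#' @param lateralized_edges Data frame `parietal`,`premotor` of interlobar
#'   pairs whose left-hemisphere expectation is multiplied by `delta`.
#' @param delta Left/right expectation ratio for lateralized edges
#'   (default 2; 1 disables lateralization).
#' @param noise_sigma Lognormal sdlog of the multiplicative subject noise
#'   (default 0.2).
#' @param weight_jitter Lognormal sdlog of per-edge heterogeneity of the
#'   expected weights (default 0.4). Drawn once from the spec seed,
#'   symmetric, shared across subjects and hemispheres, so it is part of
#'   the planted expectation: streamline weights in real connectomes are
#'   heavy-tailed rather than block-constant, and without heterogeneity
#'   shortest paths degenerate onto the hub edges. Set 0 for exact
#'   block-constant expectations.
#' @param waytotal Expected streamline budget per seed ROI (default 1e5).
#' @param mode `"poisson"` (stochastic) or `"deterministic"` (counts are
#'   the rounded expectations; for exact ground-truth checks).
#' @param seed RNG seed; the cohort is bit-reproducible from it.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 40,
                           roiset = default_roiset(),
                           module_plan = default_module_plan(),
                           weight_within = 0.05,
                           weight_between = 0.005,
                           connector_nodes = c("7A", "PFm", "hIP3", "44"),
                           provincial_nodes = c("5L", "PFt", "IFJ1", "hIP5"),
                           peripheral_nodes = c("PFop", "5Ci"),
                           hub_boost = 3,
                           peripheral_factor = 0.25,
                           lateralized_edges = default_lateralized_edges(),
                           delta = 2,
                           noise_sigma = 0.2,
                           weight_jitter = 0.4,
                           waytotal = 1e5,
                           mode = c("poisson", "deterministic"),
                           seed = 1L) {
  mode <- match.arg(mode)
  planned <- unlist(module_plan, use.names = FALSE)
  if (!setequal(planned, roiset$name) || anyDuplicated(planned)) {
    stop("module_plan must partition the ROI names")
  }
  stopifnot(delta > 0, noise_sigma >= 0, weight_jitter >= 0, waytotal > 0,
            n_subjects >= 1)
  for (nodes in list(connector_nodes, provincial_nodes, peripheral_nodes)) {
    bad <- setdiff(nodes, roiset$name)
    if (length(bad)) stop("unknown ROI in hub plan: ", paste(bad, collapse = ", "))
  }
  spec <- structure(
    list(n_subjects = n_subjects, roiset = roiset, module_plan = module_plan,
         weight_within = weight_within, weight_between = weight_between,
         connector_nodes = connector_nodes,
         provincial_nodes = provincial_nodes,
         peripheral_nodes = peripheral_nodes,
         hub_boost = hub_boost, peripheral_factor = peripheral_factor,
         lateralized_edges = lateralized_edges, delta = delta,
         noise_sigma = noise_sigma, weight_jitter = weight_jitter,
         waytotal = waytotal,
         mode = mode, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  # materialize both hemispheres once so invalid boosts fail at spec time
  invisible(lapply(c("left", "right"), function(h) expected_weight_matrix(spec, h)))
  spec
}

# per-edge heterogeneity of the expectation: symmetric unit-mean lognormal
# factors, a fixed function of the spec seed
jitter_matrix <- function(spec) {
  n <- nrow(spec$roiset)
  J <- matrix(1, n, n)
  if (spec$weight_jitter > 0) {
    sdl <- spec$weight_jitter
    withr::with_seed(spec$seed + 1000L, {
      J[upper.tri(J)] <- rlnorm(n * (n - 1) / 2, meanlog = -sdl^2 / 2,
                                sdlog = sdl)
    })
    J[lower.tri(J)] <- t(J)[lower.tri(J)]
  }
  J
}

planted_membership <- function(spec) {
  mem <- integer(nrow(spec$roiset))
  names(mem) <- spec$roiset$name
  for (k in seq_along(spec$module_plan)) {
    mem[spec$module_plan[[k]]] <- k
  }
  mem
}

#' Expected directed weight matrix of a synthetic hemisphere
#'
#' @param spec A [synthetic_spec()].
#' @param hemisphere `"left"` or `"right"`.
#' @return Symmetric matrix of expected normalized weights (zero diagonal).
#' @export
expected_weight_matrix <- function(spec, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  rs <- spec$roiset
  n <- nrow(rs)
  mem <- planted_membership(spec)
  same <- outer(mem, mem, "==")
  E <- matrix(spec$weight_between, n, n, dimnames = list(rs$name, rs$name))
  E[same] <- spec$weight_within
  E <- E * jitter_matrix(spec)
  for (h in spec$connector_nodes) {
    cross <- !same[h, ]
    E[h, cross] <- E[h, cross] * spec$hub_boost
    E[cross, h] <- E[cross, h] * spec$hub_boost
  }
  for (h in spec$provincial_nodes) {
    within <- same[h, ]
    E[h, within] <- E[h, within] * spec$hub_boost
    E[within, h] <- E[within, h] * spec$hub_boost
  }
  for (h in spec$peripheral_nodes) {
    E[h, ] <- E[h, ] * spec$peripheral_factor
    E[, h] <- E[, h] * spec$peripheral_factor
  }
  if (hemisphere == "left" && nrow(spec$lateralized_edges)) {
    le <- spec$lateralized_edges
    idx <- cbind(match(le$parietal, rs$name), match(le$premotor, rs$name))
    E[idx] <- E[idx] * spec$delta
    E[idx[, 2:1, drop = FALSE]] <- E[idx[, 2:1, drop = FALSE]] * spec$delta
  }
  diag(E) <- 0
  if (any(E > 1)) {
    over <- which(E > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("expected weight > 1 after boosts at [%s, %s]",
                 rs$name[over[1]], rs$name[over[2]]))
  }
  E
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `left` and `right` (lists of [subject_connectome()]
#'   count matrices, one per subject), `truth` (planted module affiliation,
#'   hub/peripheral node sets, lateralized edges and delta), and the spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rs <- spec$roiset
  n <- nrow(rs)
  E <- list(left = expected_weight_matrix(spec, "left"),
            right = expected_weight_matrix(spec, "right"))
  meanlog <- -spec$noise_sigma^2 / 2  # unit-mean lognormal
  cohort <- list(left = vector("list", spec$n_subjects),
                 right = vector("list", spec$n_subjects))
  withr::with_seed(spec$seed, {
    for (k in seq_len(spec$n_subjects)) {
      for (h in c("left", "right")) {
        lambda <- spec$waytotal * E[[h]]
        if (spec$mode == "poisson") {
          if (spec$noise_sigma > 0) {
            lambda <- lambda * matrix(
              rlnorm(n * n, meanlog = meanlog, sdlog = spec$noise_sigma), n, n)
          }
          counts <- matrix(rpois(n * n, lambda), n, n)
        } else {
          counts <- round(lambda)
        }
        dimnames(counts) <- list(rs$name, rs$name)
        diag(counts) <- 0
        cohort[[h]][[k]] <- subject_connectome(
          counts, rs, waytotal = spec$waytotal,
          subject_id = sprintf("S%02d", k), hemisphere = h
        )
      }
    }
  })
  truth <- list(
    membership = planted_membership(spec),
    connector_nodes = spec$connector_nodes,
    provincial_nodes = spec$provincial_nodes,
    peripheral_nodes = spec$peripheral_nodes,
    lateralized_edges = spec$lateralized_edges,
    delta = spec$delta
  )
  list(left = cohort$left, right = cohort$right, truth = truth, spec = spec)
}

#' Adjusted Rand index of two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement between two labelings of
#' the same nodes; 1 means identical partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

precision_recall <- function(detected, planted) {
  if (!length(planted)) {
    return(c(precision = NA_real_, recall = NA_real_))
  }
  tp <- length(intersect(detected, planted))
  c(precision = if (length(detected)) tp / length(detected) else NA_real_,
    recall = tp / length(planted))
}

#' Score pipeline output against planted ground truth
#'
#' @param result A pipeline bundle from [run_pipeline()].
#' @param truth The `truth` element of [generate_cohort()].
#' @return List with `modules` (per-hemisphere adjusted Rand index),
#'   `nodes` (precision/recall of connector, provincial, and peripheral
#'   recovery per hemisphere; `NA` where nothing was planted), and
#'   `lateralization` (sensitivity over planted edges and realized
#'   false-discovery proportion of the significant set).
#' @export
truth_recovery_report <- function(result, truth) {
  modules <- vapply(c("left", "right"), function(h) {
    mem <- result$hemispheres[[h]]$membership
    adjusted_rand_index(mem[names(truth$membership)], truth$membership)
  }, numeric(1))
  nodes <- lapply(c("left", "right"), function(h) {
    roles <- result$hemispheres[[h]]$node_roles
    rbind(
      connector = precision_recall(
        roles$node[roles$hub_type == "connector"], truth$connector_nodes),
      provincial = precision_recall(
        roles$node[roles$hub_type == "provincial"], truth$provincial_nodes),
      peripheral = precision_recall(
        roles$node[roles$subtype == "peripheral"], truth$peripheral_nodes)
    )
  })
  names(nodes) <- c("left", "right")
  edges <- result$edge_stats$edges
  key <- function(p, m) paste(p, m, sep = "~")
  planted <- key(truth$lateralized_edges$parietal, truth$lateralized_edges$premotor)
  detected <- key(edges$parietal[edges$significant], edges$premotor[edges$significant])
  lateralization <- list(
    sensitivity = if (length(planted) && truth$delta != 1) {
      mean(planted %in% detected)
    } else NA_real_,
    n_significant = length(detected),
    fdp = if (length(detected)) {
      if (truth$delta == 1) 1 else mean(!(detected %in% planted))
    } else 0
  )
  list(modules = modules, nodes = nodes, lateralization = lateralization)
}

#' Write a synthetic cohort to disk
#'
#' Emits one CSV count matrix per subject and hemisphere (the dialect
#' [read_connectivity_matrix()] reads), the ROI metadata table, a waytotal
#' sidecar, the spec as YAML, and the ground truth as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (h in c("left", "right")) {
    dir.create(file.path(dir, h), recursive = TRUE, showWarnings = FALSE)
    for (s in cohort[[h]]) {
      write_connectivity_matrix(
        s$counts, file.path(dir, h, paste0(s$subject_id, ".csv")))
    }
  }
  rs <- cohort$spec$roiset
  data.table::fwrite(as.data.frame(unclass(rs)), file.path(dir, "roi_table.csv"))
  data.table::fwrite(
    data.frame(name = rs$name, waytotal = cohort$spec$waytotal),
    file.path(dir, "waytotal.csv"))
  write_synthetic_spec(cohort$spec, file.path(dir, "spec.yaml"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize / deserialize a synthetic spec as YAML
#'
#' @param spec A [synthetic_spec()].
#' @param path YAML path.
#' @return `write_synthetic_spec` returns `path`; `read_synthetic_spec`
#'   returns the reconstructed spec.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- unclass(spec)
  x$roiset <- as.data.frame(unclass(x$roiset))
  x$roiset <- lapply(x$roiset, as.vector)
  x$lateralized_edges <- lapply(x$lateralized_edges, as.vector)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_spec(
    n_subjects = x$n_subjects,
    roiset = roiset(x$roiset$name, x$roiset$lobe, x$roiset$subdomain,
                    x$roiset$hemisphere),
    module_plan = x$module_plan,
    weight_within = x$weight_within, weight_between = x$weight_between,
    connector_nodes = unlist(x$connector_nodes),
    provincial_nodes = unlist(x$provincial_nodes),
    peripheral_nodes = unlist(x$peripheral_nodes),
    hub_boost = x$hub_boost, peripheral_factor = x$peripheral_factor,
    lateralized_edges = data.frame(parietal = unlist(x$lateralized_edges$parietal),
                                   premotor = unlist(x$lateralized_edges$premotor),
                                   stringsAsFactors = FALSE),
    delta = x$delta, noise_sigma = x$noise_sigma,
    weight_jitter = x$weight_jitter, waytotal = x$waytotal,
    mode = x$mode, seed = x$seed
  )
}
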