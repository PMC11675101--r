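test_that("the same seed reproduces a cohort bit-identically", {
  a <- generate_cohort(small_spec(seed = 7))
  b <- generate_cohort(small_spec(seed = 7))
  expect_identical(a$left[[3]]$counts, b$left[[3]]$counts)
  expect_identical(a$right[[8]]$counts, b$right[[8]]$counts)
  c2 <- generate_cohort(small_spec(seed = 8))
  expect_false(identical(a$left[[3]]$counts, c2$left[[3]]$counts))
  # differing seeds share identical truth structure
  expect_identical(a$truth, c2$truth)
})

test_that("deterministic mode reproduces the expectation exactly", {
  spec <- synthetic_spec(n_subjects = 2, noise_sigma = 0, mode = "deterministic",
                         seed = 1)
  coh <- generate_cohort(spec)
  E <- expected_weight_matrix(spec, "left")
  expect_equal(coh$left[[1]]$counts, round(spec$waytotal * E))
  expect_identical(coh$left[[1]]$counts, coh$left[[2]]$counts)
})

test_that("delta = 1 with zero noise gives identical left/right expectations", {
  spec <- synthetic_spec(n_subjects = 1, delta = 1, noise_sigma = 0,
                         mode = "deterministic", seed = 2)
  coh <- generate_cohort(spec)
  expect_identical(coh$left[[1]]$counts, coh$right[[1]]$counts)
  # with delta > 1 the lateralized edges differ in the expected direction
  spec2 <- synthetic_spec(n_subjects = 1, delta = 2, noise_sigma = 0,
                          mode = "deterministic", seed = 2)
  coh2 <- generate_cohort(spec2)
  le <- spec2$lateralized_edges
  idx <- cbind(match(le$parietal, spec2$roiset$name),
               match(le$premotor, spec2$roiset$name))
  expect_true(all(coh2$left[[1]]$counts[idx] >= 2 * coh2$right[[1]]$counts[idx] - 2))
})

test_that("empirical block means agree with the planted expectation", {
  spec <- synthetic_spec(n_subjects = 150, seed = 31)
  coh <- generate_cohort(spec)
  E <- expected_weight_matrix(spec, "left")
  mem <- coh$truth$membership
  w_stack <- vapply(coh$left, function(s) {
    symmetrize_average(normalize_by_waytotal(s))$weights
  }, matrix(0, 37, 37))
  emp <- apply(w_stack, c(1, 2), mean)
  Esym <- (E + t(E)) / 2
  # per-block relative error of the empirical mean is small at n = 150
  same <- outer(mem, mem, "==")
  off <- row(E) != col(E)
  for (block in list(same & off, !same)) {
    expect_equal(mean(emp[block]), mean(Esym[block]), tolerance = 0.02)
  }
})

test_that("lateralized-edge detection sensitivity is monotone in delta", {
  deltas <- c(1, 1.5, 2, 3)
  sens <- vapply(deltas, function(d) {
    hits <- 0
    planted <- 0
    for (r in 1:3) {
      spec <- synthetic_spec(n_subjects = 12, delta = d, seed = 400 + r)
      coh <- generate_cohort(spec)
      # at delta = 3 a rare draw exceeds its waytotal; that warning is the
      # normalizer doing its job, not a failure of this property
      ncs <- suppressWarnings(lapply(coh[c("left", "right")], function(side) {
        lapply(side, function(s) {
          symmetrize_average(normalize_by_waytotal(s), roiset = spec$roiset)
        })
      }))
      st <- edge_lateralization_stats(ncs$left, ncs$right, spec$roiset)
      key <- paste(st$edges$parietal, st$edges$premotor, sep = "~")
      pk <- paste(spec$lateralized_edges$parietal,
                  spec$lateralized_edges$premotor, sep = "~")
      hits <- hits + sum(st$edges$significant[key %in% pk])
      planted <- planted + length(pk)
    }
    hits / planted
  }, numeric(1))
  expect_true(all(diff(sens) >= -1e-9))
  expect_gt(sens[4], 0.9)
})

test_that("strong-contrast group graphs pass all three admission criteria at 0.01", {
  for (sd in 1:4) {
    spec <- small_spec(seed = 500 + sd)
    coh <- generate_cohort(spec)
    ncs <- lapply(coh$left, function(s) {
      symmetrize_average(normalize_by_waytotal(s), roiset = spec$roiset)
    })
    g <- aggregate_group(ncs)
    tg <- apply_thresholds(g, threshold_spec(0.01, 0.01))[[1]]
    expect_true(is_connected_graph(tg))
    expect_gt(newman_modularity(tg)$Q, 0.3)
    expect_gt(small_worldness(tg, n_null = 20, seed = sd)$S, 1)
  }
})

test_that("spec validation rejects broken plans and overflowing boosts", {
  expect_error(synthetic_spec(module_plan = list(a = "hIP1")), "partition")
  expect_error(synthetic_spec(connector_nodes = "nope"), "unknown ROI")
  expect_error(synthetic_spec(weight_within = 0.5, hub_boost = 10,
                              weight_jitter = 0),
               "expected weight > 1")
})

test_that("cohorts round-trip through disk in the package CSV dialect", {
  spec <- synthetic_spec(n_subjects = 2, seed = 9)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  rs <- read_roi_table(file.path(dir, "roi_table.csv"))
  expect_equal(rs$name, spec$roiset$name)
  back <- read_connectivity_matrix(file.path(dir, "left", "S01.csv"), rs,
                                   waytotal = file.path(dir, "waytotal.csv"))
  expect_equal(back$counts, coh$left[[1]]$counts + 0)
  expect_equal(unname(back$waytotal), rep(spec$waytotal, 37))
  # spec YAML round-trip regenerates the same cohort
  spec2 <- read_synthetic_spec(file.path(dir, "spec.yaml"))
  coh2 <- generate_cohort(spec2)
  expect_identical(coh$left[[2]]$counts, coh2$left[[2]]$counts)
})

test_that("truth recovery reports undefined recalls for empty hub plans", {
  # minimal hand-built bundle: recall against an empty planted set must be
  # NA (undefined), never 0
  roles <- data.frame(
    node = c("A", "B"),
    hub_type = factor(c("connector", "nonhub"),
                      levels = c("connector", "provincial", "nonhub")),
    subtype = factor(c("rich", "unclassified"),
                     levels = c("rich_central", "rich", "poor_central",
                                "poor", "peripheral", "unclassified"))
  )
  result <- list(
    hemispheres = list(
      left = list(membership = c(A = 1, B = 2), node_roles = roles),
      right = list(membership = c(A = 1, B = 2), node_roles = roles)
    ),
    edge_stats = list(edges = data.frame(
      parietal = "A", premotor = "B", significant = FALSE))
  )
  truth <- list(
    membership = c(A = 1, B = 2),
    connector_nodes = character(0), provincial_nodes = character(0),
    peripheral_nodes = character(0),
    lateralized_edges = data.frame(parietal = character(0),
                                   premotor = character(0)),
    delta = 2
  )
  rep <- truth_recovery_report(result, truth)
  expect_true(is.na(rep$nodes$left["connector", "recall"]))
  expect_true(is.na(rep$nodes$left["provincial", "recall"]))
  expect_true(is.na(rep$lateralization$sensitivity))
  expect_equal(rep$modules[["left"]], 1)
})
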