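test_that("participation coefficient has its closed-form values", {
  # all links inside one module -> 0
  A <- matrix(1, 4, 4) - diag(4)
  rownames(A) <- colnames(A) <- paste0("v", 1:4)
  expect_equal(unname(participation_coefficient(A, rep(1, 4))), rep(0, 4))

  # equal split across m modules -> 1 - 1/m
  for (m in 2:5) {
    n <- 2 * m
    star <- matrix(0, n + 1, n + 1)
    star[1, 2:(n + 1)] <- star[2:(n + 1), 1] <- 1
    rownames(star) <- colnames(star) <- paste0("v", 1:(n + 1))
    mem <- c(1, rep(seq_len(m), each = 2) )
    y <- participation_coefficient(star, mem)
    expect_equal(unname(y[1]), 1 - 1 / m, tolerance = 1e-12)
  }

  # isolated node -> 0
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  rownames(iso) <- colnames(iso) <- c("a", "b", "c")
  expect_equal(unname(participation_coefficient(iso, c(1, 2, 1))["c"]), 0)

  # bounded by 1 - 1/|M| on random graphs
  set.seed(59)
  for (rep in 1:5) {
    w <- random_symmetric_graph(12, 0.5)
    mem <- sample(1:3, 12, replace = TRUE)
    y <- participation_coefficient(w, mem)
    expect_true(all(y >= 0 & y <= 1 - 1 / length(unique(mem)) + 1e-12))
  }
})

test_that("within-module degree z-scores standardize within modules", {
  # all within-degrees equal -> all z = 0 (zero-SD rule)
  A <- matrix(1, 4, 4) - diag(4)
  rownames(A) <- colnames(A) <- paste0("v", 1:4)
  expect_equal(unname(within_module_degree_z(A, rep(1, 4))), rep(0, 4))

  # z has module mean 0 when SD > 0; singleton module contributes 0
  set.seed(61)
  w <- random_symmetric_graph(14, 0.5)
  mem <- c(rep(1, 6), rep(2, 7), 3)
  z <- within_module_degree_z(w, mem)
  expect_equal(mean(z[mem == 1]), 0, tolerance = 1e-12)
  expect_equal(mean(z[mem == 2]), 0, tolerance = 1e-12)
  expect_equal(unname(z[mem == 3]), 0)

  # a planted within-module hub carries the largest z in its module
  B <- matrix(0.1, 8, 8)
  B[1, 2:4] <- B[2:4, 1] <- 0.9  # node 1 dominates module {1..4}
  diag(B) <- 0
  rownames(B) <- colnames(B) <- paste0("v", 1:8)
  zb <- within_module_degree_z(B, rep(1:2, each = 4))
  expect_equal(which.max(zb[1:4]), c(v1 = 1L))
})

test_that("strength sums incident weights and satisfies the handshake identity", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.3
  rownames(w) <- colnames(w) <- c("a", "b", "c")
  s <- node_strength(w)
  expect_equal(unname(s["a"]), 0.5)

  iso <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(node_strength(iso)), c(0, 0))

  set.seed(67)
  r <- random_symmetric_graph(10, 0.5)
  expect_equal(sum(node_strength(r)), 2 * sum(r[upper.tri(r)]))
})

test_that("betweenness matches brute-force path enumeration and endpoint rules", {
  # star: center carries every leaf pair, leaves none
  n <- 6
  star <- matrix(Inf, n, n)
  diag(star) <- 0
  star[1, 2:n] <- star[2:n, 1] <- 1
  b <- node_betweenness(star)
  expect_equal(unname(b[1]), 1)
  expect_equal(unname(b[2:n]), rep(0, n - 1))

  # complete graph with equal lengths: direct edges win everywhere
  K <- matrix(1, 5, 5)
  diag(K) <- 0
  expect_equal(unname(node_betweenness(K)), rep(0, 5))

  # random weighted graphs vs exhaustive enumeration (with multiplicities)
  set.seed(71)
  done <- 0
  while (done < 6) {
    w <- random_symmetric_graph(sample(5:9, 1), 0.5)
    if (sum(w) == 0) next
    done <- done + 1
    lm <- weights_to_lengths(w)
    expect_equal(unname(node_betweenness(lm)), brute_betweenness(lm),
                 tolerance = 1e-9)
  }

  # a degree-1 node can never be intermediate
  set.seed(73)
  w <- random_symmetric_graph(8, 0.6)
  w[8, ] <- w[, 8] <- 0
  w[8, 1] <- w[1, 8] <- 0.5
  b8 <- node_betweenness(weights_to_lengths(w))
  expect_equal(unname(b8[8]), 0)
})

test_that("stage-1 classification needs the cutoff at both endpoint thresholds", {
  y_low <- c(a = 0.9, b = 0.8, c = 0.1, d = 0.1, e = 0.1, f = 0.1, g = 0.1, h = 0.1)
  y_high <- c(a = 0.9, b = 0.1, c = 0.1, d = 0.1, e = 0.1, f = 0.1, g = 0.1, h = 0.1)
  z_low <- c(a = 0, b = 0, c = 2.5, d = 0, e = 0, f = 0, g = 0, h = 0)
  z_high <- c(a = 0, b = 0, c = 2.5, d = 0, e = 0, f = 0, g = 0, h = 0)
  ht <- classify_stage1(y_low, y_high, z_low, z_high)
  expect_equal(as.character(ht[["a"]]), "connector")   # above Q3 at both ends
  expect_equal(as.character(ht[["b"]]), "nonhub")      # only at the lowest
  expect_equal(as.character(ht[["c"]]), "provincial")  # z above at both ends

  # quartile sanity: at most ceiling(n/4) + ties exceed Q3
  set.seed(79)
  y <- runif(20)
  n_above <- sum(y > quantile(y, 0.75, type = 7))
  expect_lte(n_above, ceiling(20 / 4))
})

test_that("stage 2 partitions hubs by median strength and betweenness", {
  ht <- factor(c("connector", "connector", "provincial", "provincial",
                 "nonhub", "nonhub", "nonhub", "nonhub"),
               levels = c("connector", "provincial", "nonhub"))
  names(ht) <- letters[1:8]
  s <- c(a = 10, b = 9, c = 1, d = 2, e = 5, f = 5.5, g = 4.5, h = 6)
  b <- c(a = 0.9, b = 0.1, c = 0.8, d = 0.05, e = 0.5, f = 0.4, g = 0.6, h = 0.3)
  sub <- classify_stage2(ht, s, b)
  expect_equal(as.character(sub[["a"]]), "rich_central")  # s up, b up
  expect_equal(as.character(sub[["b"]]), "rich")          # s up, b down
  expect_equal(as.character(sub[["c"]]), "poor_central")  # s down, b up
  expect_equal(as.character(sub[["d"]]), "poor")          # both down
  # every hub receives exactly one subtype
  expect_true(all(sub[ht != "nonhub"] %in%
                    c("rich_central", "rich", "poor_central", "poor")))
  expect_true(all(sub[ht == "nonhub"] == "unclassified"))
})

test_that("peripheral nodes are nonhubs below both first quartiles", {
  ht <- factor(c("nonhub", "nonhub", "connector", "nonhub",
                 "nonhub", "nonhub", "nonhub", "nonhub"),
               levels = c("connector", "provincial", "nonhub"))
  names(ht) <- letters[1:8]
  s <- c(a = 0.1, b = 5, c = 0.1, d = 6, e = 7, f = 8, g = 9, h = 10)
  b <- c(a = 0.01, b = 0.02, c = 0.01, d = 0.5, e = 0.6, f = 0.7, g = 0.8, h = 0.9)
  sub <- classify_stage2(ht, s, b)
  sub <- identify_peripheral(ht, sub, s, b)
  expect_equal(as.character(sub[["a"]]), "peripheral")  # nonhub, both < Q1
  # hub with both metrics low is not peripheral
  expect_false(as.character(sub[["c"]]) == "peripheral")
  # nonhub below only one quartile stays unclassified
  expect_equal(as.character(sub[["b"]]), "unclassified")
})

test_that("planted connector and provincial hubs are recovered from a cohort", {
  spec <- small_spec(seed = 101)
  coh <- generate_cohort(spec)
  cfg <- pipeline_config(cohort = coh, n_null = 10, seed = 3)
  bundle <- run_pipeline(cfg)
  for (h in c("left", "right")) {
    roles <- bundle$hemispheres[[h]]$node_roles
    conn <- roles$node[roles$hub_type == "connector"]
    prov <- roles$node[roles$hub_type == "provincial"]
    expect_true(all(spec$connector_nodes %in% conn))
    expect_true(all(spec$provincial_nodes %in% prov))
  }
})
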