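test_that("labelled matrices parse, realign, and reject unknown ROIs", {
  rs <- toy_roiset(1, 1)  # ROIs P1, M1
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("roi,M1,P1", "M1,0,3", "P1,5,0"), f)
  conn <- read_connectivity_matrix(f, rs)
  expect_equal(conn$counts["P1", "M1"], 5)
  expect_equal(conn$counts["M1", "P1"], 3)

  writeLines(c("roi,P1,XX", "P1,0,5", "XX,3,0"), f)
  expect_error(read_connectivity_matrix(f, rs), "unknown ROI")

  writeLines(c("0,5", "-3,0"), f)
  expect_error(read_connectivity_matrix(f, rs), "negative entry")

  writeLines(c("0\t5\t1", "3\t0\t2"), f)
  expect_error(read_connectivity_matrix(f, rs), "dimension mismatch")
})

test_that("headerless and tab-delimited files are accepted in roiset order", {
  rs <- toy_roiset(1, 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t7", "2\t0"), f)
  conn <- read_connectivity_matrix(f, rs, waytotal = 10)
  expect_equal(unname(conn$counts["P1", "M1"]), 7)
  expect_equal(unname(conn$waytotal), c(10, 10))
})

test_that("a 37x37 matrix round-trips through write-then-read bit-identically", {
  rs <- default_roiset()
  set.seed(11)
  m <- matrix(rpois(37 * 37, 40), 37, 37, dimnames = list(rs$name, rs$name))
  diag(m) <- 0
  f <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_matrix(m, f)
  back <- read_connectivity_matrix(f, rs)
  expect_identical(back$counts, m + 0)  # numeric storage either way
})

test_that("waytotal normalization divides rows and enforces positivity", {
  rs <- toy_roiset(1, 1)
  conn <- subject_connectome(matrix(c(0, 30, 10, 0), 2, 2, byrow = TRUE),
                             rs, waytotal = 100)
  norm <- normalize_by_waytotal(conn)
  expect_equal(unname(norm["P1", "M1"]), 0.3)
  expect_equal(unname(norm["M1", "P1"]), 0.1)

  conn0 <- subject_connectome(matrix(c(0, 1, 1, 0), 2), rs, waytotal = 0)
  expect_error(normalize_by_waytotal(conn0), "positive")

  # rows of a random matrix sum to (row count sum)/waytotal
  rs5 <- toy_roiset(2, 3)
  set.seed(4)
  counts <- matrix(rpois(25, 20), 5, 5)
  diag(counts) <- 0
  wt <- c(50, 60, 70, 80, 90)
  conn5 <- subject_connectome(counts, rs5, waytotal = wt)
  norm5 <- normalize_by_waytotal(conn5)
  expect_equal(unname(rowSums(norm5)), unname(rowSums(conn5$counts) / wt))

  # entries above the waytotal warn but are preserved unless clipping is on
  connov <- subject_connectome(matrix(c(0, 12, 1, 0), 2, 2, byrow = TRUE),
                               rs, waytotal = 10)
  expect_warning(nov <- normalize_by_waytotal(connov), "exceed")
  expect_equal(unname(nov["P1", "M1"]), 1.2)
  expect_warning(novc <- normalize_by_waytotal(connov, clip = TRUE), "exceed")
  expect_equal(unname(novc["P1", "M1"]), 1)
})

test_that("directional averaging symmetrizes and zeroes the diagonal", {
  m <- matrix(c(0.5, 0.2, 0.4, 0.1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  nc <- symmetrize_average(m)
  expect_equal(unname(nc$weights["a", "b"]), 0.3)
  expect_equal(nc$weights, t(nc$weights))
  expect_equal(unname(diag(nc$weights)), c(0, 0))

  # already-symmetric off-diagonal input is unchanged
  s <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = dimnames(m))
  expect_equal(symmetrize_average(s)$weights, s)

  # random matrix equals the independent transpose-average
  set.seed(9)
  r <- matrix(runif(36), 6, 6)
  got <- symmetrize_average(r)$weights
  want <- (r + t(r)) / 2
  diag(want) <- 0
  dimnames(want) <- dimnames(got)
  expect_equal(got, want)
})

test_that("normalization then symmetrization stays within [0, 1]", {
  rs <- toy_roiset(3, 3)
  set.seed(21)
  for (rep in 1:10) {
    counts <- matrix(rpois(36, 30), 6, 6)
    diag(counts) <- 0
    conn <- subject_connectome(counts, rs, waytotal = 200)
    w <- symmetrize_average(normalize_by_waytotal(conn))$weights
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("the interlobar mask retains exactly n_parietal x n_premotor pairs", {
  rs <- default_roiset()
  nc <- symmetrize_average(matrix(0.1, 37, 37,
                                  dimnames = list(rs$name, rs$name)))
  masked <- mask_interlobar(nc, rs)
  expect_equal(n_retained_pairs(masked), 23 * 14)
  expect_equal(n_retained_pairs(masked), 322)

  # idempotent
  expect_identical(mask_interlobar(masked, rs), masked)

  # toy 2 parietal + 3 premotor -> 6 pairs
  rs23 <- toy_roiset(2, 3)
  nc23 <- symmetrize_average(matrix(0.1, 5, 5,
                                    dimnames = list(rs23$name, rs23$name)))
  expect_equal(n_retained_pairs(mask_interlobar(nc23, rs23)), 6)

  # degenerate: a single lobe retains nothing
  rs1 <- roiset(c("A", "B", "C"), rep("parietal", 3))
  nc1 <- symmetrize_average(matrix(0.1, 3, 3,
                                   dimnames = list(rs1$name, rs1$name)))
  expect_equal(n_retained_pairs(mask_interlobar(nc1, rs1)), 0)
})

test_that("ROI sets validate labels and lobes", {
  expect_error(roiset(c("A", "A"), c("parietal", "premotor")), "unique")
  expect_error(roiset(c("A", "B"), c("parietal", "frontal")), "unknown lobe")
  rs <- default_roiset()
  expect_equal(nrow(rs), 37)
  expect_equal(sum(rs$lobe == "parietal"), 23)
  expect_equal(sum(rs$lobe == "premotor"), 14)
})
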