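test_that("Dice, IoU and accuracy follow their definitions", {
  m <- random_mask()
  expect_equal(dice(m, m), 1)
  expect_equal(iou(m, m), 1)
  expect_equal(accuracy(m, m), 1)

  A <- matrix(0, 3, 3); A[1, 1] <- 1
  B <- matrix(0, 3, 3); B[3, 3] <- 1
  expect_equal(dice(A, B), 0)
  expect_equal(iou(A, B), 0)

  # |L| = |S| = 4, overlap 2 on a 3 x 3 grid
  L <- matrix(0, 3, 3); L[1:4] <- 1
  S <- matrix(0, 3, 3); S[3:6] <- 1
  expect_equal(dice(L, S), 0.5)
  expect_equal(iou(L, S), 1 / 3)

  # 10 x 10 grid with 3 disagreeing pixels
  L <- random_mask(10, 10); S <- L
  S[c(1, 50, 100)] <- 1 - S[c(1, 50, 100)]
  expect_equal(accuracy(L, S), 0.97)
  expect_equal(accuracy(L, 1 - L), 0)

  # empty-vs-empty convention
  z <- matrix(0, 4, 4)
  expect_equal(dice(z, z), 1)
  expect_equal(iou(z, z), 1)
  expect_error(dice(L, S[-1, ]), "aligned")
})

test_that("metrics match brute-force pixel-count oracles on random masks", {
  set.seed(11)
  for (i in 1:25) {
    L <- random_mask(9, 11, 0.4); S <- random_mask(9, 11, 0.4)
    expect_equal(dice(L, S), oracle_dice(L, S), tolerance = 1e-12)
    expect_equal(iou(L, S), oracle_iou(L, S), tolerance = 1e-12)
    expect_equal(accuracy(L, S), oracle_acc(L, S), tolerance = 1e-12)
  }
})

test_that("IoU = Dice / (2 - Dice) and IoU <= Dice on random pairs", {
  set.seed(12)
  for (i in 1:200) {
    L <- random_mask(8, 8); S <- random_mask(8, 8)
    d <- dice(L, S); j <- iou(L, S)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_lte(j, d)
  }
})

test_that("boundary extraction uses 4-connectivity with border background", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  b <- extract_boundary(m)
  expect_equal(nrow(b), 1)
  expect_equal(unname(b[1, ]), c(3, 3))

  sq <- matrix(0, 5, 5); sq[2:4, 2:4] <- 1
  b <- extract_boundary(sq)
  expect_equal(nrow(b), 8)                       # centre excluded
  expect_false(any(b[, 1] == 3 & b[, 2] == 3))

  full <- matrix(1, 4, 6)
  b <- extract_boundary(full)
  ring <- sum(full) - 2 * 4                      # interior 2 x 4 block
  expect_equal(nrow(b), ring)
  expect_equal(nrow(extract_boundary(matrix(0, 3, 3))), 0)
})

test_that("modified Hausdorff distance is symmetric and matches brute force", {
  A <- cbind(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  B <- A; B[, "col"] <- B[, "col"] + 2
  expect_equal(mhd(A, B), 1.5)                   # hand-worked shifted block
  expect_equal(mhd(A, A), 0)

  set.seed(13)
  for (i in 1:10) {
    A <- cbind(sample(1:15, 7, TRUE), sample(1:15, 7, TRUE))
    B <- cbind(sample(1:15, 5, TRUE), sample(1:15, 5, TRUE))
    expect_equal(mhd(A, B), oracle_mhd(A, B), tolerance = 1e-12)
    expect_equal(mhd(A, B), mhd(B, A))
  }
  expect_error(mhd(A[0, ], B), "empty")
})

test_that("MHD of a long segment and its shift approaches the shift", {
  A <- cbind(row = rep(5, 200), col = 1:200)
  B <- cbind(row = rep(8, 200), col = 1:200)      # shifted 3 rows
  expect_equal(mhd(A, B), 3, tolerance = 1e-12)
})

test_that("Dice and IoU are invariant under a shared transform", {
  set.seed(14)
  L <- random_mask(10, 10); S <- random_mask(10, 10)
  f <- function(m) m[nrow(m):1, ncol(m):1]        # 180-degree rotation
  expect_equal(dice(f(L), f(S)), dice(L, S))
  expect_equal(iou(f(L), f(S)), iou(L, S))
})

test_that("plaque area scales with the squared pixel spacing", {
  m <- matrix(0, 20, 20); m[1:100] <- 1
  expect_equal(plaque_area(matrix(0, 3, 3)), 0)
  expect_equal(plaque_area(m), 100)
  expect_equal(plaque_area(m, 0.1), 1.0)
  expect_error(plaque_area(m, 0), "pixel_spacing")
})

test_that("Bland-Altman bias and limits of agreement", {
  ba <- bland_altman(c(5, 7, 9), c(5, 7, 9))
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa), c(0, 0))

  ba <- bland_altman(c(5, 7, 9), c(7, 9, 11))     # constant offset 2
  expect_equal(ba$bias, 2)
  expect_equal(unname(ba$loa), c(2, 2))

  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$bias, 4 / 3)
  expect_equal(ba$abs_pct_error, c(0.2, 0.05, 0.1))
  expect_warning(bland_altman(c(0, 10), c(1, 11)), "zero ground-truth")
})

test_that("paired t-test with Bonferroni correction", {
  a <- c(0.8, 0.7, 0.9, 0.6, 0.75)
  expect_equal(paired_ttest_bonferroni(a, a, 7), 1)

  b <- a + c(1, 1, 1, 1, -1)
  # closed-form paired t on the differences
  d <- b - a
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p <- 2 * pt(-abs(tstat), length(d) - 1)
  expect_equal(paired_ttest_bonferroni(b, a, 1), p, tolerance = 1e-12)
  expect_equal(paired_ttest_bonferroni(b, a, 4), min(1, 4 * p),
               tolerance = 1e-12)
  expect_warning(out <- paired_ttest_bonferroni(a + 1, a, 1), "degenerate")
  expect_true(is.na(out))
  expect_error(paired_ttest_bonferroni(1, 1, 1), "n >= 2")
})

test_that("per-image records carry the empty-mask conventions", {
  s <- generate_phantom(tiny_phantom_params(seed = 21))
  rec <- evaluate_masks(s$plaque_mask, s$plaque_mask)
  expect_equal(rec$dice, 1); expect_equal(rec$mhd, 0)
  expect_equal(rec$delta_tpa, 0)

  z <- s$plaque_mask * 0
  expect_warning(rec <- evaluate_masks(s$plaque_mask, z), "MHD undefined")
  expect_equal(rec$dice, 0)
  expect_true(is.na(rec$mhd))
  rec <- evaluate_masks(z, z)
  expect_equal(rec$dice, 1); expect_equal(rec$acc, 1)
})
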