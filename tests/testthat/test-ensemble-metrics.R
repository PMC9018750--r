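test_that("orientation transforms have the right group structure", {
  withr::with_seed(1, a <- array(runif(4^3), c(4, 4, 4)))
  expect_identical(applyOrientation(a, "R0"), a)
  r <- a
  for (k in 1:4) r <- applyOrientation(r, "R1")
  expect_identical(r, a)                                   # rotation order 4
  expect_identical(applyOrientation(applyOrientation(a, "R2"), "R2"), a)
  expect_identical(applyOrientation(applyOrientation(a, "R3"), "R3"), a)
  for (o in c("R1", "R2", "R3", "R4"))
    expect_identical(applyOrientation(applyOrientation(a, o), o,
                                      inverse = TRUE), a)
  expect_error(applyOrientation(array(0, c(2, 3, 2)), "R1"), "cubic")
  v <- orientationVariants(a)
  expect_identical(v$variants$R0, a)
  expect_identical(v$invert(v$variants$R4, "R4"), a)
})

test_that("ensemble voting: degeneracy, threshold exclusion, averaging", {
  withr::with_seed(3, base <- array(runif(6^3), c(6, 6, 6)))
  sets <- replicate(15, base, simplify = FALSE)
  v <- ensembleVote(sets)
  expect_equal(v$probability, base)                        # mean of identical
  expect_equal(v$normalizer, 15L)
  ## a prediction with Dice 0.5 against the reference is excluded
  ref <- array(0, c(4, 4, 4)); ref[1:2, 1, 1] <- 1
  bad <- array(0, c(4, 4, 4)); bad[2:3, 1, 1] <- 1         # Dice = 0.5
  v2 <- ensembleVote(list(ref, bad, ref))
  expect_false(v2$included[2])
  expect_equal(v2$normalizer, 2L)
  expect_equal(v2$probability, ref)
  ## two included sets disagreeing at one voxel (0.8 vs 0.4) vote to 0.6
  R <- array(FALSE, c(4, 4, 4)); R[1:2, , ] <- TRUE
  a <- array(0, c(4, 4, 4)); a[R] <- 1; a[1, 1, 1] <- 0.8
  b <- array(0, c(4, 4, 4)); b[R] <- 1; b[1, 1, 1] <- 0.4
  v3 <- ensembleVote(list(a, b))     # Dice(R, R minus one voxel) > 0.8
  expect_true(all(v3$included))
  expect_equal(v3$probability[1, 1, 1], 0.6)
  ## permutation invariance up to the reference slot
  v4 <- ensembleVote(list(ref, ref, bad))
  expect_equal(v4$probability, v2$probability)
})

test_that("confusion metrics match brute-force voxel counting", {
  ## closed-form cases
  g <- array(FALSE, c(3, 3, 3)); g[1:2, 1, 1] <- TRUE
  expect_equal(confusionMetrics(g, g)$Dice, 1)
  expect_equal(confusionMetrics(g, g)$Sensitivity, 1)
  d <- array(FALSE, c(3, 3, 3)); d[3, 3, 3] <- TRUE
  expect_equal(confusionMetrics(g, d)$Dice, 0)
  ## |GT| = |PD| = 10 with overlap 5
  g2 <- array(FALSE, c(5, 5, 2)); g2[1:10] <- TRUE
  p2 <- array(FALSE, c(5, 5, 2)); p2[6:15] <- TRUE
  cm <- confusionMetrics(g2, p2)
  expect_equal(cm$Dice, 0.5); expect_equal(cm$Sensitivity, 0.5)
  expect_equal(cm$Precision, 0.5)
  ## empty/empty conventions
  e <- array(FALSE, c(2, 2, 2))
  cme <- confusionMetrics(e, e)
  expect_equal(cme$Dice, 1)
  expect_true(is.na(cme$Sensitivity))
  ## oracle equivalence: plain voxel loop on random volumes
  for (seed in 1:100) {
    withr::with_seed(seed, {
      d3 <- sample(4:10, 3, replace = TRUE)
      gt <- array(runif(prod(d3)) < 0.4, d3)
      pd <- array(runif(prod(d3)) < 0.4, d3)
    })
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(gt)) {
      if (gt[i] && pd[i]) tp <- tp + 1L
      else if (!gt[i] && pd[i]) fp <- fp + 1L
      else if (gt[i] && !pd[i]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    cm <- confusionMetrics(gt, pd)
    expect_identical(c(cm$TP, cm$FP, cm$FN, cm$TN), c(tp, fp, fn, tn))
    if (tp + fp + fn > 0)
      expect_equal(cm$Dice, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-15)
    if (tp + fn > 0)
      expect_equal(cm$Sensitivity, tp / (tp + fn), tolerance = 1e-15)
    if (tn + fp > 0)
      expect_equal(cm$Specificity, tn / (tn + fp), tolerance = 1e-15)
    if (tp + fp > 0)
      expect_equal(cm$Precision, tp / (tp + fp), tolerance = 1e-15)
  }
})

test_that("HD95 matches brute-force all-pairs surface distances", {
  b <- array(FALSE, c(14, 14, 14)); b[3:12, 3:12, 3:12] <- TRUE
  expect_equal(hd95(b, b), 0)
  sh <- array(FALSE, c(14, 14, 14)); sh[4:13, 3:12, 3:12] <- TRUE
  expect_equal(hd95(b, sh), 1.0, tolerance = 1e-12)     # unit shift
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- array(FALSE, c(9, 9, 9)); B <- array(FALSE, c(9, 9, 9))
      A[sample(729, 60)] <- TRUE
      B[sample(729, 60)] <- TRUE
    })
    expect_equal(hd95(A, B, spacing = c(1, 1.3, 0.8)),
                 hd95BruteForce(A, B, spacing = c(1, 1.3, 0.8)),
                 tolerance = 1e-10)
  }
  ## HD95 never exceeds the full Hausdorff distance
  maxHD <- function(A, B) {
    sa <- which(A, arr.ind = TRUE); sb <- which(B, arr.ind = TRUE)
    D <- sqrt(outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb))
    max(max(apply(D, 1, min)), max(apply(D, 2, min)))
  }
  A <- array(FALSE, c(7, 7, 7)); A[2:3, 2:3, 2:3] <- TRUE
  B <- array(FALSE, c(7, 7, 7)); B[5:6, 4:6, 2:6] <- TRUE
  expect_lte(hd95(A, B), maxHD(A, B) + 1e-12)
  expect_error(hd95(A, array(FALSE, c(7, 7, 7))), "empty")
})

test_that("Dice + cross-entropy loss has the stated closed forms", {
  d <- c(4, 4, 4); n <- prod(d); k <- 5
  gt <- array(0, d); gt[1:k] <- 1
  expect_lt(diceCELoss(gt, gt), 1e-5)                 # perfect prediction
  half <- array(0.5, d)
  expected <- (1 - k / (k + 0.5 * n)) + k * log(2)
  expect_equal(diceCELoss(gt, half), expected, tolerance = 1e-12)
  withr::with_seed(7, pd <- array(runif(n), d))
  expect_gte(diceCELoss(gt, pd), 0)
})
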