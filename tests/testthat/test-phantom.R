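test_that("phantom labels are nested and the brain fraction is in range", {
  ph <- testPhantom(dim = c(40, 40, 30), seed = 11)
  lab <- volumeData(ph$labels)
  expect_true(all(unique(as.vector(lab)) %in% c(0, 1, 2, 4)))
  wt <- labelRegion(lab, "WT"); tc <- labelRegion(lab, "TC")
  et <- labelRegion(lab, "ET")
  expect_true(all(wt[tc]))              # TC inside WT
  expect_true(all(tc[et]))              # ET inside TC
  expect_gt(sum(et), 0)
  expect_true(all(ph$brainMask[wt]))    # tumor inside the brain
  frac <- mean(ph$brainMask)
  expect_gt(frac, 0.12); expect_lt(frac, 0.20)
  ## full-size default spec keeps the same fraction (resolution-free)
  expect_equal(phantomSpec()$dim, c(240L, 240L, 155L))
})

test_that("phantoms are deterministic under the seed and signal is present", {
  a <- generatePhantom(phantomSpec(seed = 5, dim = c(24, 24, 18)))
  b <- generatePhantom(phantomSpec(seed = 5, dim = c(24, 24, 18)))
  expect_identical(volumeData(a$modalities$FLAIR),
                   volumeData(b$modalities$FLAIR))
  expect_identical(volumeData(a$labels), volumeData(b$labels))
  c0 <- generatePhantom(phantomSpec(seed = 6, dim = c(24, 24, 18)))
  expect_false(identical(volumeData(a$modalities$FLAIR),
                         volumeData(c0$modalities$FLAIR)))
  ## FLAIR hyperintense on WT, T1CE hyperintense on ET (driving densities)
  wt <- labelRegion(a$labels, "WT"); et <- labelRegion(a$labels, "ET")
  brainOnly <- a$brainMask & !wt
  fl <- volumeData(a$modalities$FLAIR)
  t1ce <- volumeData(a$modalities$T1CE)
  expect_gt(mean(fl[wt]) - mean(fl[brainOnly]),
            3 * a$spec$noiseSD)
  expect_gt(mean(t1ce[et]) - mean(t1ce[brainOnly]), 3 * a$spec$noiseSD)
  expect_error(generatePhantom(phantomSpec(wtFrac = 1.2)), "infeasible")
})

test_that("oracle predictor reproduces labels and respects orientation", {
  ph <- testPhantom(dim = c(24, 24, 18), seed = 4)
  lab <- array(0, c(8, 8, 8)); lab[2:5, 3:6, 2:4] <- 1
  cubes <- list(lab, lab * 0, lab * 0)
  pred <- makeOraclePredictor(cubes, noiseSD = 0)
  out <- pred(NULL, "R0")
  expect_identical(out[[1]], lab)
  ## oriented output equals the oriented labels
  out1 <- pred(NULL, "R1")
  expect_identical(out1[[1]], applyOrientation(lab, "R1"))
  ## noisy probabilities stay in [0,1] and threshold back to the labels
  predN <- makeOraclePredictor(cubes, noiseSD = 0.1, seed = 3)
  pn <- predN(NULL, "R0")[[1]]
  expect_true(min(pn) >= 0 && max(pn) <= 1)
  expect_equal(pn >= 0.5, lab == 1)
})

test_that("phantom round-trips through the BraTS NIfTI layout", {
  ph <- testPhantom(dim = c(24, 24, 18), seed = 4)
  dir <- tempfile("subj")
  writeBraTSSubject(ph, dir, id = "SYNTH00004")
  back <- readBraTSSubject(dir)
  expect_equal(volumeData(back$modalities$FLAIR),
               volumeData(ph$modalities$FLAIR), tolerance = 1e-6)
  expect_equal(volumeData(back$labels), volumeData(ph$labels))
  unlink(dir, recursive = TRUE)
})
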