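test_that("CEHE is a monotone map to [0,1] with zero background", {
  d <- c(6, 6, 4)
  mask <- array(TRUE, d); mask[1, , ] <- FALSE
  v <- array(0, d)
  v[mask] <- seq_len(sum(mask))          # strictly increasing inside mask
  out <- normalizeIntensity(VoxelVolume(v), mask)@data
  expect_true(all(out[!mask] == 0))
  expect_true(all(out[mask] >= 0 & out[mask] <= 1))
  expect_true(all(diff(out[mask][order(v[mask])]) > 0))   # strict order kept
})

test_that("CEHE two-level image maps levels to 0.5 and 1.0", {
  d <- c(4, 4, 4)
  mask <- array(TRUE, d)
  v <- array(2, d); v[1:2, , ] <- 1     # half at 1, half at 2
  out <- normalizeIntensity(VoxelVolume(v), mask)@data
  expect_equal(unique(as.vector(out[v == 1])), 0.5)
  expect_equal(unique(as.vector(out[v == 2])), 1.0)
})

test_that("CEHE constant image degenerates to 0.5 in the mask", {
  mask <- array(TRUE, c(3, 3, 3))
  out <- normalizeIntensity(VoxelVolume(array(7, c(3, 3, 3))), mask)@data
  expect_true(all(out == 0.5))
})

test_that("Phase I density is exp(gamma * CEHE) sampled at vertex cells", {
  mesh <- buildTetMesh(array(TRUE, c(2, 2, 2)))
  zero <- VoxelVolume(array(0, c(2, 2, 2)), kind = "cehe")
  expect_equal(densityValues(densityPhase1(zero, mesh, gamma = 1.5)),
               rep(1, nVertices(mesh)))
  one <- VoxelVolume(array(1, c(2, 2, 2)), kind = "cehe")
  expect_equal(densityValues(densityPhase1(one, mesh, gamma = 2)),
               rep(exp(2), nVertices(mesh)), tolerance = 1e-12)
  expect_silent(densityPhase1(one, mesh, gamma = 1.75))
  expect_warning(densityPhase1(one, mesh, gamma = 2.5), "gamma")
})

test_that("box blur is an exact m^3 mean with replicate padding", {
  withr::with_seed(5, x <- array(runif(7 * 6 * 5), c(7, 6, 5)))
  sm <- boxBlur3(x, 3)
  ## direct mean at an interior voxel
  expect_equal(sm[4, 3, 3], mean(x[3:5, 2:4, 2:4]), tolerance = 1e-12)
  ## replicate padding at a corner: indices clamp to the border
  ii <- pmin(pmax(0:2, 1), 7); jj <- pmin(pmax(0:2, 1), 6)
  kk <- pmin(pmax(0:2, 1), 5)
  expect_equal(sm[1, 1, 1], mean(x[ii, jj, kk]), tolerance = 1e-12)
  expect_true(all(sm >= min(x) & sm <= max(x)))
  expect_error(boxBlur3(x, 4), "odd")
})

test_that("Phase II density: step field, blur, and degenerate cases", {
  d <- c(11, 11, 11)
  mesh <- buildTetMesh(array(TRUE, d))
  cehe <- VoxelVolume(array(0, d), kind = "cehe")
  ## empty region -> density identically 1
  empty <- array(FALSE, d)
  expect_equal(densityValues(densityPhase2(cehe, empty, mesh, 1, 5)),
               rep(1, nVertices(mesh)))
  ## single voxel at CEHE 1 inside T, all neighbors outside, m = 5:
  ## blurred center value (e + 124)/125
  cv <- array(0, d); cv[6, 6, 6] <- 1
  reg <- array(FALSE, d); reg[6, 6, 6] <- TRUE
  rho <- densityPhase2(VoxelVolume(cv, kind = "cehe"), reg, mesh, 1, 5)
  vid <- which(apply(mesh@vertexVoxel, 1, function(r) all(r == 6)))
  expect_equal(densityValues(rho)[vid], (exp(1) + 124) / 125,
               tolerance = 1e-12)
  ## deep interior of a large constant region: blur leaves exp(gamma*c)
  cv2 <- VoxelVolume(array(0.3, d), kind = "cehe")
  rho2 <- densityPhase2(cv2, array(TRUE, d), mesh, 1.5, 5)
  expect_equal(densityValues(rho2), rep(exp(1.5 * 0.3), nVertices(mesh)),
               tolerance = 1e-12)
  expect_error(densityPhase2(cehe, empty, mesh, 1, 4), "odd")
})

test_that("Phase II with whole-grid region and m = 1 reduces to Phase I", {
  ph <- testPhantom(dim = c(24, 24, 18), seed = 3)
  sub <- cubeOMT:::.asSubject(ph)
  mesh <- buildTetMesh(sub$brainMask)
  r1 <- densityPhase1(sub$cehe$FLAIR, mesh, gamma = 1.5)
  r2 <- densityPhase2(sub$cehe$FLAIR, array(TRUE, dim(sub$brainMask)),
                      mesh, gamma = 1.5, m = 1)
  expect_equal(densityValues(r2), densityValues(r1), tolerance = 1e-12)
})

test_that("simplex measures satisfy the conservation identities", {
  ## single unit-volume tet, rho == 1: m_rho = 1/4 at each vertex
  mesh <- unitTetMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0, 0, 6)))
  meas <- simplexMeasures(mesh, uniformDensity(mesh))
  expect_equal(meas$tetVolume, 1, tolerance = 1e-12)
  expect_equal(meas$vertexVolumeMeasure, rep(0.25, 4), tolerance = 1e-12)
  ## face density is the corner mean
  rho <- new("DensityField", values = c(1, 2, 3, 10), gamma = NA_real_)
  meas2 <- simplexMeasures(mesh, rho)
  f <- which(apply(boundaryFaces(mesh), 1, setequal, c(1, 2, 3)))
  expect_equal(meas2$faceDensity[f], 2)
})

test_that("measure conservation holds to 1e-12 on random meshes and densities", {
  for (seed in 1:20) {
    mesh <- buildTetMesh(randomBlobMask(dim = c(10, 9, 8), seed = seed))
    rho <- randomDensity(mesh, seed = 100 + seed)
    meas <- simplexMeasures(mesh, rho)
    expect_equal(sum(meas$vertexVolumeMeasure), sum(meas$tetMass),
                 tolerance = 1e-12)
    expect_equal(sum(meas$vertexAreaMeasure), sum(meas$faceMass),
                 tolerance = 1e-12)
  }
})
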