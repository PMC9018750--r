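# A small real map fixture: the normalized 5^3 cube mapped to itself.
tinyMapFixture <- function() {
  if (is.null(.fix$tinyMap)) {
    mesh <- buildTetMesh(array(TRUE, c(5, 5, 5)))
    mesh <- normalizeComplex(mesh, uniformDensity(mesh))
    rho <- uniformDensity(mesh)
    gstar <- cubeBoundaryAOMT(mesh, rho, refRes = 9, maxIters = 150)
    v <- volumeOMT(mesh, rho, gstar, p = 3)
    .fix$tinyMap <- list(mesh = mesh, map = v$map,
                         assignment = cubeAssignment(v$map, mesh, 16))
  }
  .fix$tinyMap
}

test_that("rasterization samples constants exactly and keeps label alphabets", {
  fx <- tinyMapFixture()
  src <- array(3.25, c(5, 5, 5))
  cube <- rasterizeToCube(fx$map, fx$mesh, src, mode = "grayscale",
                          assignment = fx$assignment)
  expect_true(all(volumeData(cube)[cube@covered] == 3.25))
  expect_true(all(volumeData(cube)[!cube@covered] == 0))
  lab <- array(0, c(5, 5, 5)); lab[3:5, , ] <- 1
  lcube <- rasterizeToCube(fx$map, fx$mesh, lab, mode = "label",
                           assignment = fx$assignment)
  expect_true(all(volumeData(lcube) %in% c(0, 1)))
})

test_that("pullback averages cube probabilities per brain voxel", {
  fx <- tinyMapFixture()
  mask <- array(TRUE, c(5, 5, 5))
  K <- fx$assignment$cubeDim
  ## constant probability pulls back to the constant
  const <- array(0.37, c(K, K, K))
  pb <- pullbackProbabilities(fx$assignment, const, mask)
  inBrain <- pb$counts > 0
  expect_equal(range(pb$probs[inBrain]), c(0.37, 0.37), tolerance = 1e-12)
  ## hand-built assignment: one voxel receiving 0.2 and 0.6 -> 0.4
  asg <- list(cubeDim = 2L,
              covered = array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2)),
              cellLinear = c(1, 1),
              preimageIndex = rbind(c(0.2, 0.2, 0.2), c(0.7, 0.2, 0.2)),
              gridDim = c(2L, 1L, 1L))
  probs <- array(c(0.2, 0.6, rep(0, 6)), c(2, 2, 2))
  m2 <- array(TRUE, c(2, 1, 1))
  pb2 <- pullbackProbabilities(asg, probs, m2)
  expect_equal(pb2$probs[1, 1, 1], 0.4)
  ## voxel 2 has n(j) = 0: takes the nearest preimage's value (0.6)
  expect_equal(pb2$probs[2, 1, 1], 0.6)
  expect_equal(pb2$fallbackVoxels, 1L)
})

test_that("label decision follows the hierarchical rule", {
  m <- array(TRUE, c(2, 2, 1))
  p1 <- array(c(0.3, 0.9, 0.9, 0.9), c(2, 2, 1))
  p2 <- array(c(0.9, 0.3, 0.8, 0.8), c(2, 2, 1))
  p3 <- array(c(0.9, 0.9, 0.2, 0.7), c(2, 2, 1))
  lab <- volumeData(decideLabels(p1, p2, p3, m))
  expect_equal(as.vector(lab), c(0, 2, 1, 4))
  ## voxels outside the domain stay 0 whatever the probabilities
  m[1, 2, 1] <- FALSE
  expect_equal(volumeData(decideLabels(p1, p2, p3, m))[1, 2, 1], 0)
})

test_that("enlarged ratio is the quotient of WT fractions", {
  mask <- array(TRUE, c(10, 10, 1))
  lab <- array(0, c(10, 10, 1)); lab[1:10, 1, 1] <- 2      # 10% WT
  cube <- array(0, c(10, 10, 10)); cube[, , 1] <- 1         # 10% of cube
  expect_equal(enlargedRatio(lab, CubeGrid(cube, "label"), mask), 1)
  cube[, , 2] <- 1                                          # 20% of cube
  expect_equal(enlargedRatio(lab, CubeGrid(cube, "label"), mask), 2)
  expect_error(enlargedRatio(array(0, dim(lab)),
                             CubeGrid(cube, "label"), mask), "WT")
})
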