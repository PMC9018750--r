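test_that("a single voxel meshes to the 6-tet Kuhn cube with a closed boundary", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  mesh <- buildTetMesh(m)
  expect_equal(nVertices(mesh), 8L)
  expect_equal(nTets(mesh), 6L)
  expect_equal(nrow(boundaryFaces(mesh)), 12L)
  ## Euler characteristic V - E + F = 8 - 18 + 12 = 2 (checked at build)
  expect_equal(sum(tetVolumes(vertices(mesh), tets(mesh))), 1,
               tolerance = 1e-12)
  expect_error(buildTetMesh(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("a solid 2x2x2 block gives 48 positively oriented tets of total volume 8", {
  mesh <- buildTetMesh(array(TRUE, c(2, 2, 2)))
  vol <- tetVolumes(vertices(mesh), tets(mesh))
  expect_equal(nTets(mesh), 48L)
  expect_true(all(vol > 0))
  expect_equal(sum(vol), 8, tolerance = 1e-12)
})

test_that("boundary surface is closed and outward-oriented for random masks", {
  for (seed in 1:4) {
    mesh <- buildTetMesh(randomBlobMask(seed = seed))
    v <- vertices(mesh); bf <- boundaryFaces(mesh)
    ## divergence-theorem volume from the boundary equals the tet-sum volume
    nrm <- cubeOMT:::triangleNormals(v, bf)
    cent <- (v[bf[, 1], ] + v[bf[, 2], ] + v[bf[, 3], ]) / 3
    divVol <- sum(rowSums(cent * nrm)) / 6
    expect_equal(divVol, sum(tetVolumes(v, tets(mesh))),
                 tolerance = 1e-9)
  }
})

test_that("mask cleanup keeps one component and fills cavities", {
  m <- array(FALSE, c(9, 9, 9))
  m[2:6, 2:6, 2:6] <- TRUE
  m[4, 4, 4] <- FALSE           # interior cavity
  m[9, 9, 9] <- TRUE            # disconnected speck (not 26-adjacent)
  cl <- cleanupMask(m)
  expect_true(cl[4, 4, 4])      # cavity filled
  expect_false(cl[9, 9, 9])     # speck dropped
})

test_that("normalizeComplex centers mass at the origin, unit mass, idempotent", {
  mesh <- buildTetMesh(array(TRUE, c(3, 2, 2)))
  rho <- randomDensity(mesh, seed = 3)
  nm <- normalizeComplex(mesh, rho)
  meas <- simplexMeasures(nm, rho)
  expect_equal(sum(meas$tetMass), 1, tolerance = 1e-10)
  cg <- colSums(meas$vertexVolumeMeasure * vertices(nm))
  expect_lt(max(abs(cg)), 1e-10)
  nm2 <- normalizeComplex(nm, rho)
  expect_equal(vertices(nm2), vertices(nm), tolerance = 1e-12)
  ## commutes with rigid translation of the input
  shifted <- mesh
  shifted@vertices <- sweep(mesh@vertices, 2, c(5, -2, 7), "+")
  expect_equal(vertices(normalizeComplex(shifted, rho)), vertices(nm),
               tolerance = 1e-10)
})

test_that("dilateMask implements a Euclidean ball", {
  r <- array(FALSE, c(9, 9, 9)); r[5, 5, 5] <- TRUE
  expect_identical(dilateMask(r, 0), r)
  expect_equal(sum(dilateMask(r, 1)), 7)   # center + 6 face neighbors
  off <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  expect_equal(sum(dilateMask(r, 4)), sum(rowSums(off^2) <= 16))
  expect_true(all(dilateMask(r, 3)[r]))    # output contains input
  expect_error(dilateMask(r, -1), "non-negative")
})

test_that("refineMesh subdivides 1:8 in the region and conserves volume", {
  mesh <- buildTetMesh(array(TRUE, c(2, 2, 2)))
  expect_identical(tets(refineMesh(mesh, array(FALSE, c(2, 2, 2)))),
                   tets(mesh))
  reg <- array(FALSE, c(2, 2, 2)); reg[1, 1, 1] <- TRUE
  ref <- refineMesh(mesh, reg)
  expect_gt(nTets(ref), nTets(mesh))
  expect_equal(sum(tetVolumes(vertices(ref), tets(ref))), 8,
               tolerance = 1e-9)
  ## existing vertices never move
  expect_equal(vertices(ref)[seq_len(nVertices(mesh)), ], vertices(mesh))
})

test_that("red refinement of a single tet gives 8 children of volume |tau|/8", {
  mesh <- unitTetMesh()
  ref <- refineMesh(mesh, array(TRUE, c(1, 1, 1)))
  vol <- tetVolumes(vertices(ref), tets(ref))
  expect_equal(nTets(ref), 8L)
  expect_equal(vol, rep(1 / 6 / 8, 8), tolerance = 1e-12)
})

test_that("meshIndexCoords inverts the normalization affine", {
  mesh <- buildTetMesh(randomBlobMask(seed = 9), spacing = c(1, 1.2, 0.8))
  idx0 <- meshIndexCoords(mesh)
  nm <- normalizeComplex(mesh, uniformDensity(mesh))
  expect_equal(meshIndexCoords(nm), idx0, tolerance = 1e-9)
})
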