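test_that("mass Laplacian entries match the literal formula on a regular tet", {
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))   # unit edge regular tet
  mesh <- unitTetMesh(verts)
  rho <- uniformDensity(mesh)
  L <- massLaplacian(verts, mesh, rho)     # f = identity
  vol <- tetVolumes(verts, matrix(1:4, 1))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(L[i, j],
                 massWeightLiteral(verts, 1:4, i, j, 1, vol),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(L - Matrix::t(L))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
})

test_that("mass Laplacian oracle also holds on an irregular tet and general f", {
  withr::with_seed(8, {
    verts <- matrix(rnorm(12), 4, 3)
    f <- matrix(rnorm(12), 4, 3)
  })
  if (tetVolumes(verts, matrix(1:4, 1)) < 0) verts <- verts[c(1, 2, 4, 3), ]
  mesh <- unitTetMesh(verts)
  rho <- new("DensityField", values = c(0.5, 1, 2, 4), gamma = NA_real_)
  L <- massLaplacian(f, mesh, rho)
  vol <- abs(tetVolumes(verts, matrix(1:4, 1)))
  rhoTau <- mean(rho@values)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(L[i, j], massWeightLiteral(f, 1:4, i, j, rhoTau, vol),
                 tolerance = 1e-10)
})

test_that("homotopy boundary interpolates linearly between identity and g*", {
  mesh <- buildTetMesh(array(TRUE, c(3, 3, 3)))
  mesh <- normalizeComplex(mesh, uniformDensity(mesh))
  B <- boundaryVertexIds(mesh)
  withr::with_seed(2, gc <- matrix(runif(length(B) * 3, -0.5, 0.5),
                                   ncol = 3))
  gstar <- new("PLMap", coords = gc, vertexIds = B, target = "cubeBoundary")
  vb <- vertices(mesh)[B, ]
  expect_equal(mapCoords(homotopyBoundary(mesh, gstar, 0)), vb)
  expect_equal(mapCoords(homotopyBoundary(mesh, gstar, 1)), gc)
  expect_equal(mapCoords(homotopyBoundary(mesh, gstar, 0.5)),
               (vb + gc) / 2, tolerance = 1e-15)
  expect_error(homotopyBoundary(mesh, gstar, 1.2), "zeta")
})

test_that("transport cost is zero at the identity and ||t||^2 under translation", {
  mesh <- buildTetMesh(randomBlobMask(seed = 5))
  rho <- randomDensity(mesh, seed = 5)
  mesh <- normalizeComplex(mesh, rho)       # mass one
  expect_equal(transportCost(vertices(mesh), mesh, rho), 0)
  t0 <- c(0.3, -0.2, 0.15)
  f <- sweep(vertices(mesh), 2, t0, "+")
  expect_equal(transportCost(f, mesh, rho), sum(t0^2), tolerance = 1e-12)
  expect_gte(transportCost(f, mesh, rho), 0)
})

test_that("distortion diagnostics: exact preservation, scaling law, reflection", {
  mesh <- buildTetMesh(array(TRUE, c(2, 3, 2)))
  rho <- uniformDensity(mesh)
  d0 <- distortionDiagnostics(vertices(mesh), mesh, rho)
  expect_equal(d0$massDistortion, 0, tolerance = 1e-12)
  expect_equal(d0$localRatio, rep(1, nVertices(mesh)), tolerance = 1e-12)
  expect_equal(d0$foldingCount, 0)
  s <- 1.7
  ds <- distortionDiagnostics(vertices(mesh) * s, mesh, rho)
  expect_equal(ds$localRatio, rep(1 / s^3, nVertices(mesh)),
               tolerance = 1e-12)
  refl <- vertices(mesh); refl[, 1] <- -refl[, 1]
  expect_equal(distortionDiagnostics(refl, mesh, rho)$foldingCount,
               nTets(mesh))
})

test_that("V-OMT pins the boundary to g* exactly and meets the residual contract", {
  mesh <- buildTetMesh(array(TRUE, c(5, 5, 5)))
  mesh <- normalizeComplex(mesh, uniformDensity(mesh))
  rho <- uniformDensity(mesh)
  gstar <- cubeBoundaryAOMT(mesh, rho, refRes = 9, maxIters = 150)
  res <- volumeOMT(mesh, rho, gstar, p = 3)
  B <- boundaryVertexIds(mesh)
  expect_identical(mapCoords(res$map)[B, ], mapCoords(gstar))
  expect_equal(length(res$diagnostics$trace), 3L)
  expect_error(volumeOMT(mesh, rho, gstar, p = 0), "at least 1")
})
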