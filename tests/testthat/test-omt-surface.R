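test_that("stretch Laplacian matches the hand value on two equilateral faces", {
  s3 <- sqrt(3) / 2
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, s3, 0), c(0.5, -s3, 0))
  faces <- rbind(c(1L, 2L, 3L), c(2L, 1L, 4L))
  surf <- list(vertices = verts, faces = faces, rho = rep(1, 4),
               meshIds = 1:4)
  L <- stretchLaplacian(verts, surf)      # g = id so sigma == 1
  ## w_12 = -(cot 60 + cot 60)/2 = -1/sqrt(3)
  expect_equal(L[1, 2], -1 / sqrt(3), tolerance = 1e-12)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
  expect_lt(max(abs(L - Matrix::t(L))), 1e-12)
  ## w is linear in 1/sigma: doubling rho(alpha)|alpha| at fixed g doubles
  ## sigma and therefore halves the weights
  L2 <- stretchLaplacian(verts, surf,
                         faceMass = 2 * cubeOMT:::.surfaceFaceMass(surf))
  expect_equal(L2[1, 2], L[1, 2] / 2, tolerance = 1e-12)
  expect_error(stretchLaplacian(verts * c(1, 1, 0) * 0, surf), "collapsed")
})

test_that("spherical A-OMT projects to the unit sphere and covers 4pi", {
  surf <- referenceCubeBoundary(9)
  h <- sphericalAOMT(surf, maxIters = 150)
  expect_equal(rowSums(h$coords^2), rep(1, nrow(h$coords)),
               tolerance = 1e-12)
  sa <- cubeOMT:::sphericalTriangleAreas(h$coords, surf$faces)
  expect_equal(sum(sa), 4 * pi, tolerance = 0.01)
  expect_equal(h$foldedFaces, 0)
  ## energy is non-increasing across accepted iterations
  expect_true(all(diff(h$energyTrace) <= 1e-12))
})

test_that("uniform density on a round sphere keeps stretch factors near 1", {
  surf <- referenceCubeBoundary(9)
  surf$vertices <- surf$vertices / sqrt(rowSums(surf$vertices^2))
  h <- sphericalAOMT(surf, maxIters = 100)
  expect_gt(median(h$stretch), 0.95)
  expect_lt(median(h$stretch), 1.05)
})

test_that("reference map inversion is exact at vertices and round trips", {
  href <- referenceSphereMap(9)
  V <- href$surface$vertices
  ## vertex identity
  got <- invertReferenceSphereMap(href, href$coords)
  expect_equal(got, V, tolerance = 1e-9)
  ## random barycentric points round trip through the composition
  withr::with_seed(4, {
    fid <- sample(nrow(href$surface$faces), 25)
    b <- matrix(runif(75), 25, 3); b <- b / rowSums(b)
  })
  f <- href$surface$faces[fid, , drop = FALSE]
  pts <- b[, 1] * V[f[, 1], ] + b[, 2] * V[f[, 2], ] + b[, 3] * V[f[, 3], ]
  q <- b[, 1] * href$coords[f[, 1], ] + b[, 2] * href$coords[f[, 2], ] +
       b[, 3] * href$coords[f[, 3], ]
  q <- q / sqrt(rowSums(q^2))
  back <- invertReferenceSphereMap(href, q)
  expect_equal(back, pts, tolerance = 1e-8)
})

test_that("cube-boundary A-OMT lands on the cube and is near-identity on the cube itself", {
  mesh <- buildTetMesh(array(TRUE, c(8, 8, 8)))
  mesh <- normalizeComplex(mesh, uniformDensity(mesh))
  rho <- uniformDensity(mesh)
  g <- cubeBoundaryAOMT(mesh, rho, refRes = 17, maxIters = 250)
  mx <- apply(abs(mapCoords(g)), 1, max)
  expect_equal(mx, rep(0.5, nrow(mapCoords(g))), tolerance = 1e-12)
  vb <- vertices(mesh)[boundaryVertexIds(mesh), ]
  expect_lt(max(sqrt(rowSums((vb - mapCoords(g))^2))), 0.05)
  d <- attr(g, "diagnostics")
  expect_equal(d$cubeFoldedFaces, 0)
  expect_gt(median(d$areaRatio), 0.9)
  expect_lt(median(d$areaRatio), 1.1)
})
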