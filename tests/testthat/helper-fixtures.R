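# Shared fixtures, all generated in code.

# A single positively oriented unit tetrahedron as a TetMesh.
unitTetMesh <- function(verts = rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 1, 0), c(0, 0, 1))) {
  new("TetMesh", vertices = verts, tets = matrix(1:4, 1),
      boundaryFaces = rbind(c(2L, 3L, 4L), c(1L, 4L, 3L),
                            c(1L, 2L, 4L), c(1L, 3L, 2L)),
      boundaryVertexIds = 1:4, interiorVertexIds = integer(0),
      vertexVoxel = matrix(1L, 4, 3), gridDim = c(1L, 1L, 1L),
      spacing = c(1, 1, 1), center = c(0, 0, 0), scale = 1)
}

# Random blob mask: a perturbed ellipsoid, guaranteed nonempty.
randomBlobMask <- function(dim = c(12, 12, 10), seed = 1) {
  withr::with_seed(seed, {
    ax <- dim * runif(3, 0.25, 0.4)
    ctr <- dim / 2 + runif(3, -1, 1)
    x <- (seq_len(dim[1]) - 0.5 - ctr[1]) / ax[1]
    y <- (seq_len(dim[2]) - 0.5 - ctr[2]) / ax[2]
    z <- (seq_len(dim[3]) - 0.5 - ctr[3]) / ax[3]
    r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
    m <- r2 <= (1 + 0.2 * sin(3 * r2))^2
    if (!any(m)) m[dim[1] %/% 2, dim[2] %/% 2, dim[3] %/% 2] <- TRUE
    m
  })
}

# Random strictly positive density on a mesh.
randomDensity <- function(mesh, seed = 1) {
  withr::with_seed(seed,
    new("DensityField", values = exp(runif(nVertices(mesh), -1, 1)),
        gamma = NA_real_))
}

# Small test phantom + derived subject (CEHE etc.), cached per session.
.fix <- new.env(parent = emptyenv())

testPhantom <- function(dim = c(40, 40, 30), seed = 11) {
  key <- paste0("ph_", paste(dim, collapse = "x"), "_", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- generatePhantom(phantomSpec(seed = seed, dim = dim))
  .fix[[key]]
}

# The mid-size phantom used by the acceptance checks (about 100k tets),
# with the Phase I density map and homotopy solutions computed once.
acceptanceFixture <- function() {
  if (!is.null(.fix$acc)) return(.fix$acc)
  ph <- generatePhantom(phantomSpec(seed = 2021, dim = c(52, 52, 38)))
  subject <- cubeOMT:::.asSubject(ph)
  mesh <- buildTetMesh(subject$brainMask)
  rho <- densityPhase1(subject$cehe$FLAIR, mesh, gamma = 1)
  mesh <- normalizeComplex(mesh, rho)
  gstar <- cubeBoundaryAOMT(mesh, rho, refRes = 17)
  v11 <- volumeOMT(mesh, rho, gstar, p = 11)
  v1 <- volumeOMT(mesh, rho, gstar, p = 1)
  .fix$acc <- list(ph = ph, subject = subject, mesh = mesh, rho = rho,
                   gstar = gstar, v11 = v11, v1 = v1)
  .fix$acc
}

# Literal evaluation of the mass-weighted Laplacian entry: areas of the two
# image faces sharing the opposite edge, and the interior dihedral angle
# along that edge obtained by projecting out the edge direction.
massWeightLiteral <- function(f, tet, i, j, rhoTau, volTau) {
  others <- setdiff(tet, c(i, j))
  l <- others[1]; m <- others[2]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  triArea <- function(a, b, c)
    0.5 * sqrt(sum(cross3(f[b, ] - f[a, ], f[c, ] - f[a, ])^2))
  A1 <- triArea(i, l, m)
  A2 <- triArea(j, m, l)
  u <- f[m, ] - f[l, ]; u <- u / sqrt(sum(u^2))
  a <- (f[i, ] - f[l, ]) - sum((f[i, ] - f[l, ]) * u) * u
  b <- (f[j, ] - f[l, ]) - sum((f[j, ] - f[l, ]) * u) * u
  cosTheta <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  -(1 / 9) * A1 * A2 * cosTheta / (rhoTau * volTau)
}

# Brute-force HD95: all-pairs distances between 6-neighbor surface voxels.
hd95BruteForce <- function(A, B, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(idx)), function(r) {
      p <- idx[r, ]
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1) || any(q > dim(m)) || !m[q[1], q[2], q[3]])
          return(TRUE)
      }
      FALSE
    }, logical(1))
    sweep(idx[keep, , drop = FALSE], 2, spacing, "*")
  }
  sa <- surf(A); sb <- surf(B)
  D <- sqrt(pmax(outer(rowSums(sa^2), rowSums(sb^2), "+") -
                   2 * sa %*% t(sb), 0))
  max(quantile(apply(D, 1, min), 0.95, names = FALSE),
      quantile(apply(D, 2, min), 0.95, names = FALSE))
}

# Phase II + oracle validation on the acceptance phantom (cached).
acceptanceRoundTrip <- function() {
  if (!is.null(.fix$rt)) return(.fix$rt)
  acc <- acceptanceFixture()
  cfg <- pipelineConfig(cubeSize = 64, refRes = 17)
  p2 <- runPhase2(acc$subject, config = cfg, mode = "train")
  pred <- makeOraclePredictor(p2$labelCubes, noiseSD = 0)
  val <- runValidate(acc$subject, pred, config = cfg, ensemble = FALSE,
                     phase2 = p2)
  .fix$rt <- list(p2 = p2, val = val, cfg = cfg)
  .fix$rt
}
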