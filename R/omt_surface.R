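## Cubic area-measure-preserving OMT boundary map.
##
## The boundary map g* : bd(M) -> bd(C^3) is built by composition: a
## density-weighted spherical map h*_rho of the brain boundary and a uniform
## spherical map h*_1 of a reference triangulation of the cube boundary are
## both computed by projected gradient descent on the area-weighted stretch
## energy, and g* = (h*_1)^{-1} o h*_rho. The sphere map is fixed up to
## rotation; the gauge is set by aligning the rho-weighted principal axes of
## the boundary to the cube axes (skipped for near-isotropic shapes).

#' Extract the boundary surface of a tetrahedral mesh
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho optional \linkS4class{DensityField} on the mesh; its boundary
#'   restriction is carried along.
#' @return list with \code{vertices} (compact b x 3), \code{faces}
#'   (outward-oriented triangles in compact indices), \code{rho} (per-vertex
#'   density), and \code{meshIds} (compact index -> mesh vertex id).
#' @export
boundarySurface <- function(mesh, rho = NULL) {
  ids <- mesh@boundaryVertexIds
  lut <- integer(nVertices(mesh))
  lut[ids] <- seq_along(ids)
  faces <- matrix(lut[mesh@boundaryFaces], ncol = 3)
  vals <- if (is.null(rho)) rep(1, length(ids)) else rho@values[ids]
  list(vertices = mesh@vertices[ids, , drop = FALSE], faces = faces,
       rho = vals, meshIds = ids)
}

#' Triangulated boundary of the reference cube
#'
#' A \code{res x res} vertex grid on each of the 6 faces of
#' \eqn{[-1/2,1/2]^3}, shared edges and corners merged, each quad split into
#' two outward-oriented triangles.
#'
#' @param res vertices per face edge (default 33).
#' @return surface list as in [boundarySurface()] (uniform \code{rho}).
#' @export
referenceCubeBoundary <- function(res = 33L) {
  res <- as.integer(res)
  stopifnot(res >= 2L)
  g <- seq(0L, res - 1L)
  lat <- list()
  for (axis in 1:3) for (side in c(0L, res - 1L)) {
    uv <- expand.grid(u = g, v = g)
    lat[[length(lat) + 1]] <- switch(axis,
      cbind(side, uv$u, uv$v),
      cbind(uv$u, side, uv$v),
      cbind(uv$u, uv$v, side))
  }
  ## assemble lattice keys per face, merge duplicates
  allLat <- do.call(rbind, lat)
  key <- allLat[, 1] + res * (allLat[, 2] + res * allLat[, 3])
  ukey <- sort(unique(key))
  vid <- match(key, ukey)
  kx <- ukey %% res; ky <- (ukey %/% res) %% res; kz <- ukey %/% (res * res)
  verts <- unname(cbind(kx, ky, kz)) / (res - 1) - 0.5
  faces <- list()
  npf <- res * res
  for (f in 1:6) {
    off <- (f - 1) * npf
    id <- function(u, v) vid[off + (u + 1) + res * v]
    u <- rep(g[-res], res - 1)
    v <- rep(g[-res], each = res - 1)
    a <- id(u, v); b <- id(u + 1, v); c0 <- id(u + 1, v + 1); d <- id(u, v + 1)
    faces[[f]] <- rbind(cbind(a, b, c0), cbind(a, c0, d))
  }
  faces <- do.call(rbind, faces)
  ## enforce outward orientation
  nrm <- triangleNormals(verts, faces)
  cent <- (verts[faces[, 1], ] + verts[faces[, 2], ] + verts[faces[, 3], ]) / 3
  flip <- rowSums(nrm * cent) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  storage.mode(faces) <- "integer"
  list(vertices = verts, faces = faces, rho = rep(1, nrow(verts)),
       meshIds = seq_len(nrow(verts)))
}

# rho(alpha)|alpha| per surface face.
.surfaceFaceMass <- function(surface) {
  area <- triangleAreas(surface$vertices, surface$faces)
  den <- (surface$rho[surface$faces[, 1]] + surface$rho[surface$faces[, 2]] +
          surface$rho[surface$faces[, 3]]) / 3
  den * area
}

#' Area-weighted stretch Laplacian
#'
#' Off-diagonal weights are
#' \eqn{w_{ij} = -\frac12(\cot\theta_{ij}/\sigma_{g^{-1}}(\alpha_1) +
#' \cot\theta_{ji}/\sigma_{g^{-1}}(\alpha_2))} over the (at most two) faces
#' containing edge \eqn{[v_i,v_j]}, where \eqn{\theta} are the image-triangle
#' angles opposite the edge and
#' \eqn{\sigma_{g^{-1}}(\alpha)=\rho(\alpha)|\alpha|/|g(\alpha)|} is the
#' local area-stretch factor. The diagonal is the negative row sum, so rows
#' sum to zero and the matrix is symmetric.
#'
#' @param g image coordinates (b x 3 matrix or \linkS4class{PLMap}).
#' @param surface surface list from [boundarySurface()].
#' @param faceMass optional precomputed \eqn{\rho(\alpha)|\alpha|}.
#' @return sparse symmetric \code{dgCMatrix}.
#' @export
stretchLaplacian <- function(g, surface, faceMass = .surfaceFaceMass(surface)) {
  if (is(g, "PLMap")) g <- g@coords
  faces <- surface$faces
  gArea <- triangleAreas(g, faces)
  if (any(gArea <= 0))
    stop(sprintf("collapsed image face (first: %d)", which(gArea <= 0)[1]))
  sigma <- faceMass / gArea
  cots <- triangleCotangents(g, faces)
  b <- nrow(g)
  ii <- c(faces[, 2], faces[, 1], faces[, 1])
  jj <- c(faces[, 3], faces[, 3], faces[, 2])
  ww <- -0.5 * c(cots[, 1], cots[, 2], cots[, 3]) / sigma
  L <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                    dims = c(b, b))
  L - Diagonal(b, Matrix::rowSums(L))
}

# E_S(g) = 1/2 sum_t g_t' L g_t
.stretchEnergy <- function(L, g) {
  sum(vapply(1:3, function(t) as.numeric(g[, t] %*% (L %*% g[, t])),
             numeric(1))) / 2
}

#' Spherical area-measure-preserving OMT map
#'
#' Projected gradient descent on the area-weighted stretch energy: each
#' iteration takes a gradient step with the current stretch Laplacian,
#' renormalizes vertices to the unit sphere, and accepts the step only if
#' the energy decreases (otherwise the step is damped). Face masses are
#' rescaled internally so they total \eqn{4\pi}, the sphere's area.
#'
#' @param surface surface list from [boundarySurface()] or
#'   [referenceCubeBoundary()]; must be closed and genus-zero.
#' @param maxIters iteration cap.
#' @param tol relative energy-decrease stopping tolerance.
#' @return list with \code{coords} (unit-norm image points),
#'   \code{energyTrace}, \code{stretch} (per-face
#'   \eqn{\rho(\alpha)|\alpha|/|g(\alpha)|} at the normalized mass),
#'   \code{foldedFaces}, and \code{converged}.
#' @export
sphericalAOMT <- function(surface, maxIters = 200L, tol = 1e-7) {
  verts <- surface$vertices
  faces <- surface$faces
  nb <- nrow(verts)
  chi <- nb - (3L * nrow(faces)) / 2L + nrow(faces)
  if (abs(chi - 2) > 1e-9)
    stop(sprintf("surface is not genus-zero (Euler characteristic %g)", chi))
  mass <- .surfaceFaceMass(surface)
  mass <- mass * (4 * pi / sum(mass))
  ctr <- colSums(verts * surface$rho) / sum(surface$rho)
  g <- rowUnit(sweep(verts, 2, ctr))
  L <- stretchLaplacian(g, surface, mass)
  E <- .stretchEnergy(L, g)
  eta <- 0.5 / max(abs(Matrix::diag(L)))
  trace <- E
  converged <- FALSE
  for (it in seq_len(maxIters)) {
    grad <- as.matrix(L %*% g)
    accepted <- FALSE
    for (damp in 1:40) {
      gNew <- rowUnit(g - eta * grad)
      areas <- triangleAreas(gNew, faces)
      if (all(areas > 0)) {
        LNew <- stretchLaplacian(gNew, surface, mass)
        ENew <- .stretchEnergy(LNew, gNew)
        if (ENew < E) {
          g <- gNew; L <- LNew
          accepted <- TRUE
          relDrop <- (E - ENew) / abs(E)
          E <- ENew
          eta <- eta * 1.5
          break
        }
      }
      eta <- eta / 2
    }
    trace <- c(trace, E)
    if (!accepted) break
    if (relDrop < tol) { converged <- TRUE; break }
  }
  nrm <- triangleNormals(g, faces)
  cent <- (g[faces[, 1], ] + g[faces[, 2], ] + g[faces[, 3], ]) / 3
  folded <- sum(rowSums(nrm * cent) <= 0)
  list(coords = g, energyTrace = trace,
       stretch = mass / triangleAreas(g, faces),
       foldedFaces = folded, converged = converged)
}

# Rotation aligning weighted principal axes with the coordinate axes.
# Each eigenvector is assigned to the coordinate axis it is already closest
# to (signs chosen positive), so the gauge is near-identity for
# axis-aligned shapes; identity when the covariance is near-isotropic
# (symmetric shapes, where principal directions are meaningless).
.principalAxisRotation <- function(coords, weights) {
  mu <- colSums(coords * weights) / sum(weights)
  x <- sweep(coords, 2, mu)
  C <- crossprod(x * sqrt(weights / sum(weights)))
  e <- eigen(C, symmetric = TRUE)
  if ((max(e$values) - min(e$values)) < 0.02 * max(e$values))
    return(diag(3))
  E <- e$vectors                      # columns are principal directions
  R <- matrix(0, 3, 3)
  usedAxis <- usedVec <- logical(3)
  M <- abs(t(E))                      # M[vec, axis]
  for (step in 1:3) {
    idx <- which(M == max(M[!usedVec, !usedAxis, drop = FALSE]) &
                 !outer(usedVec, rep(TRUE, 3)) &
                 !outer(rep(TRUE, 3), usedAxis), arr.ind = TRUE)[1, ]
    v <- idx[1]; a <- idx[2]
    R[a, ] <- E[, v] * sign(E[a, v] + (E[a, v] == 0))
    usedVec[v] <- TRUE; usedAxis[a] <- TRUE
  }
  if (det(R) < 0) {
    k <- which.min(abs(diag(R)))
    R[k, ] <- -R[k, ]
  }
  R
}

#' Invert a reference spherical map at query directions
#'
#' Each unit-norm query is located in exactly one spherical triangle of the
#' reference map's image (ties broken by lowest face index), and pulled back
#' barycentrically onto the cube boundary; the returned points are snapped
#' exactly onto their cube face plane.
#'
#' @param h1 list with \code{surface} (cube-boundary surface) and
#'   \code{coords} (its spherical image).
#' @param queries q x 3 matrix of unit vectors.
#' @return q x 3 matrix of points on \eqn{\partial [-1/2,1/2]^3}.
#' @export
invertReferenceSphereMap <- function(h1, queries) {
  loc <- locate_dirs_tris_cpp(queries, h1$coords, h1$surface$faces, 1e-12)
  if (any(loc$tri == 0))
    stop(sprintf("%d query points not covered by the reference spherical map",
                 sum(loc$tri == 0)))
  f <- h1$surface$faces[loc$tri, , drop = FALSE]
  V <- h1$surface$vertices
  pts <- loc$coef[, 1] * V[f[, 1], , drop = FALSE] +
         loc$coef[, 2] * V[f[, 2], , drop = FALSE] +
         loc$coef[, 3] * V[f[, 3], , drop = FALSE]
  ## snap onto the face plane (reference triangles never span cube faces)
  ax <- max.col(abs(pts), ties.method = "first")
  pts[cbind(seq_len(nrow(pts)), ax)] <-
    0.5 * sign(pts[cbind(seq_len(nrow(pts)), ax)])
  pts
}

.cacheEnv <- new.env(parent = emptyenv())

#' Reference spherical map of the cube boundary
#'
#' The uniform-density spherical OMT map \eqn{h^*_1} of
#' [referenceCubeBoundary()], cached per resolution.
#'
#' @param res vertices per cube-face edge.
#' @param maxIters,tol passed to [sphericalAOMT()].
#' @return list with \code{surface} and spherical \code{coords}.
#' @export
referenceSphereMap <- function(res = 33L, maxIters = 200L, tol = 1e-7) {
  key <- sprintf("ref%d", res)
  if (!is.null(.cacheEnv[[key]])) return(.cacheEnv[[key]])
  surf <- referenceCubeBoundary(res)
  h <- sphericalAOMT(surf, maxIters = maxIters, tol = tol)
  out <- list(surface = surf, coords = h$coords)
  .cacheEnv[[key]] <- out
  out
}

#' Cubic area-measure-preserving OMT boundary map
#'
#' Composition \eqn{g^*_\rho = (h^*_1)^{-1} \circ h^*_\rho}: the
#' density-weighted spherical map of the brain boundary composed with the
#' inverse of the reference cube map. The boundary's total \eqn{\rho}-area
#' is rescaled to the cube's surface measure (6) for the reported per-face
#' area ratios.
#'
#' @param mesh a \linkS4class{TetMesh} (normalized) or a surface list.
#' @param rho \linkS4class{DensityField} on the mesh.
#' @param refRes reference cube-boundary resolution.
#' @param maxIters,tol forwarded to [sphericalAOMT()].
#' @return a \linkS4class{PLMap} onto the cube boundary for the mesh's
#'   boundary vertices, with attribute \code{"diagnostics"}: per-face area
#'   ratios \eqn{\rho(\alpha)|\alpha|/|g(\alpha)|}, spherical energy trace,
#'   folded-face counts.
#' @export
cubeBoundaryAOMT <- function(mesh, rho = NULL, refRes = 33L,
                             maxIters = 200L, tol = 1e-7) {
  surf <- if (is(mesh, "TetMesh")) boundarySurface(mesh, rho) else mesh
  hrho <- sphericalAOMT(surf, maxIters = maxIters, tol = tol)
  href <- referenceSphereMap(refRes)
  wts <- surf$rho * 0
  ## vertex weights: accumulate rho-area onto vertices for the gauge
  mass <- .surfaceFaceMass(surf)
  for (k in 1:3) {
    acc <- rowsum(mass / 3, surf$faces[, k])
    ids <- as.integer(rownames(acc))
    wts[ids] <- wts[ids] + acc[, 1]
  }
  R <- .principalAxisRotation(surf$vertices, wts)
  q <- hrho$coords %*% t(R)
  cube <- invertReferenceSphereMap(href, q)
  massScaled <- mass * (6 / sum(mass))
  gArea <- triangleAreas(cube, surf$faces)
  nrm <- triangleNormals(cube, surf$faces)
  cent <- (cube[surf$faces[, 1], ] + cube[surf$faces[, 2], ] +
           cube[surf$faces[, 3], ]) / 3
  out <- new("PLMap", coords = cube, vertexIds = as.integer(surf$meshIds),
             target = "cubeBoundary")
  attr(out, "diagnostics") <- list(
    areaRatio = massScaled / gArea,
    sphereEnergyTrace = hrho$energyTrace,
    sphereFoldedFaces = hrho$foldedFaces,
    cubeFoldedFaces = sum(rowSums(nrm * cent) <= 0),
    converged = hrho$converged,
    gaugeRotation = R)
  out
}
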