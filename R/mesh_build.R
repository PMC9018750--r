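## Mesh construction from a binary voxel mask: each retained voxel cube is
## split into the 6 Kuhn tetrahedra around the main diagonal (a globally
## conforming, positively orientable subdivision), the mask having first been
## reduced to its largest 26-connected component with interior cavities
## filled so the boundary surface is closed and genus-zero.

# The 6 Kuhn tets of the unit cube, as corner indices 1..8 where corner
# c = 1 + x + 2*y + 4*z for offsets (x,y,z) in {0,1}. Each path
# 000 -> e_{p1} -> e_{p1}+e_{p2} -> 111 over permutations p of the axes;
# odd permutations are re-ordered for positive orientation.
.kuhnTets <- local({
  corner <- function(x, y, z) 1L + x + 2L * y + 4L * z
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  even <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  out <- matrix(0L, 6, 4)
  for (i in seq_along(perms)) {
    p <- perms[[i]]
    e <- diag(3)
    v1 <- c(0, 0, 0); v2 <- e[p[1], ]; v3 <- e[p[1], ] + e[p[2], ]
    v4 <- c(1, 1, 1)
    tet <- c(corner(v1[1], v1[2], v1[3]), corner(v2[1], v2[2], v2[3]),
             corner(v3[1], v3[2], v3[3]), corner(v4[1], v4[2], v4[3]))
    if (!even[i]) tet <- tet[c(1, 2, 4, 3)]
    out[i, ] <- as.integer(tet)
  }
  out
})

.asMaskArray <- function(mask) {
  if (is(mask, "VoxelVolume")) mask <- mask@data
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  array(as.logical(mask != 0), dim(mask))
}

#' Clean a binary mask for meshing
#'
#' Keeps the largest 26-connected foreground component and fills interior
#' cavities (6-connected background components not touching the grid
#' border), so that the meshed boundary is a single closed surface.
#'
#' @param mask binary 3D array (or \linkS4class{VoxelVolume}).
#' @return logical 3D array.
#' @export
cleanupMask <- function(mask) {
  m <- .asMaskArray(mask)
  if (!any(m)) stop("mask is empty")
  lab <- cc_label_cpp(as.logical(m), dim(m), 26L)
  tab <- tabulate(lab)
  m <- array(lab == which.max(tab), dim(m))
  ## fill cavities
  bg <- cc_label_cpp(as.logical(!m), dim(m), 6L)
  bg <- array(bg, dim(m))
  d <- dim(m)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border <- setdiff(border, 0L)
  m[bg != 0 & !(bg %in% border)] <- TRUE
  m
}

#' Build a tetrahedral mesh from a binary voxel mask
#'
#' Each retained voxel is subdivided into 6 tetrahedra (Kuhn subdivision
#' with one fixed global diagonal), shared corners merged, giving a
#' conforming simplicial 3-complex whose boundary is a closed genus-zero
#' surface. Voxel cell \code{(i,j,k)} (0-based) occupies the half-open box
#' \code{[i,i+1) x [j,j+1) x [k,k+1)} in index space before spacing scaling.
#'
#' @param mask binary 3D array or \linkS4class{VoxelVolume}; cleaned with
#'   [cleanupMask()] before meshing.
#' @param spacing per-axis physical voxel lengths.
#' @return a \linkS4class{TetMesh}.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' mesh <- buildTetMesh(m)
#' nTets(mesh)   # 6
#' @export
buildTetMesh <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "VoxelVolume") && missing(spacing)) spacing <- mask@spacing
  m <- cleanupMask(mask)
  d <- dim(m)
  vox <- which(m)
  vx <- (vox - 1L) %% d[1]
  vy <- ((vox - 1L) %/% d[1]) %% d[2]
  vz <- (vox - 1L) %/% (d[1] * d[2])
  nV <- length(vox)
  ## corner keys on the (d+1)^3 corner grid, 0-based coords
  cx <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  cy <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  cz <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  gx <- d[1] + 1; gy <- d[2] + 1
  corners <- matrix(0, nV, 8)   # double keys
  for (k in 1:8)
    corners[, k] <- (vx + cx[k]) + gx * ((vy + cy[k]) + gy * (vz + cz[k]))
  keys <- sort(unique(as.vector(corners)))
  idx <- matrix(match(as.vector(corners), keys), nV, 8)
  ## vertex coordinates from keys
  kx <- keys %% gx
  ky <- (keys %/% gx) %% gy
  kz <- keys %/% (gx * gy)
  verts <- cbind(kx * spacing[1], ky * spacing[2], kz * spacing[3])
  ## tets: 6 per voxel
  tets <- matrix(0L, 6L * nV, 4L)
  for (i in 1:6)
    tets[seq.int(i, by = 6L, length.out = nV), ] <- idx[, .kuhnTets[i, ]]
  vertexVoxel <- cbind(pmin(kx, d[1] - 1) + 1L, pmin(ky, d[2] - 1) + 1L,
                       pmin(kz, d[3] - 1) + 1L)
  storage.mode(vertexVoxel) <- "integer"
  .finishMesh(verts, tets, vertexVoxel, as.integer(d), as.numeric(spacing),
              center = c(0, 0, 0), scale = 1)
}

# Derive boundary entities, run topology checks, assemble the S4 object.
.finishMesh <- function(verts, tets, vertexVoxel, gridDim, spacing,
                        center, scale) {
  vol <- tetVolumes(verts, tets)
  if (any(vol <= 0)) {
    bad <- which(vol < 0)
    tets[bad, c(3, 4)] <- tets[bad, c(4, 3)]
    if (any(tetVolumes(verts, tets) <= 0))
      stop("degenerate tetrahedra in mesh")
  }
  nv <- nrow(verts)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  fk <- faceKeys(faces, nv)
  o <- order(fk)
  runs <- rle(fk[o])
  if (any(runs$lengths > 2L))
    stop("non-manifold mesh: a face is shared by more than 2 tets")
  single <- runs$lengths == 1L
  bnd <- faces[o[cumsum(runs$lengths)[single]], , drop = FALSE]
  ## boundary topology: closed (each edge in 2 faces) and genus zero
  be <- rbind(bnd[, c(1, 2)], bnd[, c(2, 3)], bnd[, c(3, 1)])
  ek <- as.numeric(pmin(be[, 1], be[, 2])) +
    as.numeric(nv) * as.numeric(pmax(be[, 1], be[, 2]))
  eruns <- rle(sort(ek))
  if (any(eruns$lengths != 2L))
    stop("boundary surface is not closed (a hanging vertex or edge remains)")
  bv <- sort(unique(as.vector(bnd)))
  chi <- length(bv) - length(eruns$lengths) + nrow(bnd)
  if (chi != 2L)
    stop(sprintf("boundary Euler characteristic is %d, expected 2 (genus-zero)",
                 chi))
  new("TetMesh", vertices = verts, tets = tets, boundaryFaces = bnd,
      boundaryVertexIds = as.integer(bv),
      interiorVertexIds = as.integer(setdiff(seq_len(nv), bv)),
      vertexVoxel = vertexVoxel, gridDim = gridDim, spacing = spacing,
      center = as.numeric(center), scale = as.numeric(scale))
}

#' Recover voxel-index coordinates from mesh coordinates
#'
#' Inverts the affine stored by [normalizeComplex()]: index coordinates are
#' \code{(x / scale + center) / spacing}.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param coords k x 3 matrix in the mesh's current coordinate frame
#'   (defaults to the mesh vertices).
#' @return k x 3 matrix of 0-based voxel-index coordinates.
#' @export
meshIndexCoords <- function(mesh, coords = vertices(mesh)) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  phys <- sweep(coords / mesh@scale, 2, mesh@center, "+")
  sweep(phys, 2, mesh@spacing, "/")
}

# 1-based voxel cell containing each index-space point (clamped to grid).
.indexToCell <- function(idx, gridDim) {
  cell <- floor(idx)
  for (a in 1:3) cell[, a] <- pmin(pmax(cell[, a], 0), gridDim[a] - 1)
  storage.mode(cell) <- "integer"
  cell + 1L
}

#' Centralize and normalize a measured complex
#'
#' Translates the \eqn{\rho}-weighted center of mass to the origin and
#' rescales so the total mass \eqn{\sum_\tau \rho(\tau)|\tau|} is one. The
#' affine is composed into the mesh's \code{center}/\code{scale} slots so
#' physical coordinates stay recoverable via [meshIndexCoords()].
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField} (defaults to uniform density 1).
#' @return the rescaled \linkS4class{TetMesh}.
#' @export
normalizeComplex <- function(mesh, rho = uniformDensity(mesh)) {
  verts <- mesh@vertices
  vol <- tetVolumes(verts, mesh@tets)
  if (sum(vol) <= 0) stop("degenerate mesh: non-positive total volume")
  meas <- simplexMeasures(mesh, rho)
  M <- sum(meas$tetMass)
  if (M <= 0) stop("total mass must be positive")
  cg <- colSums(meas$vertexVolumeMeasure * verts) / M
  s <- M^(-1 / 3)
  newVerts <- sweep(verts, 2, cg) * s
  mesh@vertices <- newVerts
  mesh@center <- mesh@center + cg / mesh@scale
  mesh@scale <- mesh@scale * s
  mesh
}

#' Morphological dilation by a Euclidean ball
#'
#' A voxel is set in the output iff its Euclidean distance (in voxel units)
#' to the input set is at most \code{m}.
#'
#' @param region binary 3D array or \linkS4class{VoxelVolume}.
#' @param m non-negative integer radius in voxels (the pipeline default is
#'   5).
#' @return logical 3D array containing the input.
#' @export
dilateMask <- function(region, m = 5L) {
  if (length(m) != 1L || is.na(m) || m < 0 || m != round(m))
    stop("m must be a non-negative integer")
  r <- .asMaskArray(region)
  if (m == 0) return(r)
  m <- as.integer(m)
  d <- dim(r)
  pd <- d + 2L * m
  A <- array(0, pd)
  A[(m + 1):(m + d[1]), (m + 1):(m + d[2]), (m + 1):(m + d[3])] <- r
  off <- seq(-m, m)
  ball <- outer(outer(off^2, off^2, "+"), off^2, "+") <= m^2
  K <- array(0, pd)
  wrap <- function(o, n) ifelse(o >= 0, o + 1L, n + o + 1L)
  K[wrap(off, pd[1]), wrap(off, pd[2]), wrap(off, pd[3])] <- ball
  cnt <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(pd)
  out <- cnt[(m + 1):(m + d[1]), (m + 1):(m + d[2]), (m + 1):(m + d[3])] > 0.5
  array(out | r, d)
}

## ---- refinement -------------------------------------------------------

.edgeKey <- function(i, j) pmin(i, j) + pmax(i, j) * 2^26

#' Refine a tetrahedral mesh inside a voxel region
#'
#' Tetrahedra whose centroid lies in \code{region} are subdivided 1:8 (red
#' refinement); conformity is restored on their neighbors with green
#' templates (single-edge bisection, two-edge, and one-face templates),
#' promoting a tetrahedron to red where no template applies. Existing
#' vertices are never moved and total volume is conserved.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param region binary 3D array on the mesh's voxel grid.
#' @return the refined \linkS4class{TetMesh}.
#' @export
refineMesh <- function(mesh, region) {
  r <- .asMaskArray(region)
  if (!all(dim(r) == mesh@gridDim))
    stop("region grid does not match the mesh grid")
  if (!any(r)) return(mesh)
  verts <- mesh@vertices
  tets <- mesh@tets
  nT <- nrow(tets)
  cent <- (verts[tets[, 1], , drop = FALSE] +
           verts[tets[, 2], , drop = FALSE] +
           verts[tets[, 3], , drop = FALSE] +
           verts[tets[, 4], , drop = FALSE]) / 4
  cell <- .indexToCell(meshIndexCoords(mesh, cent), mesh@gridDim)
  inRegion <- r[cbind(cell[, 1], cell[, 2], cell[, 3])]
  if (!any(inRegion)) return(mesh)

  ## edge marking with red promotion closure
  pairIdx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tetEdgeKeys <- matrix(0, nT, 6)
  for (e in 1:6)
    tetEdgeKeys[, e] <- .edgeKey(tets[, pairIdx[e, 1]], tets[, pairIdx[e, 2]])
  red <- inRegion
  repeat {
    marked <- unique(as.vector(tetEdgeKeys[red, , drop = FALSE]))
    mk <- matrix(tetEdgeKeys %in% marked, nT, 6)
    cnt <- rowSums(mk)
    promote <- rep(FALSE, nT)
    three <- which(!red & cnt == 3L)
    if (length(three)) {
      oneFace <- vapply(three, function(t) {
        vs <- unique(as.vector(tets[t, pairIdx[mk[t, ], , drop = FALSE]]))
        length(vs) == 3L
      }, logical(1))
      promote[three[!oneFace]] <- TRUE
    }
    promote[!red & cnt >= 4L] <- TRUE
    if (!any(promote)) break
    red <- red | promote
  }

  ## midpoint vertices for marked edges
  marked <- sort(unique(as.vector(tetEdgeKeys[red, , drop = FALSE])))
  lo <- as.integer(marked %% 2^26)
  hi <- as.integer(marked %/% 2^26)
  mid <- (verts[lo, , drop = FALSE] + verts[hi, , drop = FALSE]) / 2
  nv0 <- nrow(verts)
  midId <- nv0 + seq_along(marked)
  verts2 <- rbind(verts, mid)
  midOf <- function(keys) midId[match(keys, marked)]

  mkAll <- matrix(tetEdgeKeys %in% marked, nT, 6)
  greenCnt <- rowSums(mkAll)
  keep <- !red & greenCnt == 0L
  green <- which(!red & greenCnt > 0L)

  ## red tets, vectorized: 4 corner children + 4 octahedron children with
  ## the shortest of the three diagonals
  redBlock <- NULL
  if (any(red)) {
    rt <- tets[red, , drop = FALSE]
    M <- matrix(0L, nrow(rt), 6)      # m12 m13 m14 m23 m24 m34
    for (e in 1:6)
      M[, e] <- midOf(.edgeKey(rt[, pairIdx[e, 1]], rt[, pairIdx[e, 2]]))
    dl <- cbind(rowSums((verts2[M[, 1], , drop = FALSE] -
                         verts2[M[, 6], , drop = FALSE])^2),
                rowSums((verts2[M[, 2], , drop = FALSE] -
                         verts2[M[, 5], , drop = FALSE])^2),
                rowSums((verts2[M[, 3], , drop = FALSE] -
                         verts2[M[, 4], , drop = FALSE])^2))
    dg <- max.col(-dl, ties.method = "first")
    corners <- rbind(cbind(rt[, 1], M[, 1], M[, 2], M[, 3]),
                     cbind(M[, 1], rt[, 2], M[, 4], M[, 5]),
                     cbind(M[, 2], M[, 4], rt[, 3], M[, 6]),
                     cbind(M[, 3], M[, 5], M[, 6], rt[, 4]))
    ## octahedron rings per diagonal choice
    ringsFor <- function(dgk) switch(dgk,
      list(d = c(1, 6), ring = c(2, 4, 5, 3)),
      list(d = c(2, 5), ring = c(1, 4, 6, 3)),
      list(d = c(3, 4), ring = c(1, 5, 6, 2)))
    octa <- vector("list", 3)
    for (k in 1:3) {
      sel <- dg == k
      if (!any(sel)) next
      rf <- ringsFor(k)
      Mk <- M[sel, , drop = FALSE]
      a <- Mk[, rf$d[1]]; b <- Mk[, rf$d[2]]
      r <- rf$ring
      octa[[k]] <- rbind(cbind(a, b, Mk[, r[1]], Mk[, r[2]]),
                         cbind(a, b, Mk[, r[2]], Mk[, r[3]]),
                         cbind(a, b, Mk[, r[3]], Mk[, r[4]]),
                         cbind(a, b, Mk[, r[4]], Mk[, r[1]]))
    }
    redBlock <- rbind(corners, do.call(rbind, octa[!vapply(octa, is.null,
                                                           logical(1))]))
  }

  greenBlocks <- vector("list", length(green))
  for (gi in seq_along(green)) {
    t <- green[gi]
    v <- tets[t, ]
    mkT <- mkAll[t, ]
    vs <- unique(as.vector(tets[t, pairIdx[mkT, , drop = FALSE]]))
    if (sum(mkT) == 3L && length(vs) == 3L) {
      ## one-face green template: face abc fully marked, apex d
      d4 <- setdiff(v, vs)
      a <- vs[1]; b <- vs[2]; c0 <- vs[3]
      mab <- midOf(.edgeKey(a, b)); mac <- midOf(.edgeKey(a, c0))
      mbc <- midOf(.edgeKey(b, c0))
      greenBlocks[[gi]] <- rbind(c(a, mab, mac, d4), c(mab, b, mbc, d4),
                                 c(mac, mbc, c0, d4), c(mab, mbc, mac, d4))
    } else {
      greenBlocks[[gi]] <- .bisectClosure(v, marked, midOf)
    }
  }
  tets2 <- rbind(tets[keep, , drop = FALSE], redBlock,
                 do.call(rbind, greenBlocks))
  storage.mode(tets2) <- "integer"
  idxNew <- meshIndexCoords(mesh, verts2[midId, , drop = FALSE])
  vv2 <- rbind(mesh@vertexVoxel, .indexToCell(idxNew, mesh@gridDim))
  ref <- .finishMesh(verts2, tets2, vv2, mesh@gridDim, mesh@spacing,
                     mesh@center, mesh@scale)
  v0 <- sum(tetVolumes(verts, tets))
  v1 <- sum(tetVolumes(ref@vertices, ref@tets))
  if (abs(v1 - v0) > 1e-10 * abs(v0))
    stop("refinement failed to conserve volume")
  ref
}

# Recursively bisect a tet at its globally-smallest marked edge; the global
# ordering keeps shared-face triangulations consistent across neighbors.
.bisectClosure <- function(v, marked, midOf) {
  pairIdx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  keys <- .edgeKey(v[pairIdx[, 1]], v[pairIdx[, 2]])
  mk <- which(keys %in% marked)
  if (!length(mk)) return(matrix(v, 1))
  e <- mk[which.min(keys[mk])]
  i <- pairIdx[e, 1]; j <- pairIdx[e, 2]
  m <- midOf(keys[e])
  v1 <- v; v1[j] <- m
  v2 <- v; v2[i] <- m
  rbind(.bisectClosure(v1, marked, midOf), .bisectClosure(v2, marked, midOf))
}
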