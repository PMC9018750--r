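## Grayscale-derived densities and simplex measures.
##
## Density construction follows the two-phase scheme: Phase I exponentiates
## the contrast-enhanced, histogram-equalized FLAIR grayscale at every brain
## vertex; Phase II restricts the exponential to a dilated candidate tumor
## region, sets 1.0 elsewhere, and smooths the step field with an m^3 mean
## (box-blur) kernel before sampling it at mesh vertices.

#' Uniform density field on a mesh
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param value constant density value.
#' @return a \linkS4class{DensityField}.
#' @export
uniformDensity <- function(mesh, value = 1) {
  new("DensityField", values = rep(as.numeric(value), nVertices(mesh)),
      gamma = NA_real_)
}

#' Contrast-enhanced histogram equalization (CEHE) of a modality
#'
#' Within the brain mask the grayscale is Z-scored, clipped to +/- 3 SD, and
#' histogram-equalized (empirical CDF) to \eqn{[0,1]}; voxels outside the
#' mask are set to 0. The transform is a monotone non-decreasing function of
#' the within-mask intensity ranks. A constant image inside the mask maps to
#' 0.5 everywhere in the mask (degenerate rule).
#'
#' @param volume a modality \linkS4class{VoxelVolume} (or 3D array).
#' @param brainMask binary array of brain voxels.
#' @return a \linkS4class{VoxelVolume} of kind \code{"cehe"}.
#' @export
normalizeIntensity <- function(volume, brainMask) {
  v <- if (is(volume, "VoxelVolume")) volume@data else as.array(volume)
  sp <- if (is(volume, "VoxelVolume")) volume@spacing else c(1, 1, 1)
  m <- .asMaskArray(brainMask)
  if (!any(m)) stop("brain mask is empty")
  x <- v[m]
  out <- array(0, dim(v))
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    out[m] <- 0.5
  } else {
    z <- pmin(pmax((x - mean(x)) / s, -3), 3)
    ## empirical CDF: #\{values <= z\} / n  (two-level image -> 0.5 and 1.0)
    r <- rank(z, ties.method = "max") / length(z)
    out[m] <- r
  }
  VoxelVolume(out, kind = "cehe", spacing = sp)
}

# Sample a voxel field at mesh vertices through the vertex->cell map.
.sampleAtVertices <- function(mesh, vol) {
  v <- if (is(vol, "VoxelVolume")) vol@data else vol
  v[mesh@vertexVoxel]
}

#' Phase I density field
#'
#' \eqn{\rho_\gamma(v) = \exp(\gamma \bar{I}_1(i,j,k))} where the vertex
#' borders voxel \eqn{(i,j,k)}; values lie in \eqn{[1, e^\gamma]} for a CEHE
#' grayscale in \eqn{[0,1]}.
#'
#' @param cehe CEHE \linkS4class{VoxelVolume} (FLAIR channel).
#' @param mesh a \linkS4class{TetMesh}.
#' @param gamma exponent, conventionally chosen from \eqn{[1,2]}; values
#'   outside that interval trigger a warning but are still computed.
#' @return a \linkS4class{DensityField}.
#' @export
densityPhase1 <- function(cehe, mesh, gamma = 1) {
  if (gamma < 1 || gamma > 2)
    warning("gamma outside [1, 2]; density computed anyway")
  vals <- exp(gamma * .sampleAtVertices(mesh, cehe))
  new("DensityField", values = vals, gamma = as.numeric(gamma))
}

#' Separable 3D box-blur with replicate padding
#'
#' Mean filter over an \code{m x m x m} window; the array border replicates
#' its edge value so the kernel always has full support.
#'
#' @param x 3D numeric array.
#' @param m odd positive window size.
#' @return blurred array of the same dimension.
#' @export
boxBlur3 <- function(x, m) {
  if (m < 1 || m %% 2 == 0) stop("kernel size m must be odd and positive")
  if (m == 1) return(x)
  r <- (m - 1) / 2
  blur1 <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- pmin(pmax(seq(1 - r, n + r), 1), n)   # replicate padding
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    mat <- matrix(ap, dm[1], dm[2] * dm[3])
    padded <- mat[idx, , drop = FALSE]
    cs <- rbind(0, apply(padded, 2, cumsum))
    sm <- (cs[(m + 1):(m + n), , drop = FALSE] - cs[1:n, , drop = FALSE]) / m
    out <- array(sm, dm)
    aperm(out, order(perm))
  }
  blur1(blur1(blur1(x, 1), 2), 3)
}

#' Phase II density field
#'
#' Builds the step field \eqn{\exp(\gamma \bar{I}_1)} inside the dilated
#' candidate region \eqn{\mathbb{T}} and 1.0 outside, over the full cuboid
#' grid; convolves it with the \eqn{m^3} mean kernel (replicate padding at
#' the cuboid border); and samples the smoothed field at mesh vertices.
#'
#' @param cehe CEHE \linkS4class{VoxelVolume}.
#' @param region binary array \eqn{\mathbb{T}} (dilated WT candidate).
#' @param mesh a \linkS4class{TetMesh}.
#' @param gamma exponent as in [densityPhase1()].
#' @param m odd blur kernel size (default 5, the 5x5x5 blur box).
#' @return a \linkS4class{DensityField}.
#' @export
densityPhase2 <- function(cehe, region, mesh, gamma = 1, m = 5L) {
  if (m %% 2 == 0) stop("blur kernel size m must be odd")
  if (gamma < 1 || gamma > 2)
    warning("gamma outside [1, 2]; density computed anyway")
  v <- if (is(cehe, "VoxelVolume")) cehe@data else as.array(cehe)
  r <- .asMaskArray(region)
  step <- array(1, dim(v))
  step[r] <- exp(gamma * v[r])
  sm <- boxBlur3(step, m)
  vals <- sm[mesh@vertexVoxel]
  new("DensityField", values = vals, gamma = as.numeric(gamma))
}

#' Simplex densities and local measures
#'
#' Induced densities are corner means:
#' \eqn{\rho(\alpha) = \frac13\sum\rho(\hat v_i)},
#' \eqn{\rho(\tau) = \frac14\sum\rho(v_i)}; local measures are
#' \eqn{a_\rho(\hat v) = \frac13 \rho(\hat v)\sum_{\hat v\subset\alpha}|\alpha|}
#' and
#' \eqn{m_\rho(v) = \frac14 \rho(v)\sum_{v\subset\tau}|\tau|}. The identities
#' \eqn{\sum_v m_\rho(v) = \sum_\tau \rho(\tau)|\tau|} and its boundary
#' analogue hold algebraically.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param rho a \linkS4class{DensityField}.
#' @return list with \code{faceDensity}, \code{tetDensity}, \code{faceArea},
#'   \code{tetVolume}, \code{faceMass} (\eqn{\rho(\alpha)|\alpha|}),
#'   \code{tetMass} (\eqn{\rho(\tau)|\tau|}),
#'   \code{vertexAreaMeasure} (\eqn{a_\rho}, nonzero on boundary vertices),
#'   and \code{vertexVolumeMeasure} (\eqn{m_\rho}).
#' @export
simplexMeasures <- function(mesh, rho) {
  stopifnot(length(rho@values) == nVertices(mesh))
  verts <- mesh@vertices
  tets <- mesh@tets
  bnd <- mesh@boundaryFaces
  vals <- rho@values
  tetVol <- abs(tetVolumes(verts, tets))
  tetDen <- (vals[tets[, 1]] + vals[tets[, 2]] +
             vals[tets[, 3]] + vals[tets[, 4]]) / 4
  n <- nVertices(mesh)
  vertVolSum <- numeric(n)
  for (k in 1:4) {
    acc <- rowsum(tetVol, tets[, k])
    ids <- as.integer(rownames(acc))
    vertVolSum[ids] <- vertVolSum[ids] + acc[, 1]
  }
  mRho <- vals * vertVolSum / 4
  faceArea <- faceDen <- aRho <- numeric(0)
  if (nrow(bnd)) {
    faceArea <- triangleAreas(verts, bnd)
    faceDen <- (vals[bnd[, 1]] + vals[bnd[, 2]] + vals[bnd[, 3]]) / 3
    vertAreaSum <- numeric(n)
    for (k in 1:3) {
      acc <- rowsum(faceArea, bnd[, k])
      ids <- as.integer(rownames(acc))
      vertAreaSum[ids] <- vertAreaSum[ids] + acc[, 1]
    }
    aRho <- vals * vertAreaSum / 3
  }
  list(faceDensity = faceDen, tetDensity = tetDen,
       faceArea = faceArea, tetVolume = tetVol,
       faceMass = faceDen * faceArea, tetMass = tetDen * tetVol,
       vertexAreaMeasure = aRho, vertexVolumeMeasure = mRho)
}
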