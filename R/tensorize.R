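## Rasterization through the V-OMT map and pullback of cube predictions.
##
## Each cube voxel center c_u is located in the image tetrahedron f(tau)
## containing it, pulled back barycentrically to a point of the brain mesh,
## and assigned to the brain voxel containing that point (0-based half-open
## cells, matching the meshing convention). Grayscale and label sampling is
## nearest-voxel -- no interpolation, so label cubes stay in the binary
## alphabet of their phase.

#' Cube-to-brain voxel assignment through a V-OMT map
#'
#' @param f cube \linkS4class{PLMap} over all mesh vertices.
#' @param mesh the source \linkS4class{TetMesh}.
#' @param cubeSize cube resolution K (default 128).
#' @param maxUncovered error threshold on the fraction of cube voxels not
#'   covered by any image tetrahedron.
#' @return list with \code{cubeDim}, \code{covered} (logical K^3 array),
#'   \code{cell} (covered x 3, 1-based brain voxel indices),
#'   \code{cellLinear} (linear voxel index per covered center),
#'   \code{preimageIndex} (covered x 3, 0-based index-space coordinates of
#'   the preimage points), \code{gridDim}.
#' @export
cubeAssignment <- function(f, mesh, cubeSize = 128L, maxUncovered = 0.05) {
  if (is(f, "PLMap")) {
    stopifnot(nrow(f@coords) == nVertices(mesh))
    fc <- f@coords
  } else fc <- f
  K <- as.integer(cubeSize)
  g1 <- (seq_len(K) - 0.5) / K - 0.5
  centers <- cbind(rep(g1, times = K * K),
                   rep(rep(g1, each = K), times = K),
                   rep(g1, each = K * K))
  loc <- locate_points_tets_cpp(centers, fc, mesh@tets, 1e-9)
  miss <- which(loc$tet == 0L)
  if (length(miss)) {   # tolerance expansion for points on face slivers
    loc2 <- locate_points_tets_cpp(centers[miss, , drop = FALSE], fc,
                                   mesh@tets, 1e-5)
    loc$tet[miss] <- loc2$tet
    loc$bary[miss, ] <- loc2$bary
  }
  covered <- loc$tet > 0L
  fracUncovered <- 1 - mean(covered)
  if (fracUncovered > maxUncovered)
    stop(sprintf("map quality insufficient: %.1f%% of cube voxels uncovered",
                 100 * fracUncovered))
  ht <- mesh@tets[loc$tet[covered], , drop = FALSE]
  bb <- loc$bary[covered, , drop = FALSE]
  V <- mesh@vertices
  pre <- bb[, 1] * V[ht[, 1], , drop = FALSE] +
         bb[, 2] * V[ht[, 2], , drop = FALSE] +
         bb[, 3] * V[ht[, 3], , drop = FALSE] +
         bb[, 4] * V[ht[, 4], , drop = FALSE]
  idx <- meshIndexCoords(mesh, pre)
  cell <- .indexToCell(idx, mesh@gridDim)
  d <- mesh@gridDim
  cellLinear <- cell[, 1] + d[1] * (cell[, 2] - 1L) +
    d[1] * d[2] * (cell[, 3] - 1L)
  list(cubeDim = K, covered = array(covered, c(K, K, K)),
       cell = cell, cellLinear = cellLinear, preimageIndex = idx,
       gridDim = d)
}

#' Rasterize brain volumes into cube tensors
#'
#' @param f cube \linkS4class{PLMap} (or a precomputed [cubeAssignment()]
#'   via \code{assignment}).
#' @param mesh the source \linkS4class{TetMesh}.
#' @param sources a \linkS4class{VoxelVolume}/array or a named list of
#'   them, all on the mesh's grid.
#' @param mode \code{"grayscale"} or \code{"label"}; label mode keeps the
#'   sampled values unchanged (nearest sampling).
#' @param cubeSize cube resolution.
#' @param assignment optional precomputed [cubeAssignment()].
#' @return a \linkS4class{CubeGrid}, or a named list of them when
#'   \code{sources} is a list; uncovered cube voxels are zero-filled and
#'   flagged in \code{covered}.
#' @export
rasterizeToCube <- function(f, mesh, sources, mode = c("grayscale", "label"),
                            cubeSize = 128L, assignment = NULL) {
  mode <- match.arg(mode)
  if (is.null(assignment))
    assignment <- cubeAssignment(f, mesh, cubeSize)
  single <- !is.list(sources)
  if (single) sources <- list(sources)
  K <- assignment$cubeDim
  out <- lapply(sources, function(s) {
    v <- if (is(s, "VoxelVolume")) s@data else as.array(s)
    stopifnot(all(dim(v) == assignment$gridDim))
    a <- array(0, c(K, K, K))
    a[assignment$covered] <- v[assignment$cellLinear]
    CubeGrid(a, kind = if (mode == "label") "label" else "grayscale",
             covered = assignment$covered)
  })
  if (single) out[[1]] else out
}

#' Pull cube probabilities back to brain voxels
#'
#' Implements the multiplicity-weighted average: each brain voxel j takes
#' the mean of the probabilities of the n(j) cube centers whose preimages
#' land in it; a brain voxel with n(j) = 0 takes the value of the cube
#' center whose preimage is nearest to the voxel center.
#'
#' @param assignment a [cubeAssignment()].
#' @param cubeProbs probability \linkS4class{CubeGrid}/array, or a list of
#'   them (one per region t).
#' @param brainMask logical array of brain-domain voxels.
#' @return list with \code{probs} (array, or list of arrays; 0 outside the
#'   mask), \code{counts} (n(j) array), and \code{fallbackVoxels}.
#' @export
pullbackProbabilities <- function(assignment, cubeProbs, brainMask) {
  single <- !is.list(cubeProbs)
  if (single) cubeProbs <- list(cubeProbs)
  m <- .asMaskArray(brainMask)
  d <- assignment$gridDim
  stopifnot(all(dim(m) == d))
  counts <- array(0, d)
  tab <- rowsum(rep(1, length(assignment$cellLinear)),
                assignment$cellLinear)
  ids <- as.integer(rownames(tab))
  counts[ids] <- tab[, 1]
  needFallback <- which(m & counts == 0)
  nearest <- integer(0)
  if (length(needFallback)) {
    vj <- cbind((needFallback - 1) %% d[1],
                ((needFallback - 1) %/% d[1]) %% d[2],
                (needFallback - 1) %/% (d[1] * d[2])) + 0.5
    nearest <- .nearestPreimage(vj, assignment)
  }
  probs <- lapply(cubeProbs, function(p) {
    pv <- if (is(p, "CubeGrid")) p@data else as.array(p)
    vals <- pv[assignment$covered]
    acc <- rowsum(vals, assignment$cellLinear)
    out <- array(0, d)
    out[ids] <- acc[, 1] / counts[ids]
    if (length(needFallback)) out[needFallback] <- vals[nearest]
    out[!m & counts == 0] <- 0
    out
  })
  list(probs = if (single) probs[[1]] else probs, counts = counts,
       fallbackVoxels = length(needFallback))
}

# For query points (0-based index coords), index of the nearest covered
# preimage point, searched over expanding voxel-bucket shells.
.nearestPreimage <- function(queries, assignment) {
  d <- assignment$gridDim
  bucket <- split(seq_along(assignment$cellLinear), assignment$cellLinear)
  pre <- assignment$preimageIndex
  vapply(seq_len(nrow(queries)), function(r) {
    q <- queries[r, ]
    c0 <- pmin(pmax(floor(q), 0), d - 1)
    for (rad in 0:max(d)) {
      lo <- pmax(c0 - rad, 0); hi <- pmin(c0 + rad, d - 1)
      cells <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
      shell <- cells[apply(abs(sweep(cells, 2, c0)), 1, max) == rad, ,
                     drop = FALSE]
      lin <- shell[, 1] + 1 + d[1] * shell[, 2] + d[1] * d[2] * shell[, 3]
      cand <- unlist(bucket[as.character(lin)], use.names = FALSE)
      if (length(cand)) {
        dd <- rowSums(sweep(pre[cand, , drop = FALSE], 2, q)^2)
        return(cand[which.min(dd)])
      }
    }
    stop("no covered preimage point found")   # unreachable for valid maps
  }, integer(1))
}

#' Hierarchical label decision
#'
#' Per brain voxel: \eqn{p^1 < 1/2 \Rightarrow 0}; else
#' \eqn{p^2 < 1/2 \Rightarrow 2}; else \eqn{p^3 < 1/2 \Rightarrow 1}; else
#' 4. Voxels outside the brain domain are 0.
#'
#' @param p1,p2,p3 probability arrays for WT, TC, ET on the brain grid.
#' @param brainMask logical array.
#' @param spacing physical voxel size for the output volume.
#' @return a label \linkS4class{VoxelVolume} over \{0,1,2,4\}.
#' @export
decideLabels <- function(p1, p2, p3, brainMask, spacing = c(1, 1, 1)) {
  m <- .asMaskArray(brainMask)
  lab <- array(0, dim(m))
  wt <- m & p1 >= 0.5
  lab[wt] <- 2
  tc <- wt & p2 >= 0.5
  lab[tc] <- 1
  lab[tc & p3 >= 0.5] <- 4
  VoxelVolume(lab, kind = "label", spacing = spacing)
}

#' Enlarged ratio of the whole-tumor region
#'
#' (WT voxel fraction among covered cube voxels) / (WT voxel fraction among
#' brain voxels) -- the magnification delivered by density-weighted OMT.
#'
#' @param brainLabels label \linkS4class{VoxelVolume}/array on the brain
#'   grid.
#' @param cubeLabels binary WT \linkS4class{CubeGrid} (phase coding: 1 on
#'   WT).
#' @param brainMask logical array of brain voxels.
#' @return scalar ratio.
#' @export
enlargedRatio <- function(brainLabels, cubeLabels, brainMask) {
  m <- .asMaskArray(brainMask)
  wtBrain <- labelRegion(brainLabels, "WT")
  nWT <- sum(wtBrain & m)
  if (nWT == 0) stop("no WT voxels in the raw data")
  rawFrac <- nWT / sum(m)
  cv <- if (is(cubeLabels, "CubeGrid")) cubeLabels@covered else
    array(TRUE, dim(cubeLabels))
  cl <- if (is(cubeLabels, "CubeGrid")) cubeLabels@data else
    as.array(cubeLabels)
  cubeFrac <- sum(cl[cv] > 0.5) / sum(cv)
  cubeFrac / rawFrac
}
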