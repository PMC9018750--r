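## Test-time-orientation ensemble voting and segmentation metrics.

.orientationNames <- c("R0", "R1", "R2", "R3", "R4")

#' Apply (or invert) a cube orientation transform
#'
#' Orientations act in the axial plane (the first two tensor axes): R0
#' identity, R1 a 90-degree counterclockwise rotation, R2 a left-right
#' mirror (first axis), R3 a top-bottom mirror (second axis), R4 the mirror
#' R2 followed by the rotation R1.
#'
#' @param a K x K x K array.
#' @param orientation one of \code{"R0"}..\code{"R4"}.
#' @param inverse apply the inverse transform.
#' @return transformed array.
#' @export
applyOrientation <- function(a, orientation = "R0", inverse = FALSE) {
  d <- dim(a)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("orientation transforms require a cubic array")
  n <- d[1]
  rotCCW <- function(x) aperm(x, c(2, 1, 3))[n:1, , , drop = FALSE]
  rotCW <- function(x) aperm(x[n:1, , , drop = FALSE], c(2, 1, 3))
  mirror1 <- function(x) x[n:1, , , drop = FALSE]
  mirror2 <- function(x) x[, n:1, , drop = FALSE]
  switch(match.arg(orientation, .orientationNames),
         R0 = a,
         R1 = if (inverse) rotCW(a) else rotCCW(a),
         R2 = mirror1(a),
         R3 = mirror2(a),
         R4 = if (inverse) mirror1(rotCW(a)) else rotCCW(mirror1(a)))
}

#' Orientation variants of a cube tensor
#'
#' @param cube \linkS4class{CubeGrid} or array.
#' @return list with \code{variants} (named list of the 5 oriented arrays)
#'   and \code{invert}, a function mapping an array in orientation mu back
#'   to the R0 frame.
#' @export
orientationVariants <- function(cube) {
  a <- if (is(cube, "CubeGrid")) cube@data else as.array(cube)
  variants <- setNames(lapply(.orientationNames, function(o)
    applyOrientation(a, o)), .orientationNames)
  list(variants = variants,
       invert = function(x, orientation)
         applyOrientation(x, orientation, inverse = TRUE))
}

#' Ensemble voting over orientation/model predictions
#'
#' All probability grids must already be mapped back to the R0 frame. Each
#' grid is binarized at 1/2 and compared (Dice) to the reference grid; the
#' grids at Dice >= \code{threshold} are averaged with equal weight. The
#' reference always votes, so the normalizer is at least 1.
#'
#' @param probSets list of probability arrays (conventionally 15: 5
#'   orientations x 3 model slots).
#' @param referenceIndex index of the reference prediction
#'   (\eqn{(\mu,\nu) = (0,1)}).
#' @param threshold Dice inclusion threshold (default 0.8).
#' @return list with \code{probability} (voted array), \code{included}
#'   (logical), \code{dice} (against the reference), \code{normalizer}.
#' @export
ensembleVote <- function(probSets, referenceIndex = 1L, threshold = 0.8) {
  stopifnot(length(probSets) >= 1L)
  bin <- lapply(probSets, function(p) p >= 0.5)
  ref <- bin[[referenceIndex]]
  dice <- vapply(bin, function(b) {
    denom <- sum(ref) + sum(b)
    if (denom == 0) 1 else 2 * sum(ref & b) / denom
  }, numeric(1))
  included <- dice >= threshold
  included[referenceIndex] <- TRUE
  N <- sum(included)
  voted <- Reduce(`+`, probSets[included]) / N
  list(probability = voted, included = included, dice = dice,
       normalizer = N)
}

#' Confusion-matrix segmentation metrics
#'
#' Dice, Sensitivity, Specificity and Precision from the voxelwise
#' confusion counts. Conventions: Dice = 1 when both sets are empty;
#' rates with empty denominators are reported as \code{NA}, never 0.
#'
#' @param GT,PD binary arrays of identical shape.
#' @return list with \code{TP}, \code{FP}, \code{FN}, \code{TN},
#'   \code{Dice}, \code{Sensitivity}, \code{Specificity}, \code{Precision}.
#' @export
confusionMetrics <- function(GT, PD) {
  gt <- as.logical(GT); pd <- as.logical(PD)
  if (length(gt) != length(pd)) stop("GT and PD shapes differ")
  tp <- sum(gt & pd); fp <- sum(!gt & pd)
  fn <- sum(gt & !pd); tn <- sum(!gt & !pd)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       Dice = dice,
       Sensitivity = rate(tp, tp + fn),
       Specificity = rate(tn, tn + fp),
       Precision = rate(tp, tp + fp))
}

# Surface voxels: set members with at least one 6-neighbor outside the set
# (array borders count as outside).
.surfaceVoxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1)] &
    pad[1:d[1], 2:(d[2]+1), 2:(d[3]+1)] & pad[3:(d[1]+2), 2:(d[2]+1), 2:(d[3]+1)] &
    pad[2:(d[1]+1), 1:d[2], 2:(d[3]+1)] & pad[2:(d[1]+1), 3:(d[2]+2), 2:(d[3]+1)] &
    pad[2:(d[1]+1), 2:(d[2]+1), 1:d[3]] & pad[2:(d[1]+1), 2:(d[2]+1), 3:(d[3]+2)]
  which(m & !interior, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric HD95 in physical units: the maximum of the two directed 95th
#' percentiles of surface-to-surface distances, surfaces being set voxels
#' with at least one 6-neighbor outside the set.
#'
#' @param GT,PD binary arrays; both must be nonempty.
#' @param spacing physical voxel size.
#' @return non-negative scalar.
#' @export
hd95 <- function(GT, PD, spacing = c(1, 1, 1)) {
  gt <- array(as.logical(GT), dim(GT)); pd <- array(as.logical(PD), dim(PD))
  if (!any(gt) || !any(pd))
    stop("HD95 is undefined for an empty set")
  sa <- sweep(.surfaceVoxels(gt), 2, spacing, "*")
  sb <- sweep(.surfaceVoxels(pd), 2, spacing, "*")
  dAB <- min_dists_cpp(sa, sb)
  dBA <- min_dists_cpp(sb, sa)
  max(quantile(dAB, 0.95, names = FALSE),
      quantile(dBA, 0.95, names = FALSE))
}

#' Dice + cross-entropy loss
#'
#' \eqn{(1 - 2\sum GT_p PD_p / \sum (GT_p + PD_p)) - \sum GT_p \log PD_p},
#' with the prediction clipped to \eqn{[\epsilon, 1]} before the logarithm.
#'
#' @param GTp,PDp probability arrays of identical shape.
#' @param eps clipping floor for the logarithm.
#' @return non-negative scalar.
#' @export
diceCELoss <- function(GTp, PDp, eps = 1e-7) {
  stopifnot(length(GTp) == length(PDp))
  diceLoss <- 1 - 2 * sum(GTp * PDp) / sum(GTp + PDp)
  ce <- -sum(GTp * log(pmin(pmax(PDp, eps), 1)))
  diceLoss + ce
}
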