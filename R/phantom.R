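## Synthetic BraTS-like subjects: a smooth perturbed-ellipsoid brain
## occupying 12-20% of the cuboid, nested tumor blobs ET < TC < WT with
## FLAIR-hyperintense WT and T1CE-hyperintense ET, and additive Gaussian
## noise -- enough signal for the density construction without any download.

#' Phantom specification
#'
#' Geometry is expressed as fractions of the grid so the brain volume
#' fraction (about 16%, inside the 12-20% band typical of skull-stripped
#' acquisitions) is resolution-independent; the default grid matches the
#' BraTS 2021 cuboid.
#'
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @param dim grid dimensions (default 240 x 240 x 155).
#' @param spacing physical voxel size.
#' @param brainAxesFrac semi-axes of the brain ellipsoid as fractions of the
#'   grid dimensions.
#' @param boundaryNoiseAmp relative amplitude of the smooth boundary
#'   perturbation.
#' @param boundaryNoiseModes number of random low-frequency modes.
#' @param tumorOffsetFrac WT center offset from the brain center, in units
#'   of the brain semi-axes.
#' @param wtFrac WT semi-axes as a fraction of the brain semi-axes.
#' @param tcFrac,etFrac TC semi-axes as a fraction of WT, and ET of TC.
#' @param intensity per-modality mean intensity for tissues
#'   \code{c(brain, edema, core, enhancing)} (rows FLAIR, T1, T1CE, T2).
#' @param noiseSD additive Gaussian noise SD inside the brain.
#' @return a list of class \code{"phantomSpec"}.
#' @export
phantomSpec <- function(seed = 1L,
                        dim = c(240L, 240L, 155L),
                        spacing = c(1, 1, 1),
                        brainAxesFrac = c(0.3875, 0.3333, 0.2968),
                        boundaryNoiseAmp = 0.03,
                        boundaryNoiseModes = 5L,
                        tumorOffsetFrac = c(0.30, -0.18, 0.12),
                        wtFrac = 0.42,
                        tcFrac = 0.70,
                        etFrac = 0.70,
                        intensity = rbind(
                          FLAIR = c(0.40, 0.80, 0.80, 0.85),
                          T1    = c(0.50, 0.45, 0.40, 0.40),
                          T1CE  = c(0.45, 0.50, 0.60, 0.90),
                          T2    = c(0.45, 0.70, 0.60, 0.60)),
                        noiseSD = 0.05) {
  spec <- list(seed = as.integer(seed), dim = as.integer(dim),
               spacing = as.numeric(spacing),
               brainAxesFrac = brainAxesFrac,
               boundaryNoiseAmp = boundaryNoiseAmp,
               boundaryNoiseModes = as.integer(boundaryNoiseModes),
               tumorOffsetFrac = tumorOffsetFrac, wtFrac = wtFrac,
               tcFrac = tcFrac, etFrac = etFrac, intensity = intensity,
               noiseSD = noiseSD)
  class(spec) <- "phantomSpec"
  spec
}

# Evaluate without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic BraTS-like subject
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{modalities} (named list of
#'   \linkS4class{VoxelVolume}s: FLAIR, T1, T1CE, T2), \code{labels}
#'   (label \linkS4class{VoxelVolume} over \{0,1,2,4\}), \code{brainMask}
#'   (logical array), and \code{spec}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7, dim = c(48, 48, 32)))
#' mean(ph$brainMask)   # about 0.16
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (spec$wtFrac >= 1)
    stop("infeasible spec: tumor semi-axes exceed the brain")
  .withSeed(spec$seed, {
    d <- spec$dim
    ax <- spec$brainAxesFrac * d
    ctr <- d / 2
    x <- (seq_len(d[1]) - 0.5 - ctr[1]) / ax[1]
    y <- (seq_len(d[2]) - 0.5 - ctr[2]) / ax[2]
    z <- (seq_len(d[3]) - 0.5 - ctr[3]) / ax[3]
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    q <- sqrt(X^2 + Y^2 + Z^2)
    eta <- array(0, d)
    for (k in seq_len(spec$boundaryNoiseModes)) {
      w <- runif(3, 1, 3) * sample(c(-1, 1), 3, replace = TRUE)
      phi <- runif(1, 0, 2 * pi)
      eta <- eta + sin(w[1] * X + w[2] * Y + w[3] * Z + phi)
    }
    eta <- spec$boundaryNoiseAmp * eta / spec$boundaryNoiseModes
    brain <- q <= 1 + eta
    ## nested tumor blobs (shared center so nesting holds by construction)
    tc0 <- spec$tumorOffsetFrac
    wtAx <- spec$wtFrac
    qt <- sqrt(((X - tc0[1]) / wtAx)^2 + ((Y - tc0[2]) / wtAx)^2 +
               ((Z - tc0[3]) / wtAx)^2)
    wt <- brain & (qt <= 1)
    tc <- brain & (qt <= spec$tcFrac)
    et <- brain & (qt <= spec$tcFrac * spec$etFrac)
    if (!any(wt)) stop("infeasible spec: tumor lies outside the brain")
    labels <- array(0, d)
    labels[wt] <- 2; labels[tc] <- 1; labels[et] <- 4
    tissue <- array(0L, d)           # 0 bg, 1 brain, 2 edema, 3 core, 4 enh
    tissue[brain] <- 1L; tissue[wt] <- 2L; tissue[tc] <- 3L; tissue[et] <- 4L
    modNames <- rownames(spec$intensity)
    modalities <- setNames(vector("list", 4), modNames)
    nb <- sum(brain)
    for (s in 1:4) {
      vol <- array(0, d)
      means <- c(0, spec$intensity[s, ])
      vol[] <- means[tissue + 1L]
      vol[brain] <- pmax(vol[brain] + rnorm(nb, 0, spec$noiseSD), 0.01)
      modalities[[s]] <- VoxelVolume(vol, kind = "modality",
                                     spacing = spec$spacing)
    }
    list(modalities = modalities,
         labels = VoxelVolume(labels, kind = "label",
                              spacing = spec$spacing),
         brainMask = brain, spec = spec)
  })
}

#' Binary region of a BraTS label volume
#'
#' @param labels label \linkS4class{VoxelVolume} or array over
#'   \{0,1,2,4\}.
#' @param region \code{"WT"} (labels \{2,1,4\}), \code{"TC"} (\{1,4\}) or
#'   \code{"ET"} (\{4\}).
#' @return logical array.
#' @export
labelRegion <- function(labels, region = c("WT", "TC", "ET")) {
  region <- match.arg(region)
  v <- if (is(labels, "VoxelVolume")) labels@data else labels
  sets <- list(WT = c(2, 1, 4), TC = c(1, 4), ET = 4)
  array(v %in% sets[[region]], dim(v))
}

#' Oracle predictor factory
#'
#' Stands in for trained networks: given the phase label cubes of a
#' subject, returns a predictor conforming to the plug-in contract
#' \code{predictor(cubes, orientation)} that emits, for each region
#' t = 1 (WT), 2 (TC), 3 (ET), the label indicator plus clipped Gaussian
#' noise, in the requested orientation frame. At \code{noiseSD = 0},
#' thresholding at 1/2 recovers the cube labels exactly.
#'
#' @param labelCubes list of 3 binary \linkS4class{CubeGrid}s (or arrays)
#'   in the R0 frame, one per region.
#' @param noiseSD non-negative noise standard deviation.
#' @param seed optional seed making the noise reproducible.
#' @return function \code{(cubes, orientation = "R0")} returning a list of
#'   3 probability arrays.
#' @export
makeOraclePredictor <- function(labelCubes, noiseSD = 0, seed = NULL) {
  stopifnot(noiseSD >= 0)
  base <- lapply(labelCubes, function(g)
    if (is(g, "CubeGrid")) g@data else as.array(g))
  force(noiseSD)
  function(cubes, orientation = "R0") {
    out <- lapply(base, function(a) applyOrientation(a, orientation))
    if (noiseSD > 0) {
      noisy <- function(a) {
        n <- if (is.null(seed)) rnorm(length(a), 0, noiseSD) else
          .withSeed(seed, rnorm(length(a), 0, noiseSD))
        array(pmin(pmax(a + n, 0), 1), dim(a))
      }
      out <- lapply(out, noisy)
    }
    out
  }
}
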