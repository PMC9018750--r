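## Two-phase pipeline orchestration and the predictor plug-in contract.
##
## Phase I maps the whole brain through the FLAIR-derived density and
## rasterizes modality cubes (plus the binary WT label cube in training
## mode). Phase II dilates the candidate WT region, builds the smoothed
## step density, refines the mesh on the region, and maps again -- the
## mass-preservation of OMT then magnifies the candidate region in the
## cube. Validation runs the predictor over five cube orientations and
## up to three model slots, votes, pulls probabilities back to the brain
## grid, and applies the hierarchical label decision.

#' Pipeline configuration
#'
#' @param gamma density exponent for a single run (in \eqn{[1,2]}).
#' @param gammaSet exponents used for training-set augmentation.
#' @param p homotopy partitions (default 11).
#' @param m dilation radius and blur kernel size in voxels (default 5).
#' @param cubeSize cube resolution (default 128; a positive multiple of 8).
#' @param refRes reference cube-boundary resolution for the A-OMT
#'   composition.
#' @param aomtIters,aomtTol spherical solver iteration cap and tolerance.
#' @param residTol interior linear-solve relative residual bound.
#' @param maxUncovered tolerated fraction of uncovered cube voxels.
#' @param training recorded (unused) network-training defaults.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(gamma = 1.0,
                           gammaSet = c(1.0, 1.5, 1.75, 2.0),
                           p = 11L, m = 5L, cubeSize = 128L, refRes = 33L,
                           aomtIters = 200L, aomtTol = 1e-7,
                           residTol = 1e-8, maxUncovered = 0.05,
                           training = list(encoderDepth = 3L,
                                           initialLearningRate = 1e-4,
                                           learningRateDropFactor = 0.95,
                                           learningRateDropPeriod = 10L,
                                           l2Regularization = 1e-4,
                                           miniBatchSize = 8L)) {
  if (p < 1) stop("p must be at least 1")
  if (m < 0 || m %% 2 == 0) stop("m must be odd and positive")
  if (cubeSize <= 0 || cubeSize %% 8 != 0)
    stop("cubeSize must be a positive multiple of 8")
  structure(list(gamma = gamma, gammaSet = gammaSet, p = as.integer(p),
                 m = as.integer(m), cubeSize = as.integer(cubeSize),
                 refRes = as.integer(refRes),
                 aomtIters = as.integer(aomtIters), aomtTol = aomtTol,
                 residTol = residTol, maxUncovered = maxUncovered,
                 training = training),
            class = "pipelineConfig")
}

.asSubject <- function(subject) {
  if (is.character(subject)) subject <- readBraTSSubject(subject)
  if (is.null(subject$brainMask)) {
    nz <- Reduce(`|`, lapply(subject$modalities, function(v)
      (if (is(v, "VoxelVolume")) v@data else v) > 0))
    subject$brainMask <- cleanupMask(nz)
  }
  if (is.null(subject$cehe))
    subject$cehe <- lapply(subject$modalities, normalizeIntensity,
                           brainMask = subject$brainMask)
  subject
}

# Shared tail of both phases: normalize, boundary A-OMT, V-OMT, rasterize.
.runOMTPhase <- function(subject, mesh, rho, config, labelSources) {
  rhoN <- rho
  mesh <- normalizeComplex(mesh, rhoN)
  gstar <- cubeBoundaryAOMT(mesh, rhoN, refRes = config$refRes,
                            maxIters = config$aomtIters,
                            tol = config$aomtTol)
  vres <- volumeOMT(mesh, rhoN, gstar, p = config$p,
                    residTol = config$residTol)
  assignment <- cubeAssignment(vres$map, mesh, config$cubeSize,
                               maxUncovered = config$maxUncovered)
  gray <- rasterizeToCube(vres$map, mesh, subject$cehe,
                          mode = "grayscale", assignment = assignment)
  labelCubes <- NULL
  if (length(labelSources))
    labelCubes <- rasterizeToCube(vres$map, mesh, labelSources,
                                  mode = "label", assignment = assignment)
  diag <- vres$diagnostics
  diag$aomt <- attr(gstar, "diagnostics")
  list(cubes = gray, labelCubes = labelCubes, mesh = mesh, rho = rhoN,
       boundaryMap = gstar, map = vres$map, assignment = assignment,
       diagnostics = diag)
}

#' Run Phase I
#'
#' Mesh the brain, build the Phase I density from the CEHE FLAIR
#' grayscale, compute the cubic V-OMT map, and rasterize the four modality
#' cubes (plus the binary WT label cube in training mode).
#'
#' @param subject a subject list (from [generatePhantom()] or
#'   [readBraTSSubject()]) or a BraTS-style directory path.
#' @param config a [pipelineConfig()].
#' @param mode \code{"train"} (labels required; emits the label cube) or
#'   \code{"infer"}.
#' @return list with \code{cubes} (4 grayscale \linkS4class{CubeGrid}s),
#'   \code{labelCubes} (train mode), \code{mesh}, \code{rho}, \code{map},
#'   \code{assignment}, \code{diagnostics}, and the augmented
#'   \code{subject}.
#' @export
runPhase1 <- function(subject, config = pipelineConfig(),
                      mode = c("train", "infer")) {
  mode <- match.arg(mode)
  subject <- .asSubject(subject)
  mesh <- buildTetMesh(subject$brainMask,
                       spacing = subject$modalities[[1]]@spacing)
  rho <- densityPhase1(subject$cehe$FLAIR, mesh, gamma = config$gamma)
  labelSources <- list()
  if (mode == "train") {
    if (is.null(subject$labels)) stop("training mode requires labels")
    labelSources <- list(WT = labelRegion(subject$labels, "WT") * 1)
  }
  out <- .runOMTPhase(subject, mesh, rho, config, labelSources)
  out$subject <- subject
  out$phase <- 1L
  out
}

#' Run Phase II
#'
#' Dilate the candidate WT region by m voxels, build the blurred step
#' density, refine the mesh on the region, recompute the V-OMT map, and
#' rasterize; training mode emits the three phase label cubes with codings
#' WT = \{2,1,4\}, TC = \{1,4\}, ET = \{4\}.
#'
#' @param subject subject list or directory (as in [runPhase1()]).
#' @param wtRegion binary candidate WT region (a Phase I prediction, or
#'   NULL to fall back to the ground-truth WT in training).
#' @param config a [pipelineConfig()].
#' @param mode \code{"train"} or \code{"infer"}.
#' @return as [runPhase1()], plus \code{region} (the dilated
#'   \eqn{\mathbb{T}}) and \code{enlargedRatio} when labels are available.
#' @export
runPhase2 <- function(subject, wtRegion = NULL, config = pipelineConfig(),
                      mode = c("train", "infer")) {
  mode <- match.arg(mode)
  subject <- .asSubject(subject)
  if (is.null(wtRegion)) {
    if (is.null(subject$labels))
      stop("wtRegion must be supplied when no labels are available")
    wtRegion <- labelRegion(subject$labels, "WT")
  }
  mesh <- buildTetMesh(subject$brainMask,
                       spacing = subject$modalities[[1]]@spacing)
  if (!any(wtRegion)) {
    warning("empty WT region; falling back to the Phase I density")
    region <- array(FALSE, dim(subject$brainMask))
    rho <- densityPhase1(subject$cehe$FLAIR, mesh, gamma = config$gamma)
  } else {
    region <- dilateMask(wtRegion, config$m) & subject$brainMask
    mesh <- refineMesh(mesh, region)
    rho <- densityPhase2(subject$cehe$FLAIR, region, mesh,
                         gamma = config$gamma, m = config$m)
  }
  labelSources <- list()
  if (mode == "train") {
    if (is.null(subject$labels)) stop("training mode requires labels")
    labelSources <- list(WT = labelRegion(subject$labels, "WT") * 1,
                         TC = labelRegion(subject$labels, "TC") * 1,
                         ET = labelRegion(subject$labels, "ET") * 1)
  }
  out <- .runOMTPhase(subject, mesh, rho, config, labelSources)
  out$subject <- subject
  out$region <- region
  out$phase <- 2L
  if (!is.null(subject$labels) && !is.null(out$labelCubes))
    out$enlargedRatio <- enlargedRatio(subject$labels, out$labelCubes$WT,
                                       subject$brainMask)
  out
}

# Validate the predictor contract on one output.
.checkPrediction <- function(pred, K) {
  if (!is.list(pred) || length(pred) != 3L)
    stop("predictor must return a list of 3 probability grids")
  for (p in pred) {
    a <- if (is(p, "CubeGrid")) p@data else p
    if (!all(dim(a) == K)) stop("predictor output has wrong dimensions")
    if (min(a) < 0 || max(a) > 1)
      stop("predictor output outside [0, 1]")
  }
  lapply(pred, function(p) if (is(p, "CubeGrid")) p@data else p)
}

#' Run validation with ensemble voting
#'
#' Executes Phase II for the subject, queries the predictor on the five
#' orientation variants for each model slot, maps all predictions back to
#' the reference frame, votes per region, pulls the voted probabilities
#' back to the brain grid, and applies the hierarchical label decision.
#' Metrics against the ground truth are computed when labels are present.
#'
#' @param subject subject list or directory.
#' @param predictor function \code{(cubes, orientation)} returning a list
#'   of 3 probability grids (WT, TC, ET) in the input's frame; or a list of
#'   up to 3 such functions (model slots).
#' @param wtRegion candidate WT region forwarded to [runPhase2()].
#' @param config a [pipelineConfig()].
#' @param ensemble use the 5-orientation ensemble (TRUE) or the single
#'   reference prediction (FALSE).
#' @param phase2 optional precomputed [runPhase2()] result for the same
#'   subject and configuration (avoids recomputing the OMT map).
#' @return list with \code{labels} (the predicted label
#'   \linkS4class{VoxelVolume}), \code{probs}, \code{metrics} (per-region
#'   data frame, when ground truth is available), \code{vote}, and
#'   \code{phase2}.
#' @export
runValidate <- function(subject, predictor, wtRegion = NULL,
                        config = pipelineConfig(), ensemble = TRUE,
                        phase2 = NULL) {
  ph2 <- if (!is.null(phase2)) phase2 else
    runPhase2(subject, wtRegion = wtRegion, config = config,
              mode = if (is.null(.asSubject(subject)$labels))
                "infer" else "train")
  subject <- ph2$subject
  predictors <- if (is.function(predictor)) list(predictor) else predictor
  K <- config$cubeSize
  grayArrays <- lapply(ph2$cubes, volumeData)
  orientations <- if (ensemble) .orientationNames else "R0"
  predSets <- vector("list", 3)   # per region t: list of prob arrays (R0)
  for (t in 1:3) predSets[[t]] <- list()
  for (nu in seq_along(predictors)) {
    for (mu in orientations) {
      oriented <- lapply(grayArrays, applyOrientation, orientation = mu)
      pred <- .checkPrediction(predictors[[nu]](oriented, mu), K)
      back <- lapply(pred, applyOrientation, orientation = mu,
                     inverse = TRUE)
      for (t in 1:3)
        predSets[[t]][[length(predSets[[t]]) + 1L]] <- back[[t]]
    }
  }
  votes <- lapply(1:3, function(t)
    ensembleVote(predSets[[t]], referenceIndex = 1L))
  pull <- pullbackProbabilities(ph2$assignment,
                                lapply(votes, `[[`, "probability"),
                                subject$brainMask)
  labels <- decideLabels(pull$probs[[1]], pull$probs[[2]], pull$probs[[3]],
                         subject$brainMask,
                         spacing = subject$modalities[[1]]@spacing)
  metrics <- NULL
  if (!is.null(subject$labels))
    metrics <- segmentationMetrics(subject$labels, labels,
                                   spacing = subject$modalities[[1]]@spacing)
  list(labels = labels, probs = pull$probs, metrics = metrics,
       vote = votes, phase2 = ph2, fallbackVoxels = pull$fallbackVoxels)
}

#' Per-region segmentation metrics table
#'
#' One row per region (WT, TC, ET) with Dice, Sensitivity, Specificity,
#' Precision and HD95.
#'
#' @param GT,PD label \linkS4class{VoxelVolume}s (or arrays) over
#'   \{0,1,2,4\}.
#' @param spacing physical voxel size for HD95.
#' @return data frame.
#' @export
segmentationMetrics <- function(GT, PD, spacing = c(1, 1, 1)) {
  rows <- lapply(c("WT", "TC", "ET"), function(r) {
    gt <- labelRegion(GT, r); pd <- labelRegion(PD, r)
    cm <- confusionMetrics(gt, pd)
    h <- tryCatch(hd95(gt, pd, spacing), error = function(e) NA_real_)
    data.frame(region = r, Dice = cm$Dice, Sensitivity = cm$Sensitivity,
               Specificity = cm$Specificity, Precision = cm$Precision,
               HD95 = h)
  })
  do.call(rbind, rows)
}
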