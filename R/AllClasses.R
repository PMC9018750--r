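#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t solve crossprod
#' @importFrom stats quantile rnorm runif sd median setNames fft
#' @importFrom utils head tail
#' @useDynLib cubeOMT, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Tetrahedral mesh of a voxelized brain domain
#'
#' A simplicial 3-complex with a single closed genus-zero boundary surface.
#' Vertex coordinates live in voxel-index space scaled by \code{spacing}
#' until \code{\link{normalizeComplex}} recenters and rescales them to
#' model units (the affine is kept in \code{center}/\code{scale} so physical
#' coordinates stay recoverable).
#'
#' @slot vertices n x 3 numeric matrix of vertex coordinates.
#' @slot tets T x 4 integer matrix of positively oriented tetrahedra
#'   (1-based vertex indices).
#' @slot boundaryFaces F x 3 integer matrix of boundary triangles, outward
#'   oriented.
#' @slot boundaryVertexIds integer vector \code{B} of vertex ids on the
#'   boundary surface.
#' @slot interiorVertexIds integer vector \code{I}, the complement of
#'   \code{B}.
#' @slot vertexVoxel n x 3 integer matrix: for each vertex, the 1-based
#'   (i,j,k) index of the voxel cell whose minimum corner it is (clamped to
#'   the grid), used to sample voxel fields at vertices.
#' @slot gridDim integer length-3: the voxel grid the mesh was built from.
#' @slot spacing numeric length-3 physical voxel size.
#' @slot center numeric length-3, translation removed by normalization
#'   (physical units).
#' @slot scale numeric scalar applied after centering.
#'
#' @seealso [buildTetMesh()], [normalizeComplex()], [refineMesh()]
#' @export
setClass("TetMesh", representation(
  vertices = "matrix",
  tets = "matrix",
  boundaryFaces = "matrix",
  boundaryVertexIds = "integer",
  interiorVertexIds = "integer",
  vertexVoxel = "matrix",
  gridDim = "integer",
  spacing = "numeric",
  center = "numeric",
  scale = "numeric"
))

setValidity("TetMesh", function(object) {
  msg <- character()
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be T x 4")
  if (nrow(object@tets) > 0) {
    if (max(object@tets) > n || min(object@tets) < 1L)
      msg <- c(msg, "tet indices out of range")
    vol <- tetVolumes(object@vertices, object@tets)
    if (any(vol <= 0))
      msg <- c(msg, sprintf("%d tetrahedra have non-positive volume",
                            sum(vol <= 0)))
  }
  ids <- sort(c(object@boundaryVertexIds, object@interiorVertexIds))
  if (length(ids) != n || any(ids != seq_len(n)))
    msg <- c(msg, "boundary/interior vertex ids must partition 1..n")
  if (length(object@spacing) != 3L) msg <- c(msg, "spacing must have length 3")
  if (length(msg)) msg else TRUE
})

#' Strictly positive per-vertex density field
#'
#' Holds the density \eqn{\rho} on mesh vertices; densities on boundary
#' triangles and tetrahedra are induced as the mean over their corner values.
#'
#' @slot values numeric vector, one strictly positive value per mesh vertex.
#' @slot gamma numeric, the exponent used to build the field (NA when not
#'   applicable).
#' @export
setClass("DensityField", representation(
  values = "numeric",
  gamma = "numeric"
))

setValidity("DensityField", function(object) {
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    "density values must be finite and strictly positive" else TRUE
})

#' Piecewise-linear map on a mesh (or its boundary)
#'
#' Stores one image point per domain vertex; images of simplices are induced
#' by barycentric coordinates.
#'
#' @slot coords k x 3 numeric matrix of image coordinates.
#' @slot vertexIds integer vector of the domain vertex ids the rows refer to.
#' @slot target character: one of "sphere" (unit 2-norm), "cubeBoundary"
#'   (max-norm 1/2), "cube", or "free".
#' @export
setClass("PLMap", representation(
  coords = "matrix",
  vertexIds = "integer",
  target = "character"
))

setValidity("PLMap", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be k x 3")
  if (nrow(object@coords) != length(object@vertexIds))
    msg <- c(msg, "coords/vertexIds length mismatch")
  if (!object@target %in% c("sphere", "cubeBoundary", "cube", "free"))
    msg <- c(msg, "unknown target")
  if (length(msg)) msg else TRUE
})

#' Scalar or label volume on the acquisition grid
#'
#' @slot data 3D numeric/integer array (e.g. 240 x 240 x 155).
#' @slot kind one of "modality", "cehe", "label", "probability", "mask".
#' @slot spacing numeric length-3 physical voxel size.
#' @export
setClass("VoxelVolume", representation(
  data = "array",
  kind = "character",
  spacing = "numeric"
))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (!object@kind %in% c("modality", "cehe", "label", "probability", "mask"))
    msg <- c(msg, "unknown kind")
  v <- object@data
  if (object@kind == "cehe" && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "cehe values must lie in [0,1]")
  if (object@kind == "probability" && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "probability values must lie in [0,1]")
  if (object@kind == "label" && !all(unique(as.vector(v)) %in% c(0, 1, 2, 4)))
    msg <- c(msg, "label values must be in {0,1,2,4}")
  if (length(msg)) msg else TRUE
})

#' Tensor on the target cube
#'
#' A K x K x K grid over the cube \eqn{[-1/2,1/2]^3}; voxel centers are
#' \code{(i - 1/2)/K - 1/2} per axis.
#'
#' @slot data K x K x K array (grayscale, binary label, or probability).
#' @slot kind one of "grayscale", "label", "probability".
#' @slot covered logical array marking cube voxels covered by the image mesh.
#' @export
setClass("CubeGrid", representation(
  data = "array",
  kind = "character",
  covered = "array"
))

setValidity("CubeGrid", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L || length(unique(d)) != 1L)
    msg <- c(msg, "cube data must be K x K x K")
  if (!object@kind %in% c("grayscale", "label", "probability"))
    msg <- c(msg, "unknown kind")
  if (object@kind == "probability" &&
      (min(object@data) < 0 || max(object@data) > 1))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@kind == "label" && !all(unique(as.vector(object@data)) %in% c(0, 1)))
    msg <- c(msg, "phase label cubes are binary 0/1")
  if (length(msg)) msg else TRUE
})

## ---- constructors -----------------------------------------------------

#' @rdname VoxelVolume-class
#' @param data 3D array.
#' @param kind volume kind.
#' @param spacing physical voxel size.
#' @export
VoxelVolume <- function(data, kind = c("modality", "cehe", "label",
                                       "probability", "mask"),
                        spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  new("VoxelVolume", data = as.array(data), kind = kind,
      spacing = as.numeric(spacing))
}

#' @rdname CubeGrid-class
#' @param data K x K x K array.
#' @param kind grid kind.
#' @param covered logical array of covered voxels (defaults to all TRUE).
#' @export
CubeGrid <- function(data, kind = c("grayscale", "label", "probability"),
                     covered = NULL) {
  kind <- match.arg(kind)
  if (is.null(covered)) covered <- array(TRUE, dim(data))
  new("CubeGrid", data = as.array(data), kind = kind, covered = covered)
}

## ---- accessors --------------------------------------------------------

#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @export
setGeneric("tets", function(x) standardGeneric("tets"))
#' @export
setGeneric("boundaryFaces", function(x) standardGeneric("boundaryFaces"))
#' @export
setGeneric("boundaryVertexIds", function(x) standardGeneric("boundaryVertexIds"))
#' @export
setGeneric("interiorVertexIds", function(x) standardGeneric("interiorVertexIds"))
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @export
setGeneric("nTets", function(x) standardGeneric("nTets"))
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @export
setGeneric("mapCoords", function(x) standardGeneric("mapCoords"))
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @describeIn TetMesh-class vertex coordinate matrix.
#' @param x object.
#' @export
setMethod("vertices", "TetMesh", function(x) x@vertices)
#' @describeIn TetMesh-class tetrahedron index matrix.
#' @export
setMethod("tets", "TetMesh", function(x) x@tets)
#' @describeIn TetMesh-class boundary triangle index matrix.
#' @export
setMethod("boundaryFaces", "TetMesh", function(x) x@boundaryFaces)
#' @describeIn TetMesh-class boundary vertex id set B.
#' @export
setMethod("boundaryVertexIds", "TetMesh", function(x) x@boundaryVertexIds)
#' @describeIn TetMesh-class interior vertex id set I.
#' @export
setMethod("interiorVertexIds", "TetMesh", function(x) x@interiorVertexIds)
#' @describeIn TetMesh-class number of vertices.
#' @export
setMethod("nVertices", "TetMesh", function(x) nrow(x@vertices))
#' @describeIn TetMesh-class number of tetrahedra.
#' @export
setMethod("nTets", "TetMesh", function(x) nrow(x@tets))
#' @describeIn DensityField-class per-vertex density values.
#' @export
setMethod("densityValues", "DensityField", function(x) x@values)
#' @describeIn PLMap-class image coordinate matrix.
#' @export
setMethod("mapCoords", "PLMap", function(x) x@coords)
#' @describeIn VoxelVolume-class the underlying array.
#' @export
setMethod("volumeData", "VoxelVolume", function(x) x@data)
#' @describeIn CubeGrid-class the underlying array.
#' @export
setMethod("volumeData", "CubeGrid", function(x) x@data)

## ---- show methods -----------------------------------------------------

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d vertices, %d tets, %d boundary faces (%d boundary vertices)\n",
              nrow(object@vertices), nrow(object@tets),
              nrow(object@boundaryFaces), length(object@boundaryVertexIds)))
  cat(sprintf("  grid %s, spacing %s, scale %.4g\n",
              paste(object@gridDim, collapse = "x"),
              paste(signif(object@spacing, 3), collapse = "x"),
              object@scale))
  invisible(NULL)
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField: %d vertices, range [%.4g, %.4g], gamma = %s\n",
              length(object@values), min(object@values), max(object@values),
              format(object@gamma)))
  invisible(NULL)
})

setMethod("show", "PLMap", function(object) {
  cat(sprintf("PLMap onto %s: %d vertices\n", object@target,
              nrow(object@coords)))
  invisible(NULL)
})

setMethod("show", "VoxelVolume", function(object) {
  cat(sprintf("VoxelVolume (%s): %s, range [%.4g, %.4g]\n", object@kind,
              paste(dim(object@data), collapse = "x"),
              min(object@data), max(object@data)))
  invisible(NULL)
})

setMethod("show", "CubeGrid", function(object) {
  cat(sprintf("CubeGrid (%s): %s, %.1f%% covered\n", object@kind,
              paste(dim(object@data), collapse = "x"),
              100 * mean(object@covered)))
  invisible(NULL)
})
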