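## NIfTI input/output (RNifti) and plain-text exports.

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param kind volume kind (see \linkS4class{VoxelVolume}).
#' @return a \linkS4class{VoxelVolume}.
#' @export
readVolumeNifti <- function(path, kind = "modality") {
  img <- RNifti::readNifti(path)
  VoxelVolume(array(as.numeric(img), dim(img)[1:3]), kind = kind,
              spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume to NIfTI
#'
#' @param volume \linkS4class{VoxelVolume} or 3D array.
#' @param path output file.
#' @param template optional NIfTI image or path supplying header geometry.
#' @export
writeVolumeNifti <- function(volume, path, template = NULL) {
  v <- if (is(volume, "VoxelVolume")) volume@data else as.array(volume)
  sp <- if (is(volume, "VoxelVolume")) volume@spacing else c(1, 1, 1)
  img <- if (is.null(template)) {
    RNifti::asNifti(v, pixdim = sp)
  } else RNifti::asNifti(v, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom (or any subject) as a BraTS-style directory
#'
#' Four modality files and, when labels are present, one segmentation file,
#' following the BraTS naming layout.
#'
#' @param subject list with \code{modalities} (FLAIR, T1, T1CE, T2) and
#'   optionally \code{labels}.
#' @param dir output directory (created).
#' @param id subject identifier used in file names.
#' @return the directory, invisibly.
#' @export
writeBraTSSubject <- function(subject, dir, id = "SYNTH001") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- c(FLAIR = "flair", T1 = "t1", T1CE = "t1ce", T2 = "t2")
  for (s in names(suffix))
    writeVolumeNifti(subject$modalities[[s]],
                     file.path(dir, sprintf("%s_%s.nii.gz", id, suffix[s])))
  if (!is.null(subject$labels))
    writeVolumeNifti(subject$labels,
                     file.path(dir, sprintf("%s_seg.nii.gz", id)))
  invisible(dir)
}

#' Read a BraTS-style subject directory
#'
#' @param dir directory containing \code{*_flair/t1/t1ce/t2.nii(.gz)} and
#'   optionally \code{*_seg.nii(.gz)}.
#' @return subject list as in [generatePhantom()] (without
#'   \code{brainMask}).
#' @export
readBraTSSubject <- function(dir) {
  find1 <- function(sfx) {
    f <- list.files(dir, pattern = sprintf("_%s\\.nii(\\.gz)?$", sfx),
                    full.names = TRUE)
    if (length(f) != 1L)
      stop(sprintf("expected exactly one *_%s.nii[.gz] in %s", sfx, dir))
    f
  }
  modalities <- list(
    FLAIR = readVolumeNifti(find1("flair")),
    T1 = readVolumeNifti(find1("t1")),
    T1CE = readVolumeNifti(find1("t1ce")),
    T2 = readVolumeNifti(find1("t2")))
  seg <- list.files(dir, pattern = "_seg\\.nii(\\.gz)?$", full.names = TRUE)
  labels <- if (length(seg) == 1L) readVolumeNifti(seg, kind = "label")
            else NULL
  list(modalities = modalities, labels = labels)
}

#' Export a mesh (with optional per-vertex attributes) as plain text
#'
#' A simple unstructured-mesh format: a header line, vertex lines
#' (\code{v x y z [attributes]}) and tetrahedron lines
#' (\code{t i j k l}).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param path output file.
#' @param attributes optional named list of per-vertex numeric vectors
#'   (e.g. a density or map coordinates).
#' @export
writeMeshText <- function(mesh, path, attributes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  attrMat <- if (is.null(attributes)) NULL else do.call(cbind, attributes)
  writeLines(sprintf("# tetmesh %d vertices %d tets%s", nVertices(mesh),
                     nTets(mesh),
                     if (is.null(attrMat)) "" else
                       paste0(" attributes ",
                              paste(names(attributes), collapse = " "))),
             con)
  V <- mesh@vertices
  if (!is.null(attrMat)) V <- cbind(V, attrMat)
  writeLines(paste("v", apply(format(V, digits = 10), 1, paste,
                              collapse = " ")), con)
  writeLines(paste("t", apply(mesh@tets, 1, paste, collapse = " ")), con)
  invisible(path)
}

#' Serialize a diagnostics report to JSON
#'
#' @param diagnostics list (e.g. from [volumeOMT()]).
#' @param path output file.
#' @export
writeDiagnosticsJSON <- function(diagnostics, path) {
  keep <- diagnostics[!vapply(diagnostics, is.function, logical(1))]
  ## summarize long vectors as five-number summaries
  keep <- lapply(keep, function(x) {
    if (is.numeric(x) && length(x) > 32)
      list(mean = mean(x), sd = sd(x), min = min(x),
           q25 = unname(quantile(x, 0.25)), median = median(x),
           q75 = unname(quantile(x, 0.75)), max = max(x))
    else x
  })
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
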