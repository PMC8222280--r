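## Readers/writers (NIfTI-1 + JSON sidecars) and geometry arithmetic.
## Dynamic series live on disk as one NIfTI per frame plus a JSON sidecar
## {times_s, n_precontrast, frames}; this avoids 4D-NIfTI dialect ambiguity.

niftiToArray <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

niftiGeometry <- function(img) {
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  org <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  list(spacing = sp, origin = org)
}

asNiftiWithGeometry <- function(values, spacing, origin) {
  img <- RNifti::asNifti(values)
  nd <- length(dim(values))
  RNifti::pixdim(img) <- if (nd == 3L) spacing else c(spacing, 1)
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  img
}

#' Load a 3D scalar NIfTI volume
#'
#' @param path path to a \code{.nii} / \code{.nii.gz} file holding a 3D
#'   scalar image (HU, Gy or unitless). 4D payloads are rejected: vector
#'   displacement fields go through \code{\link{loadField}}.
#' @return An \linkS4class{ImageGrid} with spacing/origin from the header.
#' @export
loadVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D scalar volume, got %dD payload in %s",
                 length(d), path))
  g <- niftiGeometry(img)
  ImageGrid(niftiToArray(img), spacing = g$spacing, origin = g$origin)
}

#' Save an ImageGrid as a 3D NIfTI volume
#'
#' Values round-trip bit-for-bit (float64 payload); geometry round-trips
#' within header precision. Non-finite values are refused.
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
saveVolume <- function(grid, path) {
  stopifnot(is(grid, "ImageGrid"))
  if (any(!is.finite(grid@values)))
    stop("refusing to save a volume containing non-finite values")
  v <- grid@values
  storage.mode(v) <- "double"
  RNifti::writeNifti(asNiftiWithGeometry(v, grid@spacing, grid@origin),
                     path, datatype = "double")
  invisible(path)
}

#' Save / load a BinaryMask as a uint8 0/1 NIfTI volume
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path file path.
#' @return \code{saveMask}: \code{path} invisibly; \code{loadMask}: a
#'   \linkS4class{BinaryMask} (any nonzero voxel is true).
#' @export
saveMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  storage.mode(v) <- "integer"
  RNifti::writeNifti(asNiftiWithGeometry(v, mask@spacing, mask@origin),
                     path, datatype = "uint8")
  invisible(path)
}

#' @rdname saveMask
#' @export
loadMask <- function(path) {
  g <- loadVolume(path)
  BinaryMask(g@values != 0, spacing = g@spacing, origin = g@origin)
}

#' Load / save a 3-component displacement field
#'
#' Stored as a 4D NIfTI whose 4th dimension holds the (x, y, z)
#' displacement components in mm.
#'
#' @param path file path.
#' @param field a \linkS4class{VectorField}.
#' @return \code{loadField}: a \linkS4class{VectorField}.
#' @export
loadField <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 3-component 4D vector image, got dims [",
         paste(d, collapse = ", "), "] in ", path)
  g <- niftiGeometry(img)
  VectorField(niftiToArray(img), spacing = g$spacing, origin = g$origin)
}

#' @rdname loadField
#' @export
saveField <- function(field, path) {
  stopifnot(is(field, "VectorField"))
  u <- field@u
  storage.mode(u) <- "double"
  RNifti::writeNifti(asNiftiWithGeometry(u, field@spacing, field@origin),
                     path, datatype = "double")
  invisible(path)
}

#' Save / load a DynamicSeries (NIfTI frames + JSON sidecar)
#'
#' \code{saveSeries} writes \code{frame_0001.nii.gz} ... into \code{dir}
#' plus \code{series.json} with fields \code{times_s}, \code{n_precontrast}
#' and \code{frames}. \code{loadSeries} accepts the directory or the
#' sidecar path.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param dir output directory (created if absent).
#' @param path directory or \code{series.json} path.
#' @return \code{saveSeries}: sidecar path invisibly; \code{loadSeries}:
#'   a \linkS4class{DynamicSeries}.
#' @export
saveSeries <- function(series, dir) {
  stopifnot(is(series, "DynamicSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nFrames(series)
  files <- sprintf("frame_%04d.nii.gz", seq_len(n))
  for (i in seq_len(n)) {
    saveVolume(seriesFrame(series, i), file.path(dir, files[i]))
  }
  sidecar <- file.path(dir, "series.json")
  jsonlite::write_json(
    list(times_s = seriesTimes(series),
         n_precontrast = nPrecontrast(series),
         frames = files),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname saveSeries
#' @export
loadSeries <- function(path) {
  sidecar <- if (dir.exists(path)) file.path(path, "series.json") else path
  if (!file.exists(sidecar)) stop("series sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  base <- dirname(sidecar)
  frames <- lapply(file.path(base, meta$frames), loadVolume)
  DynamicSeries(frames, times = meta$times_s,
                nPrecontrast = meta$n_precontrast)
}

#' Mask volume in cc
#'
#' Exact: \code{count(true) * voxel_volume_mm3 / 1000}. Additive over
#' disjoint masks. The 30 cc floor for dose-bin statistics is expressed in
#' these units.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return volume in cubic centimetres.
#' @examples
#' m <- BinaryMask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' maskVolumeCc(m)  # 1 cc
#' @export
maskVolumeCc <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@values) * prod(mask@spacing) / 1000
}

#' Assert that two grid-like objects share one geometry
#'
#' No-op when shape, spacing and origin match within 1e-4 mm; otherwise
#' raises an error naming the differing field. The pipeline performs no
#' implicit resampling: voxel-wise comparisons presuppose registered,
#' common-grid data.
#'
#' @param a,b \linkS4class{ImageGrid}, \linkS4class{BinaryMask} or
#'   \linkS4class{VectorField} objects.
#' @return invisibly TRUE on success.
#' @export
assertSameGeometry <- function(a, b) {
  da <- gridDim(a)
  db <- gridDim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("geometry mismatch: shape differs ([",
         paste(da, collapse = ","), "] vs [", paste(db, collapse = ","), "])")
  if (max(abs(gridSpacing(a) - gridSpacing(b))) > GEOM_TOL_MM)
    stop("geometry mismatch: spacing differs (",
         paste(gridSpacing(a), collapse = ","), " vs ",
         paste(gridSpacing(b), collapse = ","), " mm)")
  if (max(abs(gridOrigin(a) - gridOrigin(b))) > GEOM_TOL_MM)
    stop("geometry mismatch: origin differs (",
         paste(gridOrigin(a), collapse = ","), " vs ",
         paste(gridOrigin(b), collapse = ","), " mm)")
  invisible(TRUE)
}
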