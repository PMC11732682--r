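#' @include AllClasses.R
NULL

.read_nifti_array <- function(path, what) {
  if (!file.exists(path)) stopData("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stopData("unreadable NIfTI header: ",
                                               path, " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # strip the niftiImage class
  list(img = img, arr = arr)
}

#' Read a 3-D volume from NIfTI
#'
#' Reads a single-channel 3-D NIfTI file (.nii or .nii.gz), preserving voxel
#' spacing and the voxel-to-world affine.
#'
#' @param path path to a NIfTI file.
#' @return A \linkS4class{Volume}.
#' @export
readVolume <- function(path) {
  r <- .read_nifti_array(path, "volume")
  if (length(dim(r$arr)) != 3L)
    stopData("not a 3-D volume: ", path, " has ", length(dim(r$arr)), " dimensions")
  Volume(r$arr, spacing = unname(RNifti::pixdim(r$img))[1:3],
         affine = unclass2affine(RNifti::xform(r$img)))
}

unclass2affine <- function(x) {
  m <- matrix(as.numeric(x), 4, 4)
  m
}

.as_nifti <- function(data, spacing, affine) {
  img <- RNifti::asNifti(data)
  RNifti::`pixdim<-`(img, spacing) -> img
  if (!is.null(affine))
    RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  img
}

#' Write a Volume to NIfTI
#'
#' @param vol a \linkS4class{Volume}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume"))
  RNifti::writeNifti(.as_nifti(vol@data, vol@spacing, vol@affine), path)
  invisible(path)
}

#' Read a label map from NIfTI
#'
#' @param path path to a NIfTI file of integer class ids.
#' @param classes the declared class set; voxels outside it are an error.
#' @return A \linkS4class{LabelMap}.
#' @export
readLabels <- function(path, classes = unname(TISSUE_CLASSES)) {
  r <- .read_nifti_array(path, "labels")
  if (length(dim(r$arr)) != 3L)
    stopData("not a 3-D volume: ", path)
  arr <- round(r$arr)
  if (!all(arr %in% classes))
    stopData("label file contains values outside the class set: ", path)
  LabelMap(arr, classes = classes)
}

#' Write a LabelMap to NIfTI (unsigned 8-bit)
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param path output path.
#' @param spacing voxel spacing to record, default 1 mm isotropic.
#' @param affine optional affine to record.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(is(labels, "LabelMap"))
  RNifti::writeNifti(.as_nifti(labels@data, spacing, affine), path,
                     datatype = "uint8")
  invisible(path)
}

#' Read a displacement field from 4-D NIfTI
#'
#' The convention is a 4-D image whose last axis holds the x, y, z vector
#' components in voxel units on the fixed grid.
#'
#' @param path path to a 4-D NIfTI file.
#' @return A \linkS4class{DisplacementField}.
#' @export
readField <- function(path) {
  r <- .read_nifti_array(path, "field")
  d <- dim(r$arr)
  if (length(d) != 4L || d[4] != 3L)
    stopData("not a displacement field (need 4-D with 3 components): ", path)
  DisplacementField(r$arr)
}

#' Write a displacement field as 4-D NIfTI
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  RNifti::writeNifti(RNifti::asNifti(field@vectors), path)
  invisible(path)
}

#' Crop a volume to its foreground bounding box
#'
#' Finds the tight bounding box of voxels with intensity above
#' \code{threshold} (the assumption is skull-stripped input where non-brain
#' voxels are zero), expands it by \code{margin} voxels and clips to the
#' grid. A companion label map is cropped with the same box.
#'
#' @param vol a \linkS4class{Volume}.
#' @param labels optional companion \linkS4class{LabelMap}.
#' @param margin margin in voxels added on every side (default 2).
#' @param threshold foreground intensity threshold (default 0, strict).
#' @return A list with elements \code{volume} and (if given) \code{labels}.
#' @export
cropToForeground <- function(vol, labels = NULL, margin = 2, threshold = 0) {
  stopifnot(is(vol, "Volume"))
  fg <- vol@data > threshold
  if (!any(fg)) stopData("cannot crop: volume is entirely background")
  idx <- which(fg, arr.ind = TRUE)
  d <- dim(vol@data)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  out <- Volume(vol@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                spacing = vol@spacing, affine = vol@affine)
  res <- list(volume = out, box = rbind(lo = lo, hi = hi))
  if (!is.null(labels)) {
    if (!sameDim3(labels@data, vol@data))
      stopUsage("labels shape does not match volume")
    res$labels <- LabelMap(
      labels@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
      classes = labels@classes)
  }
  res
}

# Align-corners resampling positions: output index i (1..n) samples source
# position 1 + (i-1)*(m-1)/(n-1), so an identity-size resize is exact.
resampleCoords <- function(fromDims, toDims) {
  ax <- lapply(1:3, function(a) {
    n <- toDims[a]; m <- fromDims[a]
    if (n == 1L) rep(1 + (m - 1) / 2, 1) else 1 + (seq_len(n) - 1) * (m - 1) / (n - 1)
  })
  cbind(rep.int(ax[[1]], toDims[2] * toDims[3]),
        rep.int(rep(ax[[2]], each = toDims[1]), toDims[3]),
        rep(ax[[3]], each = toDims[1] * toDims[2]))
}

#' Resize a volume to an isotropic cube
#'
#' Intensities are resampled with trilinear interpolation (voxel-centre,
#' align-corners convention, so an identity resize is exact); labels with
#' nearest-neighbour. Spacing is rescaled to preserve physical extent.
#'
#' @param vol a \linkS4class{Volume}.
#' @param n target side length (>= 2).
#' @param labels optional companion \linkS4class{LabelMap}.
#' @return A list with elements \code{volume} and (if given) \code{labels}.
#' @export
resizeToCube <- function(vol, n, labels = NULL) {
  stopifnot(is(vol, "Volume"))
  if (!is.numeric(n) || n < 2) stopUsage("target size must be >= 2")
  n <- as.integer(n)
  d <- dim(vol@data)
  co <- resampleCoords(d, c(n, n, n))
  arr <- array(cpp_trilinear_gather(vol@data, c(d, 1L), co), dim = c(n, n, n))
  sp <- vol@spacing * (d - 1) / max(n - 1, 1)
  res <- list(volume = Volume(arr, spacing = sp, affine = vol@affine))
  if (!is.null(labels)) {
    if (!sameDim3(labels@data, vol@data))
      stopUsage("labels shape does not match volume")
    larr <- array(as.integer(
      cpp_nearest_gather(labels@data + 0.0, c(d, 1L), co)), dim = c(n, n, n))
    res$labels <- LabelMap(larr, classes = labels@classes)
  }
  res
}

#' Min-max normalize a volume to [0, 1]
#'
#' @param vol a \linkS4class{Volume}; must not be constant.
#' @return The rescaled \linkS4class{Volume}.
#' @export
normalizeIntensity <- function(vol) {
  stopifnot(is(vol, "Volume"))
  r <- range(vol@data)
  if (r[1] == r[2])
    stopData("cannot normalize a constant volume (undefined rescale)")
  Volume((vol@data - r[1]) / (r[2] - r[1]), spacing = vol@spacing,
         affine = vol@affine)
}

#' Standard preprocessing: crop, resize, normalize
#'
#' Applies foreground cropping, isotropic resizing and min-max intensity
#' normalization in sequence, the preprocessing expected by the registration
#' model.
#'
#' @param vol a \linkS4class{Volume}.
#' @param labels optional companion \linkS4class{LabelMap}.
#' @param size target cube side (default 128).
#' @param margin crop margin in voxels.
#' @return list with \code{volume} and optional \code{labels}.
#' @export
preprocessVolume <- function(vol, labels = NULL, size = 128, margin = 2) {
  cr <- cropToForeground(vol, labels, margin = margin)
  rs <- resizeToCube(cr$volume, size, cr$labels)
  rs$volume <- normalizeIntensity(rs$volume)
  rs
}
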