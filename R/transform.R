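#' @include AllClasses.R
NULL

.as_field_array <- function(field) {
  if (is(field, "DisplacementField")) field@vectors else field
}

# Internal warp on raw arrays; the exported warpVolume/warpLabels wrap it.
# `boundary = "clamp"` replicates the border voxel for out-of-domain
# samples; "zero" fills them with 0.
warpArray <- function(moving, phi, interpolation = "linear",
                      boundary = "clamp") {
  d <- dim(moving)
  co <- gridCoords(d) + matrix(phi, ncol = 3)
  if (interpolation == "linear") {
    out <- cpp_trilinear_gather(moving, c(d, 1L), co)
  } else if (interpolation == "nearest") {
    out <- cpp_nearest_gather(moving, c(d, 1L), co)
  } else stopUsage("unknown interpolation mode: ", interpolation)
  if (boundary == "zero") {
    oob <- co[, 1] < 1 | co[, 1] > d[1] | co[, 2] < 1 | co[, 2] > d[2] |
           co[, 3] < 1 | co[, 3] > d[3]
    out[oob] <- 0
  } else if (boundary != "clamp") stopUsage("unknown boundary policy: ", boundary)
  bumpWarpCount()
  array(out, dim = d)
}

#' Warp a volume by a displacement field
#'
#' Samples the moving image at x + phi(x) for every fixed-grid voxel x,
#' with trilinear (default) or nearest-neighbour interpolation.
#' Out-of-domain samples replicate the border voxel by default ("clamp"),
#' avoiding dark halos at the brain edge; set \code{boundary = "zero"} for
#' zero filling.
#'
#' @param moving a \linkS4class{Volume}.
#' @param field a \linkS4class{DisplacementField} of matching shape.
#' @param interpolation "linear" or "nearest".
#' @param boundary "clamp" (default) or "zero".
#' @return The warped \linkS4class{Volume}.
#' @export
warpVolume <- function(moving, field, interpolation = "linear",
                       boundary = "clamp") {
  stopifnot(is(moving, "Volume"))
  phi <- .as_field_array(field)
  if (!sameDim3(moving@data, phi))
    stopUsage("volume and field shapes do not match")
  Volume(warpArray(moving@data, phi, interpolation, boundary),
         spacing = moving@spacing, affine = moving@affine)
}

#' Propagate a label map through a displacement field
#'
#' Nearest-neighbour warp; the output can only contain classes present in
#' the input.
#'
#' @param movingLabels a \linkS4class{LabelMap}.
#' @param field a \linkS4class{DisplacementField} of matching shape.
#' @return The propagated \linkS4class{LabelMap}.
#' @export
warpLabels <- function(movingLabels, field) {
  stopifnot(is(movingLabels, "LabelMap"))
  phi <- .as_field_array(field)
  if (!sameDim3(movingLabels@data, phi))
    stopUsage("labels and field shapes do not match")
  arr <- warpArray(movingLabels@data + 0.0, phi, "nearest")
  LabelMap(arr, classes = movingLabels@classes)
}

.check_field_list <- function(fields) {
  if (length(fields) == 0) stopUsage("empty field list")
  arrs <- lapply(fields, .as_field_array)
  d1 <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d1), TRUE)))
    stopUsage("all fields must have equal shape")
  arrs
}

#' Accumulate partial displacement fields
#'
#' Voxel-wise vector sum of the partial fields, the accumulation rule of the
#' cascade: the moving image is always resampled once, from its original
#' intensities, by the running sum.
#'
#' @param fields list of \linkS4class{DisplacementField} (cascade order).
#' @return The summed \linkS4class{DisplacementField}.
#' @export
accumulateFields <- function(fields) {
  arrs <- .check_field_list(fields)
  DisplacementField(Reduce(`+`, arrs))
}

#' Compose displacement fields functionally
#'
#' Functional composition of the warps in cascade order (the first field is
#' applied to the moving image first): with c the running composition,
#' result(x) = phi_i(x + c(x)) + c(x), built right-to-left by trilinear
#' sampling. Equals accumulation when all fields are spatially constant.
#'
#' @param fields list of \linkS4class{DisplacementField} (cascade order).
#' @return The composed \linkS4class{DisplacementField}.
#' @export
composeFields <- function(fields) {
  arrs <- .check_field_list(fields)
  n <- length(arrs)
  comp <- arrs[[n]]
  d <- dim(comp)[1:3]
  if (n > 1) for (i in (n - 1):1) {
    co <- gridCoords(d) + matrix(comp, ncol = 3)
    sampled <- cpp_trilinear_gather(arrs[[i]], c(d, 3L), co)
    comp <- comp + array(sampled, dim = c(d, 3L))
  }
  DisplacementField(comp)
}

#' Jacobian determinant analysis of a transformation
#'
#' Computes det(I + grad(phi)) by central differences at interior voxels
#' (border voxels are excluded: one-sided differences inflate folding
#' estimates) and the percentage of interior voxels with negative
#' determinant, the standard folding measure.
#'
#' @param field a \linkS4class{DisplacementField}, at least 3 voxels per
#'   axis.
#' @return A \linkS4class{JacobianReport}.
#' @export
jacobianReport <- function(field) {
  phi <- .as_field_array(field)
  d <- dim(phi)[1:3]
  if (any(d < 3)) stopUsage("field must be at least 3 voxels per axis")
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); ll <- 2:(d[3] - 1)
  g <- function(comp, axis) {
    a <- phi[, , , comp]
    switch(axis,
      (a[ii + 1, jj, ll] - a[ii - 1, jj, ll]) / 2,
      (a[ii, jj + 1, ll] - a[ii, jj - 1, ll]) / 2,
      (a[ii, jj, ll + 1] - a[ii, jj, ll - 1]) / 2)
  }
  J11 <- 1 + g(1, 1); J12 <- g(1, 2); J13 <- g(1, 3)
  J21 <- g(2, 1); J22 <- 1 + g(2, 2); J23 <- g(2, 3)
  J31 <- g(3, 1); J32 <- g(3, 2); J33 <- 1 + g(3, 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  new("JacobianReport", detMap = det,
      negFraction = 100 * mean(det < 0))
}

#' Export a Jacobian report
#'
#' Writes the interior determinant map as NIfTI and a JSON summary with the
#' negative-determinant percentage.
#'
#' @param report a \linkS4class{JacobianReport}.
#' @param detPath output NIfTI path for the determinant map.
#' @param jsonPath output JSON path for the summary.
#' @return invisibly, a list with the written paths.
#' @export
writeJacobianReport <- function(report, detPath, jsonPath) {
  RNifti::writeNifti(RNifti::asNifti(report@detMap), detPath)
  jsonlite::write_json(
    list(neg_fraction_pct = report@negFraction,
         det_min = min(report@detMap), det_max = max(report@detMap),
         det_mean = mean(report@detMap)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(list(det = detPath, json = jsonPath))
}
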