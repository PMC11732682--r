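#' @include utils.R
NULL

# Tissue labelling convention used throughout: 0 = background plus seven
# tissue classes (CSF, cortical grey matter, white matter, ventricles,
# cerebellum, thalamus, brain stem).
TISSUE_CLASSES <- c(background = 0L, CSF = 1L, CGM = 2L, WM = 3L,
                    VTC = 4L, CRB = 5L, THA = 6L, BS = 7L)

#' 3-D scalar intensity volume
#'
#' A single-channel volume on a regular grid, with per-axis voxel spacing in
#' millimetres and an optional 4x4 voxel-to-world affine carried through
#' NIfTI I/O.
#'
#' @slot data 3-D numeric array (H x W x L).
#' @slot spacing numeric(3), voxel size per axis in mm.
#' @slot affine 4x4 matrix or NULL.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", affine = "ANY"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-D array")
    if (any(d < 2L)) return("every axis must have length >= 2")
    if (!is.numeric(object@data)) return("data must be numeric")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite values")
    if (!is.null(object@affine) &&
        !(is.matrix(object@affine) && all(dim(object@affine) == c(4L, 4L))))
      return("affine must be NULL or a 4x4 matrix")
    TRUE
  })

#' Construct a Volume
#'
#' @param data 3-D numeric array.
#' @param spacing voxel size per axis (mm), default isotropic 1 mm.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return A \linkS4class{Volume}.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing), affine = affine)
}

#' 3-D integer label map
#'
#' @slot data 3-D integer array, same shape as its companion volume.
#' @slot classes ordered integer label ids; 0 is background.
#' @export
setClass("LabelMap",
  representation(data = "array", classes = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-D array")
    if (!all(object@data %in% object@classes))
      return("every voxel value must be one of the declared classes")
    if (0L %in% object@classes && object@classes[1] != 0L)
      return("background class 0 must come first")
    TRUE
  })

#' Construct a LabelMap
#'
#' @param data 3-D array of integer class ids.
#' @param classes the full ordered class set (default background + 7 tissues).
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(data, classes = unname(TISSUE_CLASSES)) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, classes = as.integer(classes))
}

#' Dense displacement field
#'
#' Grid of 3-vectors in voxel units on the fixed grid. The warping
#' convention is output(x) = moving sampled at x + phi(x).
#'
#' @slot vectors 4-D numeric array (H x W x L x 3).
#' @export
setClass("DisplacementField",
  representation(vectors = "array"),
  validity = function(object) {
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4] != 3L)
      return("vectors must be a 4-D array with 3 components on the last axis")
    if (any(!is.finite(object@vectors)))
      return("field values must be finite")
    TRUE
  })

#' Construct a DisplacementField
#'
#' @param vectors 4-D array (H x W x L x 3) of voxel-unit displacements.
#' @return A \linkS4class{DisplacementField}.
#' @export
DisplacementField <- function(vectors) {
  storage.mode(vectors) <- "double"
  new("DisplacementField", vectors = vectors)
}

#' Jacobian folding report
#'
#' Determinants of I + grad(phi) at interior voxels (central differences)
#' and the percentage of interior voxels with negative determinant.
#'
#' @slot detMap 3-D array of determinants over the interior grid.
#' @slot negFraction percentage of interior voxels with determinant < 0.
#' @export
setClass("JacobianReport",
  representation(detMap = "array", negFraction = "numeric"),
  validity = function(object) {
    if (object@negFraction < 0 || object@negFraction > 100)
      return("negFraction must lie in [0, 100]")
    TRUE
  })

#' Set of annotated atlas images
#'
#' @slot volumes list of \linkS4class{Volume}.
#' @slot labels list of \linkS4class{LabelMap}, aligned with volumes.
#' @slot meta data.frame of per-atlas metadata (e.g. an age covariate).
#' @export
setClass("AtlasSet",
  representation(volumes = "list", labels = "list", meta = "data.frame"),
  validity = function(object) {
    if (length(object@volumes) != length(object@labels))
      return("volumes and labels must have equal length")
    if (!all(vapply(object@volumes, is, TRUE, "Volume")))
      return("volumes must all be Volume objects")
    if (!all(vapply(object@labels, is, TRUE, "LabelMap")))
      return("labels must all be LabelMap objects")
    cls <- lapply(object@labels, function(l) l@classes)
    if (length(cls) > 1 && !all(vapply(cls, identical, TRUE, cls[[1]])))
      return("all atlases must share the same class set")
    if (nrow(object@meta) > 0 && nrow(object@meta) != length(object@volumes))
      return("meta must have one row per atlas")
    TRUE
  })

#' Construct an AtlasSet
#'
#' @param volumes list of \linkS4class{Volume}.
#' @param labels list of \linkS4class{LabelMap}.
#' @param meta optional data.frame of per-atlas metadata.
#' @return An \linkS4class{AtlasSet}.
#' @export
AtlasSet <- function(volumes, labels, meta = data.frame()) {
  new("AtlasSet", volumes = volumes, labels = labels, meta = meta)
}

#' Cascaded registration model
#'
#' Holds the per-cascade network parameters (cascades do not share weights),
#' the cascade/backbone/loss configuration, and the training history.
#'
#' @slot params list with one parameter set per cascade.
#' @slot cascade cascade configuration (see \code{\link{cascadeConfig}}).
#' @slot loss loss configuration (see \code{\link{lossConfig}}).
#' @slot history list with training metadata (epoch log, best epoch, ...).
#' @export
setClass("CascadeModel",
  representation(params = "list", cascade = "list", loss = "list",
                 history = "list"))

# ---- accessors ----

#' @describeIn Volume the raw intensity array.
#' @param x object.
#' @export
volData <- function(x) x@data

#' @describeIn Volume voxel spacing in mm.
#' @export
volSpacing <- function(x) x@spacing

#' @describeIn Volume the voxel-to-world affine (or NULL).
#' @export
volAffine <- function(x) x@affine

#' @describeIn LabelMap the integer label array.
#' @param x object.
#' @export
labelData <- function(x) x@data

#' @describeIn LabelMap the declared class ids.
#' @export
labelClasses <- function(x) x@classes

#' @describeIn DisplacementField the (H x W x L x 3) vector array.
#' @param x object.
#' @export
fieldVectors <- function(x) x@vectors

#' @describeIn JacobianReport interior determinant map.
#' @param x object.
#' @export
detMap <- function(x) x@detMap

#' @describeIn JacobianReport percent of interior voxels with negative
#'   Jacobian determinant.
#' @export
negFraction <- function(x) x@negFraction

#' @describeIn AtlasSet list of atlas volumes.
#' @param x object.
#' @export
atlasVolumes <- function(x) x@volumes

#' @describeIn AtlasSet list of atlas label maps.
#' @export
atlasLabels <- function(x) x@labels

#' @describeIn AtlasSet per-atlas metadata.
#' @export
atlasMeta <- function(x) x@meta

#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' @export
setMethod("dim", "LabelMap", function(x) dim(x@data))

#' @export
setMethod("dim", "DisplacementField", function(x) dim(x@vectors)[1:3])

#' @export
setMethod("length", "AtlasSet", function(x) length(x@volumes))

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  present <- sort(unique(as.vector(object@data)))
  cat(sprintf("LabelMap %d x %d x %d, classes {%s}, present {%s}\n",
              d[1], d[2], d[3],
              paste(object@classes, collapse = ","),
              paste(present, collapse = ",")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat(sprintf(
    "DisplacementField %d x %d x %d (voxel units), |phi| max %.3f mean %.3f\n",
    d[1], d[2], d[3], max(mag), mean(mag)))
})

setMethod("show", "JacobianReport", function(object) {
  cat(sprintf(
    "JacobianReport: %.4g%% negative determinants, det range [%.3f, %.3f]\n",
    object@negFraction, min(object@detMap), max(object@detMap)))
})

setMethod("show", "AtlasSet", function(object) {
  cat(sprintf("AtlasSet of %d annotated volumes\n", length(object@volumes)))
  if (nrow(object@meta) > 0)
    cat("  metadata: ", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "CascadeModel", function(object) {
  cfg <- object@cascade
  cat(sprintf(
    "CascadeModel: %d cascade(s), %s mode, image size %d^3, %d parameters\n",
    cfg$nCascades, if (cfg$accumulate) "accumulation" else "composition",
    cfg$imageSize, numParameters(object)))
  if (!is.null(object@history$bestEpoch))
    cat(sprintf("  best validation similarity %.4f at epoch %d\n",
                object@history$bestValSim, object@history$bestEpoch))
})
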