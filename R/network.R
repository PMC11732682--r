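#' @include nn.R losses.R
NULL

#' Backbone (encoder-decoder) configuration
#'
#' The backbone is a 3-D convolutional encoder-decoder with skip connections
#' between same-resolution stages. In the contracted design
#' (\code{emitHalfRes = TRUE}, the default) there is no convolution at the
#' full grid size: the decoder stops at half resolution, the 3-channel field
#' is emitted there and trilinearly upsampled x2 (vectors scaled x2 for
#' voxel-unit consistency). Hidden feature counts are deliberately generous
#' relative to the removed full-resolution stage.
#'
#' @param encChannels feature maps per encoder level (one stride-2
#'   downsampling each).
#' @param decChannels feature maps per decoder level; length
#'   \code{levels - 1} when emitting at half resolution, \code{levels}
#'   otherwise.
#' @param emitHalfRes emit the field at half resolution (contracted design).
#' @return A validated list of class \code{backboneConfig}.
#' @export
backboneConfig <- function(encChannels = c(16, 32, 64, 96),
                           decChannels = c(96, 64, 32),
                           emitHalfRes = TRUE) {
  if (any(encChannels < 1) || any(decChannels < 1))
    stopUsage("channel counts must be >= 1")
  L <- length(encChannels)
  need <- if (emitHalfRes) L - 1L else L
  if (length(decChannels) != need)
    stopUsage("decChannels must have length ", need, " for ", L,
              " encoder levels (emitHalfRes = ", emitHalfRes, ")")
  structure(list(encChannels = as.integer(encChannels),
                 decChannels = as.integer(decChannels),
                 levels = L, emitHalfRes = isTRUE(emitHalfRes)),
            class = c("backboneConfig", "list"))
}

#' Cascade configuration
#'
#' @param nCascades number of stacked networks (>= 1, default 5). Cascades
#'   do not share parameters.
#' @param accumulate TRUE (default): partial fields are voxel-wise summed
#'   and the original moving image is resampled once per stage. FALSE:
#'   successive warping of the previous warped image, with regularization on
#'   the functional composition of the partial fields.
#' @param backbone a \code{\link{backboneConfig}}.
#' @param imageSize cube side of the model input; must be divisible by
#'   2^levels.
#' @return A validated list of class \code{cascadeConfig}.
#' @export
cascadeConfig <- function(nCascades = 5, accumulate = TRUE,
                          backbone = backboneConfig(), imageSize = 128) {
  if (nCascades < 1) stopUsage("nCascades must be >= 1")
  div <- 2^backbone$levels
  if (imageSize %% div != 0)
    stopUsage("imageSize must be divisible by 2^levels = ", div,
              ", got ", imageSize)
  structure(list(nCascades = as.integer(nCascades),
                 accumulate = isTRUE(accumulate), backbone = backbone,
                 imageSize = as.integer(imageSize)),
            class = c("cascadeConfig", "list"))
}

#' Initialize a cascade model
#'
#' Weights are He-initialized except the field-emission convolutions, which
#' start at zero so the untrained cascade is exactly the identity map — a
#' stable starting point for cascaded training and a testable contract.
#'
#' @param cascade a \code{\link{cascadeConfig}}.
#' @param loss a \code{\link{lossConfig}}.
#' @param seed integer seed for weight initialization.
#' @return A \linkS4class{CascadeModel}.
#' @export
initCascadeModel <- function(cascade = cascadeConfig(), loss = lossConfig(),
                             seed = 1) {
  params <- withSeed(seed, lapply(seq_len(cascade$nCascades), function(k)
    initBackboneParams(cascade$backbone)))
  new("CascadeModel", params = params, cascade = unclass(cascade),
      loss = unclass(loss), history = list())
}

#' Number of trainable parameters of a model
#'
#' @param model a \linkS4class{CascadeModel}.
#' @return integer parameter count over all cascades.
#' @export
numParameters <- function(model) paramCount(model@params)

.check_model_input <- function(model, vol) {
  d <- dim(.as_vol_array(vol))
  n <- model@cascade$imageSize
  if (!all(d == n))
    stopUsage("input shape ", paste(d, collapse = "x"),
              " does not match model input size ", n, "^3")
}

#' Run a single backbone on an image pair
#'
#' @param model a \linkS4class{CascadeModel}.
#' @param moving,fixed \linkS4class{Volume}s of the model's input size.
#' @param cascade which cascade's network to use (default 1).
#' @return The predicted \linkS4class{DisplacementField}.
#' @export
backboneForward <- function(model, moving, fixed, cascade = 1) {
  .check_model_input(model, moving)
  .check_model_input(model, fixed)
  x <- array(c(.as_vol_array(moving), .as_vol_array(fixed)),
             dim = c(dim(.as_vol_array(moving)), 2L))
  DisplacementField(bbForward(model@params[[cascade]],
                              model@cascade$backbone, x)$flow)
}

#' Run the full cascade on an image pair
#'
#' Each cascade consumes the current warped image and the fixed image and
#' predicts a partial field. In accumulation mode the running sum of partial
#' fields warps the original moving image (one interpolation per stage); in
#' composition mode each stage warps the previous warped image and the final
#' field is the functional composition.
#'
#' @param model a \linkS4class{CascadeModel}.
#' @param moving,fixed \linkS4class{Volume}s of the model's input size.
#' @return list with \code{warped} (\linkS4class{Volume}),
#'   \code{partialFields} (list of \linkS4class{DisplacementField}) and
#'   \code{finalField} (\linkS4class{DisplacementField}).
#' @export
cascadeForward <- function(model, moving, fixed) {
  .check_model_input(model, moving)
  .check_model_input(model, fixed)
  mv <- .as_vol_array(moving)
  fx <- .as_vol_array(fixed)
  res <- cascInfer(model@params, model@cascade, mv, fx)
  sp <- if (is(moving, "Volume")) moving@spacing else c(1, 1, 1)
  list(warped = Volume(res$warped, spacing = sp),
       partialFields = lapply(res$flows, DisplacementField),
       finalField = DisplacementField(res$field))
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries all parameters, the cascade/backbone/loss
#' configuration and the training history (epoch log, best validation
#' similarity).
#'
#' @param model a \linkS4class{CascadeModel}.
#' @param path checkpoint file path.
#' @return \code{path} invisibly / the restored model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, cascade = model@cascade,
               loss = model@loss, history = model@history,
               format = "CascadeReg-checkpoint-1"), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stopData("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "CascadeReg-checkpoint-1"))
    stopData("not a CascadeReg checkpoint: ", path)
  new("CascadeModel", params = ck$params, cascade = ck$cascade,
      loss = ck$loss, history = ck$history)
}
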