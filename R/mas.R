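#' @include network.R metrics.R
NULL

#' Label-fusion configuration
#'
#' @param nSelect atlases kept after similarity ranking (default 10).
#' @param selectionMetric "NCC" (default), "MSE" or "SSIM"; whole-volume
#'   similarity computed on the foreground (non-zero) region of the target.
#' @param fusion "LWV" (local weighted voting, default) or "MV" (majority
#'   voting).
#' @param window odd edge length of the LWV local-similarity window
#'   (default 9).
#' @param gain LWV exponent g applied to the local similarity (default 2);
#'   g = 0 reduces LWV to majority voting.
#' @return A validated list of class \code{fusionConfig}.
#' @export
fusionConfig <- function(nSelect = 10, selectionMetric = c("NCC", "MSE", "SSIM"),
                         fusion = c("LWV", "MV"), window = 9, gain = 2) {
  selectionMetric <- match.arg(selectionMetric)
  fusion <- match.arg(fusion)
  if (nSelect < 1) stopUsage("nSelect must be >= 1")
  assertOdd(window, "LWV window")
  if (gain < 0) stopUsage("gain must be >= 0")
  structure(list(nSelect = as.integer(nSelect),
                 selectionMetric = selectionMetric, fusion = fusion,
                 window = as.integer(window), gain = gain),
            class = c("fusionConfig", "list"))
}

#' Register every atlas to a target image
#'
#' Each atlas volume is registered as moving image onto the target (fixed)
#' with the cascade model; its labels are propagated by the final field with
#' nearest-neighbour interpolation.
#'
#' @param target a \linkS4class{Volume} at the model input size.
#' @param atlases an \linkS4class{AtlasSet}, preprocessed like the target.
#' @param model a \linkS4class{CascadeModel} (or checkpoint path).
#' @return list with one entry per atlas: \code{warped}, \code{labels},
#'   \code{field}.
#' @export
registerAtlases <- function(target, atlases, model) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (length(atlases) == 0) stopUsage("empty atlas set")
  .check_model_input(model, target)
  lapply(seq_len(length(atlases)), function(k) {
    vol <- atlases@volumes[[k]]
    .check_model_input(model, vol)
    reg <- cascadeForward(model, vol, target)
    list(warped = reg$warped,
         labels = warpLabels(atlases@labels[[k]], reg$finalField),
         field = reg$finalField)
  })
}

# Whole-volume similarity metrics for atlas ranking, computed over the
# foreground (non-zero) voxels of the target.
.sim_foreground <- function(target) {
  t <- .as_vol_array(target)
  list(t = t, mask = t > 0)
}

globalNCC <- function(target, img, mask = NULL) {
  t <- .as_vol_array(target); g <- .as_vol_array(img)
  if (is.null(mask)) mask <- t > 0
  tv <- t[mask]; gv <- g[mask]
  num <- sum((tv - mean(tv)) * (gv - mean(gv)))
  den <- sqrt(sum((tv - mean(tv))^2) * sum((gv - mean(gv))^2))
  if (den == 0) return(0)
  num / den
}

globalMSE <- function(target, img, mask = NULL) {
  t <- .as_vol_array(target); g <- .as_vol_array(img)
  if (is.null(mask)) mask <- t > 0
  mean((t[mask] - g[mask])^2)
}

# Mean local SSIM over box windows (standard constants for unit dynamic
# range), restricted to windows centred on the foreground.
globalSSIM <- function(target, img, mask = NULL, window = 7) {
  t <- .as_vol_array(target); g <- .as_vol_array(img)
  if (is.null(mask)) mask <- t > 0
  d <- dim(t)
  N <- as.double(window)^3
  bs <- function(x) cpp_boxsum3d(x, d, as.integer(window))
  cnt <- bs(array(1, d))
  mu_t <- bs(t) / cnt; mu_g <- bs(g) / cnt
  var_t <- pmax(bs(t * t) / cnt - mu_t^2, 0)
  var_g <- pmax(bs(g * g) / cnt - mu_g^2, 0)
  cov <- bs(t * g) / cnt - mu_t * mu_g
  C1 <- 0.01^2; C2 <- 0.03^2
  ssim <- ((2 * mu_t * mu_g + C1) * (2 * cov + C2)) /
    ((mu_t^2 + mu_g^2 + C1) * (var_t + var_g + C2))
  mean(ssim[mask])
}

#' Rank registered atlases by similarity to the target
#'
#' Orders the warped atlases by descending similarity (ascending error for
#' MSE). NCC is the whole-volume Pearson correlation on the target
#' foreground; an exact copy of the target scores NCC = 1 and MSE = 0.
#'
#' @param target the target \linkS4class{Volume}.
#' @param warped list of warped atlas \linkS4class{Volume}s (or the result
#'   list of \code{\link{registerAtlases}}).
#' @param metric "NCC", "MSE" or "SSIM".
#' @return data.frame with columns \code{index} (into \code{warped}) and
#'   \code{score}, best first.
#' @export
rankAtlases <- function(target, warped, metric = c("NCC", "MSE", "SSIM")) {
  metric <- match.arg(metric)
  if (length(warped) == 0) stopUsage("empty atlas list")
  imgs <- lapply(warped, function(w) if (is.list(w) && !is.null(w$warped))
    w$warped else w)
  mask <- .as_vol_array(target) > 0
  scores <- vapply(imgs, function(im) switch(metric,
    NCC = globalNCC(target, im, mask),
    MSE = globalMSE(target, im, mask),
    SSIM = globalSSIM(target, im, mask)), 0)
  ord <- order(scores, decreasing = (metric != "MSE"))
  data.frame(index = ord, score = scores[ord])
}

.fusion_stack <- function(propagated) {
  if (length(propagated) == 0) stopUsage("empty propagated-label list")
  d <- dim(propagated[[1]]@data)
  for (p in propagated) if (!identical(dim(p@data), d))
    stopUsage("propagated label maps must share one shape")
  classes <- propagated[[1]]@classes
  list(d = d, classes = classes)
}

#' Majority-voting label fusion
#'
#' Per-voxel modal label over the propagated maps; ties broken by the
#' lowest class id (deterministic).
#'
#' @param propagated non-empty list of \linkS4class{LabelMap}s of equal
#'   shape.
#' @return The fused \linkS4class{LabelMap}.
#' @export
majorityVote <- function(propagated) {
  s <- .fusion_stack(propagated)
  best <- array(-Inf, s$d)
  lab <- array(s$classes[1], s$d)
  for (k in s$classes) {
    votes <- Reduce(`+`, lapply(propagated, function(p) (p@data == k) * 1))
    win <- votes > best          # strict: earlier (lower) class keeps ties
    lab[win] <- k
    best[win] <- votes[win]
  }
  LabelMap(lab, classes = s$classes)
}

#' Local-weighted-voting label fusion
#'
#' Each atlas k votes at voxel i with weight |m|^g, where m is the local
#' NCC (signed correlation over the d^3 window between the warped atlas and
#' the target, clamped below at 0) and g the gain. Class scores are the
#' weight sums over atlases voting for that class; the argmax wins, ties to
#' the lowest class id. With g = 0 all weights are 1 and the result equals
#' majority voting. A tiny uniform weight floor makes voxels where no atlas
#' shows any positive local similarity degrade to a plain majority vote.
#'
#' @param target the target \linkS4class{Volume}.
#' @param warped list of warped atlas \linkS4class{Volume}s.
#' @param propagated list of propagated \linkS4class{LabelMap}s, aligned
#'   with \code{warped}.
#' @param cfg a \code{\link{fusionConfig}} (window and gain are used).
#' @return The fused \linkS4class{LabelMap}.
#' @export
localWeightedVote <- function(target, warped, propagated,
                              cfg = fusionConfig()) {
  if (length(warped) != length(propagated))
    stopUsage("warped and propagated lists must be aligned")
  s <- .fusion_stack(propagated)
  t <- .as_vol_array(target)
  dint <- as.integer(s$d)
  bs <- function(x) cpp_boxsum3d(x, dint, cfg$window)
  cnt <- bs(array(1, s$d))
  St <- bs(t); Stt <- bs(t * t)
  weights <- lapply(warped, function(w) {
    g <- .as_vol_array(if (is.list(w) && !is.null(w$warped)) w$warped else w)
    Sg <- bs(g)
    cross <- bs(t * g) - St * Sg / cnt
    var_t <- pmax(Stt - St^2 / cnt, 0)
    var_g <- pmax(bs(g * g) - Sg^2 / cnt, 0)
    m <- cross / sqrt((var_t + 1e-5) * (var_g + 1e-5))
    # the tiny floor makes voxels where no atlas shows any local similarity
    # fall back to an (unweighted) majority vote instead of background
    pmax(m, 0)^cfg$gain + 1e-9
  })
  best <- array(-Inf, s$d)
  lab <- array(s$classes[1], s$d)
  for (k in s$classes) {
    score <- Reduce(`+`, Map(function(w, p) w * (p@data == k),
                             weights, propagated))
    win <- score > best
    lab[win] <- k
    best[win] <- score[win]
  }
  LabelMap(lab, classes = s$classes)
}

#' Multi-atlas segmentation of a target volume
#'
#' The full pipeline: register every atlas to the target, rank the warped
#' atlases by the selection metric, keep the best \code{nSelect}, propagate
#' their labels and fuse them (LWV or MV). The provenance records the
#' ranking scores, the selected atlas ids and the configuration.
#'
#' @param target a preprocessed \linkS4class{Volume} at the model input
#'   size.
#' @param atlases an \linkS4class{AtlasSet}.
#' @param model a \linkS4class{CascadeModel} or checkpoint path.
#' @param cfg a \code{\link{fusionConfig}}.
#' @return list with \code{labels} (the fused \linkS4class{LabelMap}) and
#'   \code{provenance}.
#' @export
segmentTarget <- function(target, atlases, model, cfg = fusionConfig()) {
  if (cfg$nSelect > length(atlases))
    stopUsage("nSelect exceeds the atlas count")
  reg <- registerAtlases(target, atlases, model)
  rk <- rankAtlases(target, reg, cfg$selectionMetric)
  keep <- rk$index[seq_len(cfg$nSelect)]
  warped <- lapply(reg[keep], `[[`, "warped")
  propagated <- lapply(reg[keep], `[[`, "labels")
  fused <- if (cfg$fusion == "MV") majorityVote(propagated)
           else localWeightedVote(target, warped, propagated, cfg)
  list(labels = fused,
       provenance = list(ranking = rk, selected = keep,
                         config = unclass(cfg)))
}
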