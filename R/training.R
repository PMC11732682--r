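#' @include network.R
NULL

#' Training configuration
#'
#' Defaults mirror the full-scale schedule: 500 epochs of 100 iterations,
#' batch size 2, Adam with base learning rate 3e-4 decayed exponentially by
#' a factor e^-3 over the run. For CPU-scale work see
#' \code{\link{deskProfile}}.
#'
#' @param epochs maximum epoch count EPmax (>= 1).
#' @param itersPerEpoch optimizer iterations per epoch.
#' @param batchSize pairs per iteration (>= 1).
#' @param baseLr Adam learning rate at epoch 0.
#' @param lrDecayRate decay exponent: lr(ep) = baseLr * exp(-rate * ep / EPmax).
#' @param seed integer seed controlling sampling and any stochastic choice.
#' @param device compute-target tag (informational; only "cpu" is
#'   implemented).
#' @return A validated list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 500, itersPerEpoch = 100, batchSize = 2,
                        baseLr = 3e-4, lrDecayRate = 3, seed = 1,
                        device = "cpu") {
  if (epochs < 1) stopUsage("epochs must be >= 1")
  if (batchSize < 1) stopUsage("batchSize must be >= 1")
  if (itersPerEpoch < 1) stopUsage("itersPerEpoch must be >= 1")
  if (baseLr <= 0) stopUsage("baseLr must be > 0")
  structure(list(epochs = as.integer(epochs),
                 itersPerEpoch = as.integer(itersPerEpoch),
                 batchSize = as.integer(batchSize), baseLr = baseLr,
                 lrDecayRate = lrDecayRate, seed = as.integer(seed),
                 device = device),
            class = c("trainConfig", "list"))
}

#' Desk-scale experiment profile
#'
#' A configuration bundle sized for CPU experimentation: 32^3 volumes, a
#' narrow contracted backbone, 3 cascades, 30 epochs of 10 iterations with
#' batch size 1 and a larger base learning rate suited to the short
#' schedule. Exercises every code path of the full-scale setup in minutes.
#'
#' @param nCascades cascade count (default 3).
#' @param lambda regularization weight (default 1).
#' @param patchSizes NCC window sizes (default 9, single scale).
#' @param seed integer seed.
#' @param epochs,itersPerEpoch training budget.
#' @return list with elements \code{cascade}, \code{loss}, \code{train}.
#' @export
deskProfile <- function(nCascades = 3, lambda = 1, patchSizes = 9, seed = 1,
                        epochs = 30, itersPerEpoch = 10) {
  bb <- backboneConfig(encChannels = c(8, 16, 16), decChannels = c(16, 8))
  list(cascade = cascadeConfig(nCascades = nCascades, backbone = bb,
                               imageSize = 32),
       loss = lossConfig(patchSizes = patchSizes, lambda = lambda),
       train = trainConfig(epochs = epochs, itersPerEpoch = itersPerEpoch,
                           batchSize = 1, baseLr = 6e-3, seed = seed))
}

#' Exponentially decaying learning-rate schedule
#'
#' lr(ep) = baseLr * exp(-lrDecayRate * ep / epochs); strictly decreasing in
#' the epoch index, from baseLr at epoch 0 to baseLr * e^-rate at the final
#' epoch.
#'
#' @param ep epoch index in [0, epochs].
#' @param cfg a \code{\link{trainConfig}}.
#' @return the learning rate.
#' @export
lrSchedule <- function(ep, cfg) {
  if (any(ep < 0) || any(ep > cfg$epochs))
    stopUsage("epoch index out of range [0, ", cfg$epochs, "]")
  cfg$baseLr * exp(-cfg$lrDecayRate * ep / cfg$epochs)
}

#' Sampler over ordered volume pairs
#'
#' Draws ordered (moving, fixed) pairs uniformly without replacement within
#' each epoch, excluding self-pairs, reshuffling every epoch. With a single
#' pre-formed pair, returns it at every call.
#'
#' @param volumes list of \linkS4class{Volume}s (>= 2), or a list with
#'   elements \code{moving} and \code{fixed} for fixed-pair training.
#' @param seed integer seed for the shuffling stream.
#' @return function(epoch, iter, batchSize) returning a list of
#'   \code{list(moving =, fixed =)} pairs.
#' @export
makePairSampler <- function(volumes, seed = 1) {
  if (!is.null(volumes$moving) && !is.null(volumes$fixed)) {
    pair <- list(moving = .as_vol_array(volumes$moving),
                 fixed = .as_vol_array(volumes$fixed))
    return(function(epoch, iter, batchSize)
      rep(list(pair), batchSize))
  }
  if (length(volumes) < 2) stopUsage("need at least 2 volumes to form pairs")
  arrs <- lapply(volumes, .as_vol_array)
  K <- length(arrs)
  ordered <- expand.grid(mv = seq_len(K), fx = seq_len(K))
  ordered <- ordered[ordered$mv != ordered$fx, , drop = FALSE]
  env <- new.env(parent = emptyenv())
  env$epoch <- -1L
  function(epoch, iter, batchSize) {
    if (epoch != env$epoch) {
      env$perm <- withSeed(seed + epoch, sample.int(nrow(ordered)))
      env$pos <- 0L
      env$epoch <- epoch
    }
    idx <- integer(batchSize)
    for (b in seq_len(batchSize)) {
      env$pos <- env$pos + 1L
      if (env$pos > length(env$perm)) env$pos <- 1L  # wrap if epoch is long
      idx[b] <- env$perm[env$pos]
    }
    lapply(idx, function(i) list(moving = arrs[[ordered$mv[i]]],
                                 fixed = arrs[[ordered$fx[i]]]))
  }
}

#' Train a cascade model (unsupervised)
#'
#' Minimises the total loss — multi-scale local NCC plus lambda times the
#' smoothness energy, both computed on the final cascade output only — with
#' Adam under the exponential learning-rate schedule. After every epoch the
#' image-similarity term alone is evaluated on the validation pairs and the
#' parameters are checkpointed whenever it improves; the regularization term
#' takes no part in checkpoint selection (so no labels and no field ground
#' truth are ever needed).
#'
#' @param sampler a \code{\link{makePairSampler}} function, or a list with
#'   \code{moving}/\code{fixed}, or a list of \linkS4class{Volume}s.
#' @param model a \linkS4class{CascadeModel} from
#'   \code{\link{initCascadeModel}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param validationPairs list of \code{list(moving =, fixed =)} pairs; when
#'   NULL the first training batch of each epoch doubles as validation.
#' @param checkpointPath optional file; the best checkpoint is written there.
#' @param verbose print one line per epoch.
#' @return The trained \linkS4class{CascadeModel} with best-validation
#'   parameters and an epoch log in \code{history}.
#' @export
trainCascade <- function(sampler, model, cfg = trainConfig(),
                         validationPairs = NULL, checkpointPath = NULL,
                         verbose = FALSE) {
  if (!is.function(sampler)) sampler <- makePairSampler(sampler, seed = cfg$seed)
  first <- sampler(0L, 1L, 1L)
  if (length(first) == 0) stopData("empty pair sampler")
  if (is.null(validationPairs)) validationPairs <- first
  validationPairs <- lapply(validationPairs, function(p)
    list(moving = .as_vol_array(p$moving), fixed = .as_vol_array(p$fixed)))
  params <- model@params
  casCfg <- model@cascade
  lossCfg <- model@loss
  state <- adamInit(params)
  valSim <- function(ps) {
    mean(vapply(validationPairs, function(p) {
      r <- cascInfer(ps, casCfg, p$moving, p$fixed)
      multiscaleNCC(p$fixed, r$warped, lossCfg$patchSizes, lossCfg$epsilon)
    }, 0))
  }
  best <- list(sim = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), lr = numeric(), trainLoss = numeric(),
                    valSim = numeric())
  for (ep in seq_len(cfg$epochs)) {
    lr <- lrSchedule(ep - 1L, cfg)
    epLoss <- 0
    for (it in seq_len(cfg$itersPerEpoch)) {
      batch <- sampler(ep, it, cfg$batchSize)
      gsum <- NULL
      bloss <- 0
      for (p in batch) {
        r <- cascLossGrad(params, casCfg, p$moving, p$fixed, lossCfg)
        bloss <- bloss + r$loss
        gsum <- if (is.null(gsum)) r$grads
                else paramMap2(gsum, r$grads, `+`)
      }
      if (cfg$batchSize > 1)
        gsum <- paramMap2(gsum, gsum, function(g, .) g / cfg$batchSize)
      upd <- adamStep(params, gsum, state, lr)
      params <- upd$params
      state <- upd$state
      epLoss <- epLoss + bloss / cfg$batchSize
    }
    vs <- valSim(params)
    log <- rbind(log, data.frame(epoch = ep, lr = lr,
                                 trainLoss = epLoss / cfg$itersPerEpoch,
                                 valSim = vs))
    if (vs < best$sim) {
      best <- list(sim = vs, params = params, epoch = ep)
      if (!is.null(checkpointPath)) {
        tmp <- new("CascadeModel", params = params, cascade = casCfg,
                   loss = lossCfg,
                   history = list(log = log, bestEpoch = ep, bestValSim = vs))
        saveCheckpoint(tmp, checkpointPath)
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val sim %.5f%s",
                      ep, lr, epLoss / cfg$itersPerEpoch, vs,
                      if (best$epoch == ep) "  *" else ""))
  }
  new("CascadeModel", params = best$params, cascade = casCfg, loss = lossCfg,
      history = list(log = log, bestEpoch = best$epoch,
                     bestValSim = best$sim, finalParams = params))
}
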