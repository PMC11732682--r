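# Internal neural-network machinery: 3-D convolution via im2col + BLAS gemm,
# leaky rectification, trilinear up/down-sampling, and hand-derived
# reverse-mode gradients for the fixed encoder-decoder topology. Tensors are
# (nx, ny, nz, C) arrays; patches are (nOut x k^3*Cin) matrices and weights
# are stored transposed as (k^3*Cin x Cout), so forward and reverse passes
# are pure gemm calls with no large transposes.

convForward <- function(x, W, b, stride, k = 3L, pad = 1L) {
  d <- dim(x)
  cols <- cpp_im2col(x, as.integer(d), k, stride, pad)
  on <- (d[1:3] + 2L * pad - k) %/% stride + 1L
  out <- cols %*% W
  if (anyNA(b) || any(b != 0)) out <- out + rep(b, each = nrow(out))
  dim(out) <- c(on, ncol(W))
  list(y = out, cols = cols, xdim = d,
       stride = stride, k = k, pad = pad)
}

convBackward <- function(cache, W, dY) {
  co <- dim(dY)[4]
  dYn <- matrix(dY, ncol = co)                # nout x Cout (no copy of order)
  dW <- crossprod(cache$cols, dYn)            # krows x Cout
  db <- colSums(dYn)
  dcols <- tcrossprod(dYn, W)                 # nout x krows
  dX <- cpp_col2im(dcols, as.integer(cache$xdim), cache$k, cache$stride,
                   cache$pad)
  list(dW = dW, db = db, dX = dX)
}

lreluForward <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg, slope = slope)
}

lreluBackward <- function(cache, dY) {
  dY[cache$neg] <- dY[cache$neg] * cache$slope
  dY
}

# cache of align-corners resampling grids keyed by from/to dims
.resample_cache <- new.env(parent = emptyenv())

resampleGrid <- function(from, to) {
  key <- paste(c(from, to), collapse = "x")
  g <- .resample_cache[[key]]
  if (is.null(g)) {
    g <- resampleCoords(from, to)
    .resample_cache[[key]] <- g
  }
  g
}

upsampleForward <- function(x, to) {
  d <- dim(x)
  co <- resampleGrid(d[1:3], to)
  y <- cpp_trilinear_gather(x, as.integer(d), co)
  dim(y) <- c(to, d[4])
  list(y = y, from = d, to = to)
}

upsampleBackward <- function(cache, dY) {
  co <- resampleGrid(cache$from[1:3], cache$to)
  dOut <- matrix(dY, ncol = cache$from[4])
  g <- cpp_trilinear_gather_grad(array(0, cache$from), as.integer(cache$from),
                                 co, dOut, TRUE, FALSE)
  g$dimg
}

heInit <- function(cout, cin, k = 3L) {
  fan <- k^3 * cin
  list(W = matrix(rnorm(cout * fan, sd = sqrt(2 / fan)), fan, cout),
       b = numeric(cout))
}

# Parameters for one backbone: stride-2 encoder convs, stride-1 decoder
# convs after trilinear upsampling + skip concatenation, and a zero-
# initialized field-emission conv so the untrained network is the identity.
initBackboneParams <- function(cfg) {
  L <- length(cfg$encChannels)
  cin <- 2L
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    enc[[l]] <- heInit(cfg$encChannels[l], cin)
    cin <- cfg$encChannels[l]
  }
  dec <- vector("list", length(cfg$decChannels))
  dcur <- cfg$encChannels[L]
  for (i in seq_along(cfg$decChannels)) {
    skipc <- if (i < L) cfg$encChannels[L - i] else 2L
    dec[[i]] <- heInit(cfg$decChannels[i], dcur + skipc)
    dcur <- cfg$decChannels[i]
  }
  emit <- list(W = matrix(0, 27L * dcur, 3L), b = numeric(3L))
  list(enc = enc, dec = dec, emit = emit)
}

# Forward pass of one backbone on the 2-channel (moving-or-warped, fixed)
# input. Returns the full-resolution flow; with cache = TRUE also every
# intermediate needed by bbBackward.
bbForward <- function(p, cfg, x, cache = FALSE) {
  L <- length(cfg$encChannels)
  nd <- length(cfg$decChannels)
  acts <- vector("list", L + 1L)
  acts[[1]] <- x
  cEnc <- vector("list", L)
  for (l in seq_len(L)) {
    cc <- convForward(acts[[l]], p$enc[[l]]$W, p$enc[[l]]$b, stride = 2L)
    aa <- lreluForward(cc$y)
    acts[[l + 1]] <- aa$y
    if (cache) cEnc[[l]] <- list(conv = cc, act = aa)
    else cEnc[[l]] <- NULL
  }
  d <- acts[[L + 1]]
  cDec <- vector("list", nd)
  for (i in seq_len(nd)) {
    skip <- if (i < L) acts[[L - i + 1]] else acts[[1]]
    up <- upsampleForward(d, dim(skip)[1:3])
    xin <- c(up$y, skip)
    dim(xin) <- c(dim(skip)[1:3], dim(up$y)[4] + dim(skip)[4])
    cc <- convForward(xin, p$dec[[i]]$W, p$dec[[i]]$b, stride = 1L)
    aa <- lreluForward(cc$y)
    d <- aa$y
    if (cache) cDec[[i]] <- list(up = up, upC = dim(up$y)[4], conv = cc, act = aa)
  }
  em <- convForward(d, p$emit$W, p$emit$b, stride = 1L)
  if (cfg$emitHalfRes) {
    full <- dim(x)[1:3]
    upf <- upsampleForward(em$y, full)
    flow <- 2 * upf$y   # voxel-unit consistency after the x2 upsampling
  } else {
    upf <- NULL
    flow <- em$y
  }
  if (!cache) return(list(flow = flow))
  list(flow = flow,
       cache = list(enc = cEnc, dec = cDec, emit = em, upf = upf, L = L,
                    nd = nd))
}

# Reverse pass: upstream dFlow -> parameter gradients + gradient w.r.t. the
# 2-channel input.
bbBackward <- function(p, cfg, cache, dFlow) {
  L <- cache$L; nd <- cache$nd
  if (cfg$emitHalfRes) {
    dEm <- upsampleBackward(cache$upf, 2 * dFlow)
  } else {
    dEm <- dFlow
  }
  g <- list(enc = vector("list", L), dec = vector("list", nd), emit = NULL)
  cb <- convBackward(cache$emit, p$emit$W, dEm)
  g$emit <- list(W = cb$dW, b = cb$db)
  dd <- cb$dX
  dActs <- vector("list", L + 1L)  # grads of encoder activations (+ input)
  for (i in rev(seq_len(nd))) {
    cd <- cache$dec[[i]]
    dPre <- lreluBackward(cd$act, dd)
    cb <- convBackward(cd$conv, p$dec[[i]]$W, dPre)
    g$dec[[i]] <- list(W = cb$dW, b = cb$db)
    upC <- cd$upC
    dcat <- cb$dX
    dims <- dim(dcat)
    dUp <- dcat[, , , seq_len(upC), drop = FALSE]
    dSkip <- dcat[, , , (upC + 1):dims[4], drop = FALSE]
    si <- if (i < L) L - i + 1L else 1L
    dActs[[si]] <- if (is.null(dActs[[si]])) dSkip else dActs[[si]] + dSkip
    dd <- upsampleBackward(cd$up, dUp)
  }
  dActs[[L + 1]] <- dd
  for (l in rev(seq_len(L))) {
    ce <- cache$enc[[l]]
    dPre <- lreluBackward(ce$act, dActs[[l + 1]])
    cb <- convBackward(ce$conv, p$enc[[l]]$W, dPre)
    g$enc[[l]] <- list(W = cb$dW, b = cb$db)
    dActs[[l]] <- if (is.null(dActs[[l]])) cb$dX else dActs[[l]] + cb$dX
  }
  list(grads = g, dX = dActs[[1]])
}

# ---- recursive helpers over parameter trees (leaves: numeric W/b) ----

paramMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- paramMap2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

paramZeroLike <- function(a) {
  if (is.list(a)) lapply(a, paramZeroLike) else a * 0
}

paramCount <- function(a) {
  if (is.list(a)) sum(vapply(a, paramCount, 0)) else length(a)
}

# Adam with decoupled state trees; deterministic given the call sequence.
adamInit <- function(params) {
  list(m = paramZeroLike(params), v = paramZeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- paramMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- paramMap2(state$m, state$m, function(m, .) m / bc1)
  vhat <- paramMap2(state$v, state$v, function(v, .) v / bc2)
  upd <- paramMap2(mhat, vhat, function(m, v) m / (sqrt(v) + eps))
  params <- paramMap2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# ---- cascade forward/backward ----

checkFiniteFlow <- function(flow) {
  if (!is.finite(sum(flow)))
    stopData("non-finite deformation field predicted (diverged training?); ",
             "aborting")
  flow
}

# Training-mode forward+backward through the whole cascade.
# Accumulate mode: cascade k consumes (warped_{k-1}, fixed), its flow is
# summed into the running field, and the ORIGINAL moving image is resampled
# once by the running sum. Composition mode: each step warps the previous
# warped image by its own flow and the final field is the functional
# composition of the partial flows.
cascLossGrad <- function(paramsList, casCfg, moving, fixed, lossCfg) {
  d <- dim(moving)
  dims4 <- as.integer(c(d, 1L))
  grid <- gridCoords(d)
  n <- casCfg$nCascades
  bb <- casCfg$backbone
  flows <- vector("list", n)
  caches <- vector("list", n)
  wp <- moving
  if (casCfg$accumulate) {
    accs <- vector("list", n)
    acc <- array(0, c(d, 3L))
    for (k in seq_len(n)) {
      xin <- c(wp, fixed)
      dim(xin) <- c(d, 2L)
      fw <- bbForward(paramsList[[k]], bb, xin, cache = TRUE)
      checkFiniteFlow(fw$flow)
      flows[[k]] <- fw$flow
      caches[[k]] <- fw$cache
      acc <- acc + fw$flow
      accs[[k]] <- acc
      co <- grid + matrix(acc, ncol = 3)
      bumpWarpCount()
      wp <- cpp_trilinear_gather(moving, dims4, co)
      dim(wp) <- d
    }
    finalField <- acc
  } else {
    wps <- vector("list", n + 1L)
    wps[[1]] <- moving
    for (k in seq_len(n)) {
      xin <- c(wp, fixed)
      dim(xin) <- c(d, 2L)
      fw <- bbForward(paramsList[[k]], bb, xin, cache = TRUE)
      checkFiniteFlow(fw$flow)
      flows[[k]] <- fw$flow
      caches[[k]] <- fw$cache
      co <- grid + matrix(fw$flow, ncol = 3)
      bumpWarpCount()
      wp <- cpp_trilinear_gather(wps[[k]], dims4, co)
      dim(wp) <- d
      wps[[k + 1]] <- wp
    }
    # running composition psi_k(x) = f_k(x) + psi_{k-1}(x + f_k(x))
    psis <- vector("list", n)
    psis[[1]] <- flows[[1]]
    if (n > 1) for (k in 2:n) {
      co <- grid + matrix(flows[[k]], ncol = 3)
      s <- cpp_trilinear_gather(psis[[k - 1]], as.integer(c(d, 3L)), co)
      psis[[k]] <- flows[[k]] + array(s, dim = c(d, 3L))
    }
    finalField <- psis[[n]]
  }
  bumpLossCount()
  sim <- multiscaleNCCWithGrad(fixed, wp, lossCfg$patchSizes, lossCfg$epsilon)
  smo <- smoothnessWithGrad(finalField, grad = TRUE)
  loss <- sim$loss + lossCfg$lambda * smo$loss
  if (!is.finite(loss)) stopData("non-finite training loss; aborting")

  grads <- vector("list", n)
  if (casCfg$accumulate) {
    dwp <- sim$grad
    dacc <- lossCfg$lambda * smo$grad
    for (k in rev(seq_len(n))) {
      co <- grid + matrix(accs[[k]], ncol = 3)
      gg <- cpp_trilinear_gather_grad(moving, dims4, co,
                                      matrix(dwp, ncol = 1), FALSE, TRUE)
      dco <- gg$dcoords
      dim(dco) <- c(d, 3L)
      dacc <- dacc + dco
      bbk <- bbBackward(paramsList[[k]], bb, caches[[k]], dacc)
      grads[[k]] <- bbk$grads
      dwp <- bbk$dX[, , , 1]
    }
  } else {
    # smoothness path through the composition recursion
    dflowSmooth <- lapply(seq_len(n), function(k) array(0, c(d, 3L)))
    dpsi <- lossCfg$lambda * smo$grad
    if (n > 1) for (k in rev(2:n)) {
      co <- grid + matrix(flows[[k]], ncol = 3)
      gg <- cpp_trilinear_gather_grad(psis[[k - 1]], as.integer(c(d, 3L)), co,
                                      matrix(dpsi, ncol = 3), TRUE, TRUE)
      dflowSmooth[[k]] <- dflowSmooth[[k]] + dpsi +
        array(gg$dcoords, dim = c(d, 3L))
      dpsi <- gg$dimg
    }
    dflowSmooth[[1]] <- dflowSmooth[[1]] + dpsi
    dwp <- sim$grad
    for (k in rev(seq_len(n))) {
      co <- grid + matrix(flows[[k]], ncol = 3)
      gg <- cpp_trilinear_gather_grad(wps[[k]], dims4, co,
                                      matrix(dwp, ncol = 1), TRUE, TRUE)
      dflow <- array(gg$dcoords, dim = c(d, 3L)) + dflowSmooth[[k]]
      bbk <- bbBackward(paramsList[[k]], bb, caches[[k]], dflow)
      grads[[k]] <- bbk$grads
      dwp <- array(gg$dimg, dim = d) + array(bbk$dX[, , , 1], dim = d)
    }
  }
  list(loss = loss, sim = sim$loss, smooth = smo$loss, grads = grads,
       warped = wp, field = finalField)
}

# Inference-only cascade pass (no caches).
cascInfer <- function(paramsList, casCfg, moving, fixed) {
  d <- dim(moving)
  dims4 <- as.integer(c(d, 1L))
  grid <- gridCoords(d)
  n <- casCfg$nCascades
  flows <- vector("list", n)
  wp <- moving
  if (casCfg$accumulate) {
    acc <- array(0, c(d, 3L))
    for (k in seq_len(n)) {
      xin <- c(wp, fixed)
      dim(xin) <- c(d, 2L)
      flows[[k]] <- checkFiniteFlow(bbForward(paramsList[[k]], casCfg$backbone, xin)$flow)
      acc <- acc + flows[[k]]
      bumpWarpCount()
      wp <- cpp_trilinear_gather(moving, dims4, grid + matrix(acc, ncol = 3))
      dim(wp) <- d
    }
    finalField <- acc
  } else {
    for (k in seq_len(n)) {
      xin <- c(wp, fixed)
      dim(xin) <- c(d, 2L)
      flows[[k]] <- checkFiniteFlow(bbForward(paramsList[[k]], casCfg$backbone, xin)$flow)
      bumpWarpCount()
      wp <- cpp_trilinear_gather(wp, dims4, grid + matrix(flows[[k]], ncol = 3))
      dim(wp) <- d
    }
    finalField <- composeFields(lapply(flows, DisplacementField))@vectors
  }
  list(warped = wp, flows = flows, field = finalField)
}
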