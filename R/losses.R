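#' @include transform.R
NULL

#' Loss configuration
#'
#' @param patchSizes odd window edge lengths for the local NCC similarity;
#'   a single size gives the single-scale loss, several sizes the
#'   multi-resolution variant (their values are averaged with equal weight).
#' @param lambda weight of the smoothness regularization (>= 0, default 1).
#' @param epsilon variance-stabilization constant added to both denominator
#'   factors of the local correlation; windows of (near-)constant intensity
#'   then contribute 0 instead of 0/0.
#' @return A validated list of class \code{lossConfig}.
#' @export
lossConfig <- function(patchSizes = 9, lambda = 1, epsilon = 1e-5) {
  assertOdd(patchSizes, "patch size")
  if (lambda < 0) stopUsage("lambda must be >= 0")
  if (epsilon <= 0) stopUsage("epsilon must be > 0")
  structure(list(patchSizes = as.integer(patchSizes), lambda = lambda,
                 epsilon = epsilon),
            class = c("lossConfig", "list"))
}

.as_vol_array <- function(x) if (is(x, "Volume")) x@data else x

# Local NCC with optional reverse-mode gradient with respect to the second
# (warped) image. Each valid window contributes
#   cc_p = cross_p^2 / ((varf_p + eps) * (varg_p + eps))  in [0, 1],
# computed from box sums; the loss is -mean(cc) over voxels whose full d^3
# window fits inside the grid. The gradient closed form is
#   d(-mean cc)/dg(q) = -(1/N) * [ f(q)*box(A) - box(A*fbar)
#                                  - g(q)*box(B) + box(B*gbar) ](q)
# with A_p = 2 cross_p / (F_p G_p), B_p = 2 cross_p^2 / (F_p G_p^2),
# zero outside the valid region (box = centred moving sum, self-adjoint).
nccWithGrad <- function(f, g, d, eps = 1e-5, grad = FALSE) {
  dims <- dim(f)
  if (!identical(dims, dim(g))) stopUsage("image shapes do not match")
  assertOdd(d)
  r <- (d - 1L) %/% 2L
  if (any(dims < d)) stopUsage("window larger than image")
  N <- as.double(d)^3
  bs <- function(x) cpp_boxsum3d(x, dims, d)
  Sf <- bs(f); Sg <- bs(g)
  cross <- bs(f * g) - Sf * Sg / N
  varf <- pmax(bs(f * f) - Sf * Sf / N, 0)
  varg <- pmax(bs(g * g) - Sg * Sg / N, 0)
  valid <- array(FALSE, dims)
  valid[(r + 1):(dims[1] - r), (r + 1):(dims[2] - r), (r + 1):(dims[3] - r)] <- TRUE
  Fm <- varf + eps; Gm <- varg + eps
  cc <- cross^2 / (Fm * Gm)
  nValid <- sum(valid)
  loss <- -sum(cc[valid]) / nValid
  if (!grad) return(list(loss = loss))
  A <- array(0, dims); B <- array(0, dims)
  A[valid] <- 2 * cross[valid] / (Fm[valid] * Gm[valid])
  B[valid] <- 2 * cross[valid]^2 / (Fm[valid] * Gm[valid]^2)
  fbar <- Sf / N; gbar <- Sg / N
  dcc <- f * bs(A) - bs(A * fbar) - g * bs(B) + bs(B * gbar)
  list(loss = loss, grad = -dcc / nValid)
}

#' Negative local normalized cross-correlation
#'
#' Windowed similarity between a fixed and a warped image: at each voxel the
#' squared local covariance over the d^3 window is divided by the product of
#' the two local sums of squared deviations, so every window term lies in
#' [0, 1] and the sign of the correlation is immaterial. The loss is the
#' negative mean over all voxels whose full window fits inside the grid
#' (identical images give -1).
#'
#' @param fixed,warped \linkS4class{Volume}s (or arrays) of equal shape.
#' @param d odd window edge length.
#' @param epsilon variance-stabilization constant.
#' @return scalar loss in [-1, 0].
#' @export
localNCC <- function(fixed, warped, d = 9, epsilon = 1e-5) {
  nccWithGrad(.as_vol_array(fixed), .as_vol_array(warped), d, epsilon)$loss
}

#' Multi-resolution NCC loss
#'
#' Unweighted mean of \code{\link{localNCC}} over several window sizes,
#' letting the objective see both coarse structure (large windows) and fine
#' detail (small windows).
#'
#' @param fixed,warped \linkS4class{Volume}s (or arrays) of equal shape.
#' @param patchSizes non-empty vector of odd window sizes.
#' @param epsilon variance-stabilization constant.
#' @return scalar loss in [-1, 0].
#' @export
multiscaleNCC <- function(fixed, warped, patchSizes = c(5, 7, 9, 11),
                          epsilon = 1e-5) {
  if (length(patchSizes) == 0) stopUsage("patchSizes must be non-empty")
  mean(vapply(patchSizes, function(d) localNCC(fixed, warped, d, epsilon), 0))
}

multiscaleNCCWithGrad <- function(f, g, patchSizes, eps) {
  terms <- lapply(patchSizes, function(d) nccWithGrad(f, g, d, eps, grad = TRUE))
  list(loss = mean(vapply(terms, `[[`, 0, "loss")),
       grad = Reduce(`+`, lapply(terms, `[[`, "grad")) / length(terms))
}

# Smoothness energy of a field with optional gradient. Each of the 9 partial
# derivatives (forward differences) is averaged over its own valid support,
# so an affine field phi_c = a * x_c gives exactly 3 a^2.
smoothnessWithGrad <- function(phi, grad = FALSE) {
  d <- dim(phi)[1:3]
  if (any(d < 2)) stopUsage("field must be at least 2 voxels per axis")
  cpp_smoothness(phi, as.integer(d), grad)
}

#' Smoothness (gradient-norm) regularization of a displacement field
#'
#' Mean over voxels of the squared Euclidean norm of the spatial gradient of
#' phi (all 9 partial derivatives, forward differences). Zero for any
#' constant field: pure translations are not penalized.
#'
#' @param field a \linkS4class{DisplacementField} (or 4-D array).
#' @return scalar energy >= 0.
#' @export
smoothnessLoss <- function(field) {
  smoothnessWithGrad(.as_field_array(field))$loss
}

#' Total registration loss
#'
#' \code{multiscaleNCC + lambda * smoothnessLoss}, evaluated on the final
#' warped image and the final (accumulated or composed) field only — the
#' cascades receive no intermediate supervision. Both terms are means over
#' voxels, so \code{lambda} has a comparable meaning across image sizes.
#'
#' @param fixed,warped \linkS4class{Volume}s of equal shape.
#' @param field the final \linkS4class{DisplacementField}.
#' @param cfg a \code{\link{lossConfig}}.
#' @return scalar loss.
#' @export
totalLoss <- function(fixed, warped, field, cfg = lossConfig()) {
  bumpLossCount()
  multiscaleNCC(fixed, warped, cfg$patchSizes, cfg$epsilon) +
    cfg$lambda * smoothnessLoss(field)
}
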