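#' @include volume_io.R
NULL

# Per-class mean intensities for the synthetic phantom (background stays 0 so
# the foreground-cropping assumption holds). Values are loosely modelled on
# T2-weighted contrast: fluid bright, cortical ribbon dark.
.PHANTOM_MEANS <- c(CSF = 0.90, CGM = 0.35, WM = 0.65, VTC = 0.95,
                    CRB = 0.45, THA = 0.80, BS = 0.55)

#' Specification of a synthetic multi-tissue phantom
#'
#' @param size cube side in voxels (>= 16).
#' @param nTissues number of non-background classes (<= 7).
#' @param age scalar in [0, 1]; maps linearly to overall head scale (+/-20\%)
#'   and to the amplitude of the sinusoidal cortical-boundary perturbation,
#'   giving a monotone morphology axis that emulates gestational age.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer random seed; identical specs generate bit-identical
#'   phantoms.
#' @return A validated list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(size = 32, nTissues = 7, age = 0.5, noiseSd = 0.03,
                        seed = 1) {
  if (size < 16) stopUsage("phantom size must be >= 16 (regions degenerate)")
  if (nTissues < 1 || nTissues > 7) stopUsage("nTissues must be in 1..7")
  if (age < 0 || age > 1) stopUsage("age must lie in [0, 1]")
  if (noiseSd < 0) stopUsage("noiseSd must be >= 0")
  structure(list(size = as.integer(size), nTissues = as.integer(nTissues),
                 age = age, noiseSd = noiseSd, seed = as.integer(seed)),
            class = c("phantomSpec", "list"))
}

#' Specification of a smooth random ground-truth deformation
#'
#' @param size cube side in voxels.
#' @param maxDisp maximum displacement magnitude in voxels (>= 0).
#' @param smoothnessSigma Gaussian smoothing scale in voxels (> 0).
#' @param seed integer random seed.
#' @return A validated list of class \code{deformationSpec}.
#' @export
deformationSpec <- function(size = 32, maxDisp = 4, smoothnessSigma = 4,
                            seed = 1) {
  if (maxDisp < 0) stopUsage("maxDisp must be >= 0")
  if (smoothnessSigma <= 0) stopUsage("smoothnessSigma must be > 0")
  structure(list(size = as.integer(size), maxDisp = maxDisp,
                 smoothnessSigma = smoothnessSigma, seed = as.integer(seed)),
            class = c("deformationSpec", "list"))
}

# Separable Gaussian smoothing along one axis via a row-normalized band
# matrix (kernels are renormalized at the edges, avoiding boundary
# darkening).
.gauss_axis <- function(arr, sigma, axis) {
  d <- dim(arr)
  n <- d[axis]
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  out <- K %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

gaussSmooth3d <- function(arr, sigma) {
  for (ax in 1:3) arr <- .gauss_axis(arr, sigma, ax)
  arr
}

# Paint the nested-region geometry. Returns an integer array of class ids.
.phantom_labels <- function(size, nTissues, age) {
  n <- size
  u <- (2 * (seq_len(n) - 0.5) / n) - 1   # voxel centres in [-1, 1]
  X <- array(rep.int(u, n * n), c(n, n, n))
  Y <- array(rep.int(rep(u, each = n), n), c(n, n, n))
  Z <- array(rep(u, each = n * n), c(n, n, n))
  s <- 0.78 * (1 + 0.4 * (age - 0.5))     # +/-20% global scale across age
  A <- s * c(0.95, 0.85, 0.80)            # head semi-axes
  r2 <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2
  lab <- array(0L, c(n, n, n))
  head <- r2(0, 0, 0.02, A[1], A[2], A[3])
  lab[head <= 1] <- 1L                                        # CSF shell
  if (nTissues >= 2) {
    # cortical surface with a sinusoidal perturbation growing with age
    theta <- atan2(Y, X)
    amp <- 0.03 + 0.09 * age
    pert <- 1 + amp * sin(5 * theta) * cos(4 * pi * Z)
    lab[r2(0, 0, 0.02, 0.86 * A[1], 0.86 * A[2], 0.86 * A[3]) <=
          pert^2] <- 2L                                       # CGM ribbon
  }
  if (nTissues >= 3)
    lab[r2(0, 0, 0.04, 0.70 * A[1], 0.70 * A[2], 0.68 * A[3]) <= 1] <- 3L # WM
  inHead <- head <= 1
  if (nTissues >= 5) {
    # cerebellum + brain stem occupy the inferior-posterior compartment
    lab[r2(0, -0.40 * s, -0.40 * s, 0.40 * s, 0.28 * s, 0.24 * s) <= 1 &
          inHead] <- 5L
    if (nTissues >= 7)
      lab[r2(0, -0.10 * s, -0.48 * s, 0.17 * s, 0.17 * s, 0.30 * s) <= 1 &
            inHead] <- 7L
  }
  if (nTissues >= 4) {
    # two ventricle lobes inside the white matter
    vt <- (r2(-0.22 * s, 0.14 * s, 0.14 * s, 0.16 * s, 0.26 * s, 0.16 * s) <= 1) |
          (r2(0.22 * s, 0.14 * s, 0.14 * s, 0.16 * s, 0.26 * s, 0.16 * s) <= 1)
    lab[vt & lab == 3L] <- 4L
  }
  if (nTissues >= 6)
    lab[r2(0, -0.06 * s, -0.02 * s, 0.22 * s, 0.18 * s, 0.17 * s) <= 1 &
          lab == 3L] <- 6L                                     # thalamus
  lab
}

#' Generate a synthetic multi-tissue phantom
#'
#' Builds nested ellipsoidal "brain" regions (CSF shell, cortical ribbon
#' with sinusoidal boundary perturbation, white-matter interior, paired
#' ventricles, cerebellum, thalamus, brain stem), assigns each region a
#' distinct mean intensity, adds Gaussian noise on the foreground, clips to
#' [0, 1] and rescales so intensities span [0, 1] exactly.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{volume} (\linkS4class{Volume}) and \code{labels}
#'   (\linkS4class{LabelMap}).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  lab <- .phantom_labels(spec$size, spec$nTissues, spec$age)
  means <- c(0, .PHANTOM_MEANS)[lab + 1L]
  vol <- array(means, dim(lab))
  if (spec$noiseSd > 0) {
    fg <- lab > 0L
    noise <- withSeed(spec$seed, rnorm(sum(fg), 0, spec$noiseSd))
    vol[fg] <- pmin(pmax(vol[fg] + noise, 0), 1)
  }
  if (max(vol) > 0) vol <- vol / max(vol)
  list(volume = Volume(vol),
       labels = LabelMap(lab, classes = unname(TISSUE_CLASSES)))
}

#' Generate a smooth random displacement field
#'
#' White-noise 3-vector grid, Gaussian-smoothed at scale
#' \code{smoothnessSigma}, mean-centred per component, and rescaled so the
#' largest voxel displacement norm equals \code{maxDisp} exactly.
#'
#' @param spec a \code{\link{deformationSpec}}.
#' @return A \linkS4class{DisplacementField}.
#' @export
makeSmoothField <- function(spec) {
  stopifnot(inherits(spec, "deformationSpec"))
  n <- spec$size
  if (spec$maxDisp == 0)
    return(DisplacementField(array(0, c(n, n, n, 3))))
  raw <- withSeed(spec$seed, array(rnorm(n^3 * 3), c(n, n, n, 3)))
  sm <- array(0, c(n, n, n, 3))
  for (c in 1:3) {
    comp <- gaussSmooth3d(raw[, , , c], spec$smoothnessSigma)
    sm[, , , c] <- comp - mean(comp)
  }
  mag <- sqrt(sm[, , , 1]^2 + sm[, , , 2]^2 + sm[, , , 3]^2)
  DisplacementField(sm * (spec$maxDisp / max(mag)))
}

#' Generate a registration test pair with known ground truth
#'
#' The fixed image is a noise-free phantom; the moving image is the phantom
#' warped by a smooth random ground-truth field (labels propagated with
#' nearest-neighbour). Independent noise realizations are then added to the
#' two volumes. Registering moving to fixed should approximately undo the
#' truth field.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param dspec a \code{\link{deformationSpec}} of matching size.
#' @return list with \code{fixed}, \code{moving} (\linkS4class{Volume}),
#'   \code{fixedLabels}, \code{movingLabels} (\linkS4class{LabelMap}) and
#'   \code{truthField} (\linkS4class{DisplacementField}).
#' @export
makePair <- function(spec, dspec) {
  stopifnot(inherits(spec, "phantomSpec"), inherits(dspec, "deformationSpec"))
  if (spec$size != dspec$size)
    stopUsage("phantom and deformation sizes differ: ",
              spec$size, " vs ", dspec$size)
  clean <- makePhantom(phantomSpec(spec$size, spec$nTissues, spec$age,
                                   noiseSd = 0, seed = spec$seed))
  truth <- makeSmoothField(dspec)
  movingVol <- warpVolume(clean$volume, truth, "linear")
  movingLab <- warpLabels(clean$labels, truth)
  addNoise <- function(vol, lab, seed) {
    if (spec$noiseSd == 0) return(vol)
    a <- vol@data
    fg <- lab@data > 0L
    a[fg] <- pmin(pmax(a[fg] + withSeed(seed, rnorm(sum(fg), 0, spec$noiseSd)),
                       0), 1)
    Volume(a, spacing = vol@spacing, affine = vol@affine)
  }
  list(fixed = addNoise(clean$volume, clean$labels, spec$seed + 101L),
       moving = addNoise(movingVol, movingLab, spec$seed + 211L),
       fixedLabels = clean$labels,
       movingLabels = movingLab,
       truthField = truth)
}

#' Generate a cohort of phantoms along an age axis
#'
#' Ages are sampled evenly over \code{ageRange}; each phantom gets a
#' distinct seed derived from the base seed. Serves as an atlas library for
#' multi-atlas segmentation experiments.
#'
#' @param n number of phantoms (>= 2).
#' @param baseSpec a \code{\link{phantomSpec}} providing size, tissue count,
#'   noise level and base seed.
#' @param ageRange length-2 increasing interval inside [0, 1].
#' @return list of \code{n} elements, each with \code{volume}, \code{labels}
#'   and \code{age}; ages strictly increasing.
#' @export
makeCohort <- function(n, baseSpec, ageRange = c(0.2, 0.9)) {
  stopifnot(inherits(baseSpec, "phantomSpec"))
  if (n < 2) stopUsage("cohort size must be >= 2")
  if (length(ageRange) != 2 || ageRange[2] <= ageRange[1])
    stopUsage("ageRange must be a non-empty increasing interval")
  ages <- seq(ageRange[1], ageRange[2], length.out = n)
  lapply(seq_len(n), function(i) {
    ph <- makePhantom(phantomSpec(baseSpec$size, baseSpec$nTissues, ages[i],
                                  baseSpec$noiseSd,
                                  seed = baseSpec$seed + 7919L * i))
    list(volume = ph$volume, labels = ph$labels, age = ages[i])
  })
}
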