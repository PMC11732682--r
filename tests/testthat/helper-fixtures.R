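# Shared fixtures, built in code. Kept tiny so each file runs in seconds.

tinyVolume <- function(n = 8, seed = 1) {
  Volume(CascadeReg:::withSeed(seed, array(runif(n^3), c(n, n, n))))
}

rampVolume <- function(n = 12, axis = 1) {
  idx <- switch(axis,
    rep(seq_len(n), n * n),
    rep(rep(seq_len(n), each = n), n),
    rep(seq_len(n), each = n * n))
  Volume(array(idx / n, c(n, n, n)))
}

constantField <- function(n, v) {
  DisplacementField(array(rep(v, each = n^3), c(n, n, n, 3)))
}

zeroField <- function(n) constantField(n, c(0, 0, 0))

# small random label map over classes 0..3
tinyLabels <- function(n = 10, seed = 4) {
  LabelMap(CascadeReg:::withSeed(seed, array(sample(0:3, n^3, replace = TRUE),
                                             c(n, n, n))),
           classes = 0:3)
}

# a tiny trainable configuration (16^3, 2 levels) for fast network tests
tinyProfile <- function(nCascades = 2, patchSizes = 5, lambda = 1,
                        seed = 1, epochs = 2, itersPerEpoch = 2) {
  bb <- backboneConfig(encChannels = c(4, 8), decChannels = c(8))
  list(cascade = cascadeConfig(nCascades = nCascades, backbone = bb,
                               imageSize = 16),
       loss = lossConfig(patchSizes = patchSizes, lambda = lambda),
       train = trainConfig(epochs = epochs, itersPerEpoch = itersPerEpoch,
                           batchSize = 1, baseLr = 3e-3, seed = seed))
}

tinyPair <- function(n = 16, maxDisp = 2, sigma = 3, seed = 7) {
  makePair(phantomSpec(n, seed = seed),
           deformationSpec(n, maxDisp, sigma, seed = seed + 50L))
}

# brute-force oracles ---------------------------------------------------

# all-pairs one-sided percentile Hausdorff distance
bruteOneSidedHD <- function(aMask, bMask, percentile = 100,
                            spacing = c(1, 1, 1)) {
  A <- which(aMask, arr.ind = TRUE)
  B <- which(bMask, arr.ind = TRUE)
  A <- sweep(A, 2, spacing, `*`)
  B <- sweep(B, 2, spacing, `*`)
  mins <- apply(A, 1, function(p)
    sqrt(min(colSums((t(B) - p)^2))))
  unname(quantile(mins, percentile / 100, type = 7))
}

# direct per-window local-NCC loss (valid windows only)
bruteLocalNCC <- function(f, g, d, eps = 1e-5) {
  r <- (d - 1) / 2
  dims <- dim(f)
  total <- 0; nval <- 0
  for (i in (r + 1):(dims[1] - r))
    for (j in (r + 1):(dims[2] - r))
      for (l in (r + 1):(dims[3] - r)) {
        wf <- f[(i - r):(i + r), (j - r):(j + r), (l - r):(l + r)]
        wg <- g[(i - r):(i + r), (j - r):(j + r), (l - r):(l + r)]
        cross <- sum((wf - mean(wf)) * (wg - mean(wg)))
        vf <- sum((wf - mean(wf))^2); vg <- sum((wg - mean(wg))^2)
        total <- total + cross^2 / ((vf + eps) * (vg + eps))
        nval <- nval + 1
      }
  -total / nval
}

# direct smoothness energy: mean squared forward difference per partial
bruteSmoothness <- function(phi) {
  d <- dim(phi)[1:3]
  tot <- 0
  for (comp in 1:3) {
    a <- phi[, , , comp]
    tot <- tot + mean((a[2:d[1], , ] - a[1:(d[1] - 1), , ])^2) +
      mean((a[, 2:d[2], ] - a[, 1:(d[2] - 1), ])^2) +
      mean((a[, , 2:d[3]] - a[, , 1:(d[3] - 1)])^2)
  }
  tot
}

# direct central-difference Jacobian determinant at one interior voxel
bruteJacDet <- function(phi, i, j, l) {
  J <- diag(3)
  for (c in 1:3) {
    J[c, 1] <- J[c, 1] + (phi[i + 1, j, l, c] - phi[i - 1, j, l, c]) / 2
    J[c, 2] <- J[c, 2] + (phi[i, j + 1, l, c] - phi[i, j - 1, l, c]) / 2
    J[c, 3] <- J[c, 3] + (phi[i, j, l + 1, c] - phi[i, j, l - 1, c]) / 2
  }
  det(J)
}
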