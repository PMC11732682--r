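#' @include AllClasses.R
NULL

# Exact 1-D squared-distance transform (lower envelope of parabolas) with a
# per-axis sample spacing w; f holds squared distances, Inf allowed.
.dt1d <- function(f, w) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf; z[2] <- Inf
  w2 <- w * w
  for (q in 2:n) {
    if (is.infinite(f[q])) next
    repeat {
      p <- v[k]
      s <- if (is.infinite(f[p])) -Inf
           else ((f[q] + w2 * q^2) - (f[p] + w2 * p^2)) / (2 * w2 * (q - p))
      if (s <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    if (is.infinite(f[v[k]])) {
      v[k] <- q
      z[k + 1L] <- Inf
    } else {
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- w2 * (q - p)^2 + f[p]
  }
  d
}

.dt_axis <- function(arr, w, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(is.infinite(col))) next
    m[, j] <- .dt1d(col, w)
  }
  aperm(array(m, dim = d[perm]), order(perm))
}

# Exact Euclidean distance transform: squared distance from every voxel
# centre to the nearest TRUE voxel centre of `mask`, in spacing-scaled
# coordinates.
edtSquared <- function(mask, spacing = c(1, 1, 1)) {
  f <- array(Inf, dim(mask))
  f[mask] <- 0
  for (ax in 1:3) f <- .dt_axis(f, spacing[ax], ax)
  f
}

.as_mask <- function(x, classId = NULL) {
  if (is(x, "LabelMap")) {
    if (is.null(classId)) stopUsage("classId required with a LabelMap")
    x@data == classId
  } else if (is.logical(x)) x else x != 0
}

#' Dice similarity coefficient
#'
#' 2 |A intersect B| / (|A| + |B|) on the binary masks of \code{classId}.
#'
#' @param a,b \linkS4class{LabelMap}s (or logical arrays) of equal shape.
#' @param classId the class to compare (ignored for logical masks).
#' @return Dice in [0, 1].
#' @export
diceScore <- function(a, b, classId = NULL) {
  ma <- .as_mask(a, classId); mb <- .as_mask(b, classId)
  if (!sameDim3(ma, mb)) stopUsage("mask shapes do not match")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0)
    stopData("class absent from both maps: Dice undefined (0/0)")
  2 * sum(ma & mb) / (na + nb)
}

#' Mean Dice over foreground classes
#'
#' @param a,b \linkS4class{LabelMap}s of equal shape.
#' @param classes classes to average over; defaults to the non-background
#'   classes present in either map.
#' @return mean Dice.
#' @export
meanForegroundDice <- function(a, b, classes = NULL) {
  if (is.null(classes)) {
    present <- sort(unique(c(unique(as.vector(a@data)),
                             unique(as.vector(b@data)))))
    classes <- setdiff(present, 0L)
  }
  mean(vapply(classes, function(k) diceScore(a, b, k), 0))
}

#' One-sided (percentile) Hausdorff distance
#'
#' The stated percentile of the set of minimum Euclidean distances from
#' every voxel of mask a to mask b, in spacing-scaled coordinates. All mask
#' voxels participate (no surface extraction). Percentile 100 is the
#' classical one-sided Hausdorff maximum; 95 the robust variant.
#' Percentiles interpolate linearly between order statistics.
#'
#' @param aMask,bMask non-empty logical arrays (or 0/1 arrays).
#' @param percentile percentile in (0, 100], default 100.
#' @param spacing per-axis voxel size.
#' @return the distance (same units as spacing).
#' @export
oneSidedHD <- function(aMask, bMask, percentile = 100, spacing = c(1, 1, 1)) {
  ma <- .as_mask(aMask); mb <- .as_mask(bMask)
  if (!sameDim3(ma, mb)) stopUsage("mask shapes do not match")
  if (!any(ma) || !any(mb)) stopData("empty mask: Hausdorff undefined")
  dist <- sqrt(edtSquared(mb, spacing)[ma])
  unname(quantile(dist, percentile / 100, type = 7))
}

#' 95th-percentile bidirectional Hausdorff distance
#'
#' Maximum of the two one-sided 95th-percentile distances (the percentile is
#' applied per direction, then the maximum taken). Set
#' \code{pooled = TRUE} to instead take the 95th percentile of the pooled
#' two-directional distance set.
#'
#' @param aMask,bMask non-empty masks of equal shape.
#' @param spacing per-axis voxel size.
#' @param percentile percentile (default 95).
#' @param pooled pool the two directions before taking the percentile.
#' @return the distance.
#' @export
hd95 <- function(aMask, bMask, spacing = c(1, 1, 1), percentile = 95,
                 pooled = FALSE) {
  ma <- .as_mask(aMask); mb <- .as_mask(bMask)
  if (!sameDim3(ma, mb)) stopUsage("mask shapes do not match")
  if (!any(ma) || !any(mb)) stopData("empty mask: Hausdorff undefined")
  if (pooled) {
    d1 <- sqrt(edtSquared(mb, spacing)[ma])
    d2 <- sqrt(edtSquared(ma, spacing)[mb])
    return(unname(quantile(c(d1, d2), percentile / 100, type = 7)))
  }
  max(oneSidedHD(ma, mb, percentile, spacing),
      oneSidedHD(mb, ma, percentile, spacing))
}

#' Standard error of a sample
#'
#' sigma / sqrt(n) with sigma the standard deviation under the population
#' divisor n (set \code{divisor = "n-1"} for the sample divisor).
#'
#' @param values numeric vector, length >= 2.
#' @param divisor "n" (default) or "n-1".
#' @return the standard error.
#' @export
stdError <- function(values, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  n <- length(values)
  if (n < 2) stopUsage("need at least 2 values for a standard error")
  sigma <- if (divisor == "n") sqrt(mean((values - mean(values))^2))
           else sd(values)
  sigma / sqrt(n)
}

#' Per-class overlap report
#'
#' Dice and HD95 for every class present in either map, plus averages with
#' standard errors. Classes absent from both maps are reported as missing
#' (NA), not zero; HD95 is NA when a class is present on only one side.
#'
#' @param fixedLabels,warpedLabels \linkS4class{LabelMap}s of equal shape.
#' @param classes classes to report; default: the declared non-background
#'   classes.
#' @param spacing per-axis voxel size for the distances.
#' @return data.frame with columns class, dice, hd95, present; the rows are
#'   per class with a final "average" row, and the averages' standard errors
#'   are in attributes \code{diceSE} / \code{hd95SE}.
#' @export
overlapReport <- function(fixedLabels, warpedLabels, classes = NULL,
                          spacing = c(1, 1, 1)) {
  stopifnot(is(fixedLabels, "LabelMap"), is(warpedLabels, "LabelMap"))
  if (!sameDim3(fixedLabels@data, warpedLabels@data))
    stopUsage("label map shapes do not match")
  if (is.null(classes))
    classes <- setdiff(fixedLabels@classes, 0L)
  rows <- lapply(classes, function(k) {
    ma <- fixedLabels@data == k
    mb <- warpedLabels@data == k
    inA <- any(ma); inB <- any(mb)
    if (!inA && !inB)
      return(data.frame(class = k, dice = NA_real_, hd95 = NA_real_,
                        present = FALSE))
    dc <- 2 * sum(ma & mb) / (sum(ma) + sum(mb))
    hd <- if (inA && inB) hd95(ma, mb, spacing) else NA_real_
    data.frame(class = k, dice = dc, hd95 = hd, present = TRUE)
  })
  tab <- do.call(rbind, rows)
  got <- tab[tab$present, , drop = FALSE]
  avg <- data.frame(class = NA_integer_, dice = mean(got$dice),
                    hd95 = mean(got$hd95, na.rm = TRUE), present = TRUE)
  out <- rbind(tab, avg)
  rownames(out) <- c(paste0("class_", classes), "average")
  attr(out, "diceSE") <- if (nrow(got) >= 2) stdError(got$dice) else NA_real_
  hdv <- got$hd95[!is.na(got$hd95)]
  attr(out, "hd95SE") <- if (length(hdv) >= 2) stdError(hdv) else NA_real_
  out
}

#' Write an overlap report to CSV and JSON
#'
#' @param report result of \code{\link{overlapReport}}.
#' @param csvPath,jsonPath output paths (either may be NULL).
#' @return invisibly, the written paths.
#' @export
writeOverlapReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) write.csv(report, csvPath, row.names = TRUE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(rows = report, dice_se = attr(report, "diceSE"),
           hd95_se = attr(report, "hd95SE")),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  invisible(list(csv = csvPath, json = jsonPath))
}
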