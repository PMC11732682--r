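test_that("Dice matches direct counts and its boundary cases", {
  lab <- tinyLabels(10)
  expect_equal(diceScore(lab, lab, 1), 1)
  a <- array(0L, c(6, 6, 6)); b <- a
  a[1:2, 1, 1] <- 1L; b[5:6, 6, 6] <- 1L
  A <- LabelMap(a, 0:1); B <- LabelMap(b, 0:1)
  expect_equal(diceScore(A, B, 1), 0)
  # |A| = |B| = 4, |A intersect B| = 2 -> 0.5
  a2 <- array(0L, c(6, 6, 6)); b2 <- a2
  a2[1:4, 1, 1] <- 1L; b2[3:6, 1, 1] <- 1L
  expect_equal(diceScore(LabelMap(a2, 0:1), LabelMap(b2, 0:1), 1), 0.5)
  # symmetry; equality iff masks equal
  expect_equal(diceScore(A, B, 1), diceScore(B, A, 1))
  expect_lt(diceScore(LabelMap(a2, 0:1), LabelMap(b2, 0:1), 1), 1)
  expect_error(diceScore(A, B, 0:0 + 99), class = "dataError")
})

test_that("one-sided Hausdorff matches hand values and the all-pairs oracle", {
  m <- array(FALSE, c(10, 10, 10))
  m[3, 4, 5] <- TRUE
  expect_equal(oneSidedHD(m, m), 0)
  b <- array(FALSE, c(10, 10, 10))
  b[6, 8, 5] <- TRUE   # offset (3,4,0) -> distance 5
  expect_equal(oneSidedHD(m, b), 5)
  set.seed(3)
  ra <- array(runif(1000) < 0.1, c(10, 10, 10))
  rb <- array(runif(1000) < 0.1, c(10, 10, 10))
  for (p in c(100, 95, 50))
    expect_equal(oneSidedHD(ra, rb, p), bruteOneSidedHD(ra, rb, p),
                 tolerance = 1e-9)
  # anisotropic spacing
  sp <- c(0.5, 2, 1.3)
  expect_equal(oneSidedHD(ra, rb, 95, sp), bruteOneSidedHD(ra, rb, 95, sp),
               tolerance = 1e-9)
  expect_error(oneSidedHD(ra, array(FALSE, c(10, 10, 10))), "empty",
               class = "dataError")
})

test_that("HD95 is the direction-wise max, bounded by HD100, symmetric", {
  set.seed(4)
  ra <- array(runif(1000) < 0.08, c(10, 10, 10))
  rb <- array(runif(1000) < 0.08, c(10, 10, 10))
  expect_equal(hd95(ra, ra), 0)
  expect_equal(hd95(ra, rb),
               max(bruteOneSidedHD(ra, rb, 95), bruteOneSidedHD(rb, ra, 95)),
               tolerance = 1e-9)
  expect_lte(hd95(ra, rb), max(oneSidedHD(ra, rb), oneSidedHD(rb, ra)))
  expect_equal(hd95(ra, rb), hd95(rb, ra))
  # two offset cubes against the oracle
  ca <- array(FALSE, c(12, 12, 12)); cb <- ca
  ca[2:5, 2:5, 2:5] <- TRUE; cb[5:8, 6:9, 4:7] <- TRUE
  expect_equal(hd95(ca, cb),
               max(bruteOneSidedHD(ca, cb, 95), bruteOneSidedHD(cb, ca, 95)),
               tolerance = 1e-9)
  # pooled variant also agrees with its sort-based definition
  pool <- quantile(c(apply(which(ca, arr.ind = TRUE), 1, function(p)
                       sqrt(min(colSums((t(which(cb, arr.ind = TRUE))
                                         - p)^2)))),
                     apply(which(cb, arr.ind = TRUE), 1, function(p)
                       sqrt(min(colSums((t(which(ca, arr.ind = TRUE))
                                         - p)^2))))),
                   0.95, type = 7)
  expect_equal(hd95(ca, cb, pooled = TRUE), unname(pool), tolerance = 1e-9)
})

test_that("standard errors use the population divisor and 1/sqrt(n) scaling", {
  expect_equal(stdError(c(3, 3, 3, 3)), 0)
  expect_equal(stdError(c(0, 2)), 1 / sqrt(2))          # sigma = 1 under /n
  expect_equal(stdError(c(0, 2), divisor = "n-1"), 1)   # sd = sqrt(2)
  x <- c(1, 4, 2, 8, 5)
  expect_equal(stdError(rep(x, 4)), stdError(x) / 2, tolerance = 1e-12)
  expect_error(stdError(1), "at least 2", class = "usageError")
})

test_that("overlap reports aggregate per-class rows correctly", {
  lab <- makePhantom(phantomSpec(24, seed = 6))$labels
  rep0 <- overlapReport(lab, lab)
  got <- rep0[rep0$present & !is.na(rep0$class), ]
  expect_true(all(got$dice == 1))
  expect_true(all(got$hd95 == 0))
  expect_equal(rep0["average", "dice"], 1)
  # averages recompute from the per-class rows
  f <- makeSmoothField(deformationSpec(24, 3, 3, seed = 7))
  warped <- warpLabels(lab, f)
  rp <- overlapReport(lab, warped)
  rows <- rp[!is.na(rp$class) & rp$present, ]
  expect_equal(rp["average", "dice"], mean(rows$dice), tolerance = 1e-12)
  expect_equal(attr(rp, "diceSE"), stdError(rows$dice), tolerance = 1e-12)
  # a class absent from both maps is reported missing, not zero
  small <- LabelMap(array(c(0L, 1L), c(4, 4, 4)), classes = 0:5)
  rs <- overlapReport(small, small)
  expect_false(rs["class_5", "present"])
  expect_true(is.na(rs["class_5", "dice"]))
  # report writers produce parseable files
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeOverlapReport(rp, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_equal(nrow(utils::read.csv(csv)), nrow(rp))
  expect_true(is.list(jsonlite::read_json(js)))
})
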