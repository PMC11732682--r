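test_that("NIfTI round-trip preserves data, spacing and affine", {
  vol <- tinyVolume(8, seed = 2)
  aff <- diag(c(1.5, 2, 2.5, 1)); aff[1:3, 4] <- c(10, -4, 3)
  vol <- Volume(volData(vol), spacing = c(1.5, 2, 2.5), affine = aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_equal(volData(back), volData(vol), tolerance = 1e-6)
  expect_equal(volSpacing(back), c(1.5, 2, 2.5), tolerance = 1e-6)
  expect_equal(volAffine(back)[1:3, 4], c(10, -4, 3), tolerance = 1e-5)

  lab <- tinyLabels(8)
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabels(lab, fl)
  labBack <- readLabels(fl, classes = 0:3)
  expect_identical(labelData(labBack), labelData(lab))

  fld <- DisplacementField(array(rnorm(8^3 * 3), c(8, 8, 8, 3)))
  ff <- withr::local_tempfile(fileext = ".nii.gz")
  writeField(fld, ff)
  expect_equal(fieldVectors(readField(ff)), fieldVectors(fld),
               tolerance = 1e-6)
})

test_that("read errors are distinct and classed", {
  expect_error(readVolume(file.path(tempdir(), "nope.nii.gz")),
               "file not found", class = "dataError")
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(readVolume(f4), "not a 3-D volume", class = "dataError")
  fbad <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti at all", fbad)
  expect_error(readVolume(fbad), "unreadable", class = "dataError")
})

test_that("foreground cropping finds the tight box plus margin", {
  a <- array(0, c(16, 16, 16))
  a[7:10, 7:10, 7:10] <- 1   # bright 4^3 block at offset (6,6,6)
  vol <- Volume(a)
  expect_equal(dim(cropToForeground(vol, margin = 0)$volume), c(4, 4, 4))
  expect_equal(dim(cropToForeground(vol, margin = 2)$volume), c(8, 8, 8))
  # fully bright volume is unchanged
  expect_equal(dim(cropToForeground(Volume(a * 0 + 1), margin = 0)$volume),
               c(16, 16, 16))
  expect_error(cropToForeground(Volume(a * 0)), "background",
               class = "dataError")
  # labels are cropped with the same box
  lab <- LabelMap(array(as.integer(a), dim(a)), classes = 0:1)
  cr <- cropToForeground(vol, lab, margin = 1)
  expect_equal(dim(cr$labels), dim(cr$volume))
})

test_that("resizing is exact at identity, on constants, and on ramps", {
  vol <- tinyVolume(9, seed = 5)
  expect_equal(volData(resizeToCube(vol, 9)$volume), volData(vol),
               tolerance = 1e-12)
  cvol <- Volume(array(0.37, c(6, 6, 6)))
  expect_equal(volData(resizeToCube(cvol, 11)$volume),
               array(0.37, c(11, 11, 11)), tolerance = 1e-12)
  # 2x upsampling of a linear ramp matches the closed-form interpolant
  n <- 6
  ramp <- Volume(array(rep(seq_len(n), n * n), c(n, n, n)))
  up <- resizeToCube(ramp, 2 * n)$volume
  expected <- 1 + (seq_len(2 * n) - 1) * (n - 1) / (2 * n - 1)
  expect_equal(volData(up)[, 3, 3], expected, tolerance = 1e-12)
  expect_error(resizeToCube(vol, 1), "size", class = "usageError")
  # labels resampled nearest keep the class set
  lab <- tinyLabels(9)
  rs <- resizeToCube(tinyVolume(9), 13, lab)
  expect_true(all(labelData(rs$labels) %in% 0:3))
})

test_that("intensity normalization spans [0,1] and rejects constants", {
  v <- Volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
  nv <- normalizeIntensity(v)
  expect_equal(sort(unique(as.vector(volData(nv)))), c(0, 0.5, 1))
  v01 <- tinyVolume(6, seed = 8)
  d <- volData(v01); d[1] <- 0; d[2] <- 1
  expect_equal(volData(normalizeIntensity(Volume(d))), d)
  expect_error(normalizeIntensity(Volume(array(5, c(3, 3, 3)))),
               "constant", class = "dataError")
})

test_that("the crop-resize-normalize pipeline is deterministic", {
  ph <- makePhantom(phantomSpec(24, seed = 11))
  p1 <- preprocessVolume(ph$volume, ph$labels, size = 16)
  p2 <- preprocessVolume(ph$volume, ph$labels, size = 16)
  expect_identical(volData(p1$volume), volData(p2$volume))
  expect_identical(labelData(p1$labels), labelData(p2$labels))
  expect_equal(range(volData(p1$volume)), c(0, 1))
})
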