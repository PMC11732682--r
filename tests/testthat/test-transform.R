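test_that("warping honours identity, integer shifts and half shifts", {
  ramp <- rampVolume(12)
  expect_equal(volData(warpVolume(ramp, zeroField(12))), volData(ramp))
  # +1 voxel shift along axis 1: interior matches the index oracle
  sh1 <- constantField(12, c(1, 0, 0))
  w1 <- volData(warpVolume(ramp, sh1))
  expect_equal(w1[1:11, , ], volData(ramp)[2:12, , ])
  # +0.5 voxel shift: midpoint average of neighbours
  sh05 <- constantField(12, c(0.5, 0, 0))
  w05 <- volData(warpVolume(ramp, sh05))
  expect_equal(w05[1:11, , ],
               (volData(ramp)[1:11, , ] + volData(ramp)[2:12, , ]) / 2,
               tolerance = 1e-12)
  expect_error(warpVolume(ramp, zeroField(10)), "match",
               class = "usageError")
  expect_error(warpVolume(ramp, zeroField(12), "cubic"), "interpolation",
               class = "usageError")
})

test_that("linear warps preserve constants and never exceed the input range", {
  f <- makeSmoothField(deformationSpec(12, 2, 2, seed = 5))
  cv <- Volume(array(0.42, c(12, 12, 12)))
  expect_equal(volData(warpVolume(cv, f)), volData(cv), tolerance = 1e-12)
  v <- tinyVolume(12, seed = 6)
  w <- warpVolume(v, f)
  expect_gte(min(volData(w)), min(volData(v)))
  expect_lte(max(volData(w)), max(volData(v)))
  # zero boundary policy fills out-of-domain samples with 0
  big <- constantField(12, c(20, 0, 0))
  expect_true(all(volData(warpVolume(cv, big, boundary = "zero")) == 0))
})

test_that("label propagation shifts labels and cannot invent classes", {
  lab <- tinyLabels(10)
  expect_identical(labelData(warpLabels(lab, zeroField(10))),
                   labelData(lab))
  sh <- constantField(10, c(1, 0, 0))
  wl <- warpLabels(lab, sh)
  expect_identical(labelData(wl)[1:9, , ], labelData(lab)[2:10, , ])
  f <- makeSmoothField(deformationSpec(10, 2, 2, seed = 8))
  expect_true(all(labelData(warpLabels(lab, f)) %in% labelClasses(lab)))
  expect_error(warpLabels(lab, zeroField(8)), "match", class = "usageError")
})

test_that("field accumulation is a commutative vector sum", {
  f1 <- constantField(8, c(1, 0, 0))
  f2 <- constantField(8, c(0, 2, 0))
  f3 <- constantField(8, c(0, 0, -1))
  expect_equal(fieldVectors(accumulateFields(list(f1))), fieldVectors(f1))
  s <- accumulateFields(list(f1, f2, f3))
  expect_equal(fieldVectors(s), fieldVectors(constantField(8, c(1, 2, -1))))
  sPerm <- accumulateFields(list(f3, f1, f2))
  expect_equal(fieldVectors(s), fieldVectors(sPerm))
  neg <- DisplacementField(-fieldVectors(f1))
  expect_true(all(fieldVectors(accumulateFields(list(f1, neg))) == 0))
  expect_error(accumulateFields(list()), "empty", class = "usageError")
  expect_error(accumulateFields(list(f1, zeroField(6))), "equal shape",
               class = "usageError")
})

test_that("composition matches accumulation for constants but not in general", {
  f1 <- constantField(8, c(1, 0, 0))
  f2 <- constantField(8, c(0, 2, 0))
  expect_equal(fieldVectors(composeFields(list(f1, f2))),
               fieldVectors(accumulateFields(list(f1, f2))))
  expect_equal(fieldVectors(composeFields(list(f1))), fieldVectors(f1))
  # first-order agreement for small smooth fields
  g1 <- makeSmoothField(deformationSpec(12, 0.5, 2, seed = 2))
  g2 <- makeSmoothField(deformationSpec(12, 0.5, 2, seed = 3))
  comp <- fieldVectors(composeFields(list(g1, g2)))
  accu <- fieldVectors(accumulateFields(list(g1, g2)))
  expect_lt(max(abs(comp - accu)), 0.5^2)
  # composition is order-sensitive on a crafted pair
  h1 <- makeSmoothField(deformationSpec(12, 3, 2, seed = 4))
  h2 <- makeSmoothField(deformationSpec(12, 3, 2, seed = 5))
  ab <- fieldVectors(composeFields(list(h1, h2)))
  ba <- fieldVectors(composeFields(list(h2, h1)))
  expect_gt(max(abs(ab - ba)), 1e-3)
})

test_that("Jacobian determinants match analytic values and a direct oracle", {
  z <- jacobianReport(zeroField(8))
  expect_true(all(detMap(z) == 1))
  expect_equal(negFraction(z), 0)
  n <- 10
  g <- CascadeReg:::gridCoords(c(n, n, n))
  expand <- DisplacementField(array(0.1 * g, c(n, n, n, 3)))
  expect_equal(unique(round(as.vector(detMap(jacobianReport(expand))), 9)),
               1.331)
  # folding field: phi_x = -2x gives det -1 everywhere in the interior
  fold <- DisplacementField(array(c(-2 * g[, 1], 0 * g[, 2], 0 * g[, 3]),
                                  c(n, n, n, 3)))
  jr <- jacobianReport(fold)
  expect_equal(unique(as.vector(detMap(jr))), -1)
  expect_equal(negFraction(jr), 100)
  # random smooth field against the per-voxel brute-force determinant
  f <- makeSmoothField(deformationSpec(10, 2, 2, seed = 6))
  jr2 <- jacobianReport(f)
  phi <- fieldVectors(f)
  for (v in list(c(2, 2, 2), c(5, 6, 4), c(9, 9, 9)))
    expect_equal(detMap(jr2)[v[1] - 1, v[2] - 1, v[3] - 1],
                 bruteJacDet(phi, v[1], v[2], v[3]), tolerance = 1e-9)
  expect_error(jacobianReport(zeroField(2)), "3 voxels",
               class = "usageError")
})
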