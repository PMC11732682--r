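test_that("the backbone honours shape, zero-init and divisibility contracts", {
  prof <- tinyProfile()
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 2)
  p <- tinyPair(16, seed = 31)
  fld <- backboneForward(model, p$moving, p$fixed)
  expect_equal(dim(fieldVectors(fld)), c(16, 16, 16, 3))
  # zero-initialized emission: the untrained network predicts the zero field
  expect_true(all(fieldVectors(fld) == 0))
  expect_error(cascadeConfig(backbone = prof$cascade$backbone,
                             imageSize = 18),
               "divisible by 2\\^levels", class = "usageError")
  expect_error(backboneForward(model, tinyVolume(8), tinyVolume(8)),
               "input size", class = "usageError")
  expect_error(backboneConfig(encChannels = c(4, 8), decChannels = c(8, 4)),
               "decChannels", class = "usageError")
})

test_that("an untrained cascade is the identity map for any cascade count", {
  p <- tinyPair(16, seed = 32)
  for (n in c(1, 3)) {
    prof <- tinyProfile(nCascades = n)
    model <- initCascadeModel(prof$cascade, prof$loss, seed = 3)
    out <- cascadeForward(model, p$moving, p$fixed)
    expect_length(out$partialFields, n)
    expect_true(all(fieldVectors(out$finalField) == 0))
    expect_equal(volData(out$warped), volData(p$moving))
  }
})

test_that("one cascade behaves identically in both modes", {
  p <- tinyPair(16, seed = 33)
  base <- tinyProfile(nCascades = 1)
  model <- initCascadeModel(base$cascade, base$loss, seed = 4)
  # give it nonzero weights so the comparison is informative
  model@params <- rapply(model@params, function(x)
    x + CascadeReg:::withSeed(5, rnorm(length(x), sd = 0.01)),
    how = "replace")
  accu <- cascadeForward(model, p$moving, p$fixed)
  modelNA <- model
  modelNA@cascade$accumulate <- FALSE
  comp <- cascadeForward(modelNA, p$moving, p$fixed)
  expect_equal(volData(accu$warped), volData(comp$warped), tolerance = 1e-12)
  expect_equal(fieldVectors(accu$finalField),
               fieldVectors(comp$finalField), tolerance = 1e-12)
  single <- backboneForward(model, p$moving, p$fixed)
  expect_equal(fieldVectors(accu$partialFields[[1]]), fieldVectors(single))
})

test_that("accumulation resamples the original moving image once per cascade", {
  p <- tinyPair(16, seed = 34)
  prof <- tinyProfile(nCascades = 3)
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 6)
  CascadeReg:::resetInstrumentation()
  invisible(cascadeForward(model, p$moving, p$fixed))
  expect_equal(CascadeReg:::getInstrumentation()$warp_calls, 3L)
})

test_that("cascade gradients flow and match finite differences", {
  prof <- tinyProfile(nCascades = 2)
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 7)
  params <- rapply(model@params, function(x)
    x + CascadeReg:::withSeed(8, rnorm(length(x), sd = 0.01)), how = "replace")
  p <- tinyPair(16, seed = 35)
  mv <- volData(p$moving); fx <- volData(p$fixed)
  r <- CascadeReg:::cascLossGrad(params, model@cascade, mv, fx, model@loss)
  expect_true(is.finite(r$loss))
  # gradient is nonzero somewhere in every cascade
  for (k in 1:2)
    expect_gt(max(abs(unlist(r$grads[[k]]))), 0)
  # spot-check against central finite differences
  eps <- 1e-5
  leaf <- params[[1]]$enc[[1]]$W
  for (i in c(11, 101)) {
    pp <- params; pp[[1]]$enc[[1]]$W[i] <- leaf[i] + eps
    pm <- params; pm[[1]]$enc[[1]]$W[i] <- leaf[i] - eps
    fd <- (CascadeReg:::cascLossGrad(pp, model@cascade, mv, fx,
                                     model@loss)$loss -
             CascadeReg:::cascLossGrad(pm, model@cascade, mv, fx,
                                       model@loss)$loss) / (2 * eps)
    expect_equal(r$grads[[1]]$enc[[1]]$W[i], fd, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip the full model", {
  prof <- tinyProfile(nCascades = 2)
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  expect_equal(back@params, model@params)
  expect_equal(back@cascade, model@cascade)
  expect_equal(numParameters(back), numParameters(model))
  expect_error(loadCheckpoint(file.path(tempdir(), "missing.rds")),
               "not found", class = "dataError")
  notck <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notck)
  expect_error(loadCheckpoint(notck), "not a CascadeReg checkpoint",
               class = "dataError")
})
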