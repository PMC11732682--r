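makeTinyAtlases <- function(n = 4, size = 16, seed = 61) {
  coh <- makeCohort(n, phantomSpec(size, seed = seed))
  AtlasSet(lapply(coh, `[[`, "volume"), lapply(coh, `[[`, "labels"),
           meta = data.frame(age = vapply(coh, `[[`, 0, "age")))
}

test_that("atlas registration returns one triplet per atlas", {
  atl <- makeTinyAtlases(3)
  prof <- tinyProfile()
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 14)
  target <- makePhantom(phantomSpec(16, age = 0.5, seed = 77))$volume
  reg <- registerAtlases(target, atl, model)
  expect_length(reg, 3)
  # untrained model is the identity: warped atlas equals the atlas
  for (k in 1:3) {
    expect_equal(volData(reg[[k]]$warped), volData(atlasVolumes(atl)[[k]]))
    expect_identical(labelData(reg[[k]]$labels),
                     labelData(atlasLabels(atl)[[k]]))
  }
  expect_error(registerAtlases(target, AtlasSet(list(), list()), model),
               "empty", class = "usageError")
})

test_that("ranking puts an exact copy first under every metric", {
  target <- makePhantom(phantomSpec(16, age = 0.4, seed = 78))$volume
  others <- lapply(1:3, function(i)
    makePhantom(phantomSpec(16, age = 0.8, seed = 80 + i))$volume)
  warped <- c(list(target), others)
  for (m in c("NCC", "MSE", "SSIM")) {
    rk <- rankAtlases(target, warped, m)
    expect_equal(rk$index[1], 1)
  }
  rkN <- rankAtlases(target, warped, "NCC")
  expect_equal(rkN$score[1], 1, tolerance = 1e-12)
  rkM <- rankAtlases(target, warped, "MSE")
  expect_equal(rkM$score[1], 0, tolerance = 1e-12)
  # MSE of constant offsets ranks the smaller offset first
  off <- lapply(c(0.2, 0.1), function(d)
    Volume(pmin(volData(target) + d, 1)))
  rkO <- rankAtlases(target, off, "MSE")
  expect_equal(rkO$index, c(2, 1))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  rkP <- rankAtlases(target, warped[perm], "NCC")
  expect_equal(perm[rkP$index[1]], 1)
  expect_error(rankAtlases(target, list(), "NCC"), "empty",
               class = "usageError")
})

test_that("majority voting is modal with lowest-class tie-breaks", {
  base <- array(0L, c(6, 6, 6))
  m1 <- LabelMap(base + 1L, 0:3)
  m2 <- LabelMap(base + 1L, 0:3)
  m3 <- LabelMap(base + 2L, 0:3)
  expect_true(all(labelData(majorityVote(list(m1, m2, m3))) == 1L))
  # unanimity returns the map itself
  expect_identical(labelData(majorityVote(list(m3, m3))), labelData(m3))
  # 1 vs 2 tie -> lowest class id wins
  expect_true(all(labelData(majorityVote(list(m1, m3))) == 1L))
  expect_error(majorityVote(list()), "empty", class = "usageError")
})

test_that("local weighted voting favours the locally matching atlas", {
  # target with two-valued structure; atlas A matches it exactly, atlas B is
  # anti-correlated, and the two disagree on the label everywhere
  set.seed(5)
  t <- array(runif(9^3), c(9, 9, 9))
  target <- Volume(t)
  atlA <- Volume(t)
  atlB <- Volume(1 - t)
  labA <- LabelMap(array(1L, c(9, 9, 9)), 0:2)
  labB <- LabelMap(array(2L, c(9, 9, 9)), 0:2)
  cfg <- fusionConfig(nSelect = 2, window = 5, gain = 2)
  fused <- localWeightedVote(target, list(atlA, atlB), list(labA, labB), cfg)
  expect_true(all(labelData(fused) == 1L))
  # swapping the roles flips the outcome
  fused2 <- localWeightedVote(target, list(atlB, atlA), list(labB, labA), cfg)
  expect_true(all(labelData(fused2) == 1L))
  # gain 0 reduces LWV to majority voting
  atl3 <- list(atlA, atlB, atlB)
  lab3 <- list(labA, labB, labB)
  g0 <- localWeightedVote(target, atl3, lab3,
                          fusionConfig(nSelect = 3, window = 5, gain = 0))
  expect_identical(labelData(g0), labelData(majorityVote(lab3)))
  # single atlas passes through unchanged
  solo <- localWeightedVote(target, list(atlB), list(labB), cfg)
  expect_identical(labelData(solo), labelData(labB))
  expect_error(localWeightedVote(target, list(atlA), lab3, cfg),
               "aligned", class = "usageError")
})

test_that("fusion is idempotent on identical propagated maps", {
  lab <- makePhantom(phantomSpec(16, seed = 91))$labels
  target <- tinyVolume(16, seed = 92)
  maps <- list(lab, lab, lab)
  expect_identical(labelData(majorityVote(maps)), labelData(lab))
  vols <- lapply(1:3, function(i) tinyVolume(16, seed = 92 + i))
  lwv <- localWeightedVote(target, vols, maps, fusionConfig(window = 5))
  expect_identical(labelData(lwv), labelData(lab))
})

test_that("the pipeline composes selection and fusion with provenance", {
  atl <- makeTinyAtlases(4)
  prof <- tinyProfile()
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 15)
  target <- makePhantom(phantomSpec(16, age = 0.45, seed = 93))$volume
  # with every atlas kept and MV fusion, the pipeline equals majorityVote
  segMV <- segmentTarget(target, atl, model,
                         fusionConfig(nSelect = 4, fusion = "MV"))
  reg <- registerAtlases(target, atl, model)
  mv <- majorityVote(lapply(reg, `[[`, "labels"))
  expect_identical(labelData(segMV$labels), labelData(mv))
  expect_setequal(segMV$provenance$selected, 1:4)
  # output classes never leave the atlas class set
  segLWV <- segmentTarget(target, atl, model,
                          fusionConfig(nSelect = 2, window = 5))
  expect_true(all(labelData(segLWV$labels) %in%
                    labelClasses(atlasLabels(atl)[[1]])))
  expect_length(segLWV$provenance$selected, 2)
  expect_equal(nrow(segLWV$provenance$ranking), 4)
  expect_error(segmentTarget(target, atl, model,
                             fusionConfig(nSelect = 9)),
               "exceeds", class = "usageError")
})

test_that("NCC selection prefers age-similar atlases on a cohort", {
  atl <- makeTinyAtlases(8, seed = 95)
  ages <- atlasMeta(atl)$age
  prof <- tinyProfile()
  model <- initCascadeModel(prof$cascade, prof$loss, seed = 16)
  gaps <- c()
  for (tAge in c(0.3, 0.5, 0.7)) {
    target <- makePhantom(phantomSpec(16, age = tAge, seed = 200 +
                                        round(100 * tAge)))$volume
    reg <- registerAtlases(target, atl, model)
    rk <- rankAtlases(target, reg, "NCC")
    sel <- rk$index[1:3]
    gaps <- c(gaps, median(abs(ages[sel] - tAge)))
  }
  randGap <- median(abs(ages - 0.5))  # expected gap of uniform selection
  expect_lt(median(gaps), randGap)
})
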