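test_that("zero clusters yield a pure-background scene with empty mask", {
  cfg <- syntheticSceneConfig(height = 32, width = 32,
    nTargetClusters = 0L, seed = 3)
  sc <- generateScene(cfg)
  expect_true(all(sc$mask == 0))
  expect_identical(dim(sc$image), c(32L, 32L, 3L))
})

test_that("realized prevalence stays within 20 percent of the request", {
  sc <- generateScene(syntheticSceneConfig(height = 512, width = 512,
    targetPrevalence = 0.035, seed = 7))
  prev <- sum(sc$mask) / (512 * 512)
  expect_gte(prev, 0.028)
  expect_lte(prev, 0.042)
})

test_that("identical configs generate bit-identical scenes", {
  cfg <- smallSceneConfig(seed = 19)
  a <- generateScene(cfg)
  b <- generateScene(cfg)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$mask, b$mask)
  c <- generateScene(smallSceneConfig(seed = 20))
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("the noise-free background has numerical rank <= backgroundRank", {
  for (r in 1:3) {
    cfg <- syntheticSceneConfig(height = 64, width = 80,
      backgroundRank = r, nTargetClusters = 0L, seed = r + 5)
    sc <- generateScene(cfg)
    for (ch in 1:3)
      expect_lte(numericalRank(sc$background[, , ch]), r)
  }
})

test_that("unreachable prevalence and bad configs are rejected", {
  # 30% prevalence with 2 tiny discs would need radius far above range
  expect_error(generateScene(syntheticSceneConfig(height = 64, width = 64,
    nTargetClusters = 2L, clusterRadius = c(1, 3),
    targetPrevalence = 0.3, seed = 1)), "radius|prevalence")
  expect_error(syntheticSceneConfig(targetPrevalence = 0.7), "Prevalence",
    ignore.case = TRUE)
  expect_error(syntheticSceneConfig(channels = 2), "channels")
})

test_that("targets are bright light-green additive shifts inside the mask", {
  sc <- generateScene(smallSceneConfig(seed = 4))
  px <- pixels(sc$image)
  m <- sc$mask == 1
  # green channel contrast strongest, all channels non-negative shift
  contrast <- vapply(1:3, function(ch) mean(px[, , ch][m]) -
    mean(px[, , ch][!m]), numeric(1))
  expect_true(all(contrast > 0))
  expect_identical(which.max(contrast), 2L)
})

test_that("rpca on a generated scene recovers most planted target pixels", {
  sc <- generateScene(smallSceneConfig(seed = 27))
  # adequate l0 budget: half again as many slots as planted target pixels
  budget <- ceiling(1.5 * sum(sc$mask))
  e <- sparseEnhance(sc$image, rpcaConfig("godec",
    cardinalityBound = budget))
  support <- Reduce("|", lapply(e@perChannelResults,
    function(r) sparsePart(r) != 0))
  expect_gte(mean(support[sc$mask == 1]), 0.8)
})

test_that("paired areas differ, keep roles, and distractors stay unmasked", {
  pair <- generatePairedAreas(smallSceneConfig(seed = 1),
    smallSceneConfig(seed = 2, distractor = TRUE))
  expect_false(identical(pixels(pair$train$image),
    pixels(pair$test$image)))
  expect_identical(pair$roles$role, c("train", "test"))
  # distractor texture occupies the lower-right corner but never the mask
  h <- 96L; w <- 96L
  corner <- pair$test$mask[(h - h %/% 5 + 1):h, (w - w %/% 5 + 1):w]
  expect_true(all(corner == 0))
  cornerPx <- pixels(pair$test$image)[(h - h %/% 5 + 1):h,
    (w - w %/% 5 + 1):w, 1]
  plain <- generateScene(smallSceneConfig(seed = 2))
  expect_gt(mean(cornerPx),
    mean(pixels(plain$image)[(h - h %/% 5 + 1):h, (w - w %/% 5 + 1):w,
      1]))
  # identical seeds are disambiguated rather than silently duplicated
  pair2 <- generatePairedAreas(smallSceneConfig(seed = 5),
    smallSceneConfig(seed = 5))
  expect_false(identical(pixels(pair2$train$image),
    pixels(pair2$test$image)))
})
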