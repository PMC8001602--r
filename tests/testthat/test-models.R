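modelNames <- c("segnet", "unet", "3l_sn", "3l_usn", "2l_usn",
  "2l_conv_usn")

test_that("architecture audit: layer counts, pooling depths, skip links", {
  d <- lapply(modelNames, function(m)
    describeArchitecture(architecture(buildModel(m, 3, 1))))
  names(d) <- modelNames
  # SegNet baseline: 26 convolutions, 5 max-pooling, 5 upsampling, no skips
  expect_identical(d$segnet[c("conv", "mp", "up", "skip")],
    list(conv = 26L, mp = 5L, up = 5L, skip = 0L))
  expect_identical(d$unet$mp, 4L)
  expect_identical(d$unet$skip, 4L)
  # pooling depth 3 for the 3L models, 2 for the 2L models
  expect_identical(d[["3l_sn"]]$poolingDepth, 3L)
  expect_identical(d[["3l_usn"]]$poolingDepth, 3L)
  expect_identical(d[["2l_usn"]]$poolingDepth, 2L)
  expect_identical(d[["2l_conv_usn"]]$poolingDepth, 2L)
  expect_identical(d[["3l_sn"]]$mp, 3L)
  expect_identical(d[["3l_sn"]]$up, 3L)
  # skip links present exactly for unet and the USN variants
  expect_identical(d[["3l_sn"]]$skip, 0L)
  expect_identical(d[["3l_usn"]]$skip, 3L)
  expect_identical(d[["2l_usn"]]$skip, 2L)
  expect_identical(d[["2l_conv_usn"]]$skip, 2L)
  # every convolution is paired with a batch normalization
  for (m in modelNames) expect_identical(d[[m]]$bn, d[[m]]$conv)
})

test_that("2l_conv_usn is 2l_usn plus one extra conv+BN at the bottleneck", {
  a <- describeArchitecture(architecture(buildModel("2l_usn", 3, 1)))
  b <- describeArchitecture(architecture(buildModel("2l_conv_usn", 3, 1)))
  expect_identical(b$conv, a$conv + 1L)
  expect_identical(b$bn, a$bn + 1L)
  expect_identical(b[c("mp", "up", "skip", "poolingDepth")],
    a[c("mp", "up", "skip", "poolingDepth")])
})

test_that("capacity ordering: the shallow hybrid is much smaller than SegNet", {
  expect_gt(nParameters(buildModel("segnet", 3, 1)),
    nParameters(buildModel("3l_sn", 3, 1)))
})

test_that("unknown model names and bad patches are rejected", {
  expect_error(buildModel("segnet9000"), "unknown model")
  net <- buildModel("3l_usn", 3, 1)
  expect_error(predictPatch(net, array(0, c(30, 32, 3))), "divisible")
  expect_error(predictPatch(net, array(0, c(32, 32, 1))), "channel")
  expect_error(predictPatch(net, array(2, c(32, 32, 3))), "0, 1")
})

test_that("shape contract holds for all six models at two input sizes", {
  set.seed(2)
  for (m in modelNames) {
    net <- buildModel(m, 3, 1)
    for (side in c(64L, 128L)) {
      x <- array(runif(side * side * 3), c(side, side, 3))
      p <- predictPatch(net, x)
      expect_identical(dim(p), c(side, side))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("all-zero input yields finite scores strictly inside (0,1)", {
  for (m in c("3l_sn", "2l_conv_usn")) {
    p <- predictPatch(buildModel(m, 1, 5), array(0, c(32, 32, 1)))
    expect_true(all(is.finite(p)))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("networks round-trip through RDS and specs export as JSON", {
  net <- buildModel("2l_usn", 1, 4)
  path <- withr::local_tempfile(fileext = ".rds")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(predictPatch(back, x), predictPatch(net, x))
  js <- jsonlite::fromJSON(architectureJson(net))
  expect_identical(js$name, "2l_usn")
  expect_identical(js$poolingDepth, 2L)
  expect_identical(nrow(js$skipPairs), 2L)
})

test_that("seeded construction is deterministic end to end", {
  a <- buildModel("2l_usn", 3, 42)
  b <- buildModel("2l_usn", 3, 42)
  expect_identical(a@params, b@params)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predictPatch(a, x), predictPatch(b, x))
  c <- buildModel("2l_usn", 3, 43)
  expect_false(identical(a@params, c@params))
  # describe(build(x)) deterministic
  expect_identical(describeArchitecture(architecture(a)),
    describeArchitecture(architecture(b)))
})
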