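test_that("the study geometry yields 289 training and 25 test patches", {
  # 1300-wide x 1000-tall scene, 260 x 200 (w x h) window
  expect_identical(patchCount(tileSpec(260, 200, 65, 50), 1000, 1300), 289L)
  expect_identical(patchCount(tileSpec(260, 200, 260, 200), 1000, 1300),
    25L)
})

test_that("patch extraction matches the count formula and is row-major", {
  set.seed(2)
  px <- array(runif(40 * 52 * 3), c(40, 52, 3))
  mask <- matrix(rbinom(40 * 52, 1, 0.1), 40, 52)
  spec <- tileSpec(13, 10, 13, 10)
  ps <- extractPatches(px, mask, spec)
  expect_identical(nPatches(ps), patchCount(spec, 40, 52))
  org <- patchOrigins(ps)
  expect_identical(order(org$row, org$col), seq_len(nrow(org)))
  # windows are faithful crops
  i <- 7L
  r <- org$row[i]; c <- org$col[i]
  expect_identical(imageWindow(ps, i),
    px[(r + 1):(r + 10), (c + 1):(c + 13), , drop = FALSE])
  expect_identical(maskWindow(ps, i),
    mask[(r + 1):(r + 10), (c + 1):(c + 13)])
})

test_that("a window covering the whole image yields exactly one patch", {
  px <- array(runif(16 * 20), c(16, 20, 1))
  ps <- extractPatches(px, NULL, tileSpec(20, 16, 3, 5))
  expect_identical(nPatches(ps), 1L)
  expect_identical(patchOrigins(ps)$row, 0L)
  expect_identical(patchOrigins(ps)$col, 0L)
})

test_that("a quarter-scale study scene yields 25 training patches", {
  # derived by brute-force origin enumeration
  expect_identical(bruteForcePatchCount(400, 520, 200, 260, 50, 65), 25)
  expect_identical(patchCount(tileSpec(260, 200, 65, 50), 400, 520), 25L)
})

test_that("count formula matches brute-force enumeration on random specs", {
  set.seed(99)
  for (i in 1:50) {
    H <- sample(20:200, 1); W <- sample(20:200, 1)
    wh <- sample(5:H, 1); ww <- sample(5:W, 1)
    sy <- sample(1:30, 1); sx <- sample(1:30, 1)
    expect_identical(patchCount(tileSpec(ww, wh, sx, sy), H, W),
      as.integer(bruteForcePatchCount(H, W, wh, ww, sy, sx)))
  }
})

test_that("oversized windows and overlapping stitch specs are rejected", {
  px <- array(0.5, c(10, 10, 1))
  expect_error(extractPatches(px, NULL, tileSpec(11, 4)), "exceed")
  expect_error(extractPatches(px, matrix(0, 3, 3), tileSpec(4, 4)),
    "mask shape")
  expect_error(extractPatches(px, matrix(2, 10, 10), tileSpec(4, 4)),
    "binary")
  expect_error(
    stitchPredictions(list(), data.frame(row = integer(0),
      col = integer(0)), c(10, 10), tileSpec(4, 4, 3, 4)),
    "non-overlapping")
})

test_that("stitching non-overlapping mask windows round-trips exactly", {
  set.seed(5)
  mask <- matrix(rbinom(60 * 80, 1, 0.2), 60, 80)
  px <- array(runif(60 * 80), c(60, 80, 1))
  spec <- tileSpec(16, 12, 16, 12)
  ps <- extractPatches(px, mask, spec)
  stitched <- stitchPredictions(lapply(seq_len(nPatches(ps)), function(i)
    maskWindow(ps, i) * 1.0), ps, c(60, 80), spec)
  covered <- !is.na(stitched)
  expect_equal(stitched[covered], mask[covered])
  # coverage: 5 x 5 full windows of 16 x 12 tile 60 x 80 completely
  expect_identical(sum(covered), 25L * 16L * 12L)
})

test_that("the non-overlapping study spec covers the full scene", {
  # 25 windows of 260 x 200 tile 1300 x 1000 with zero uncovered pixels
  spec <- tileSpec(260, 200, 260, 200)
  org <- patchOrigins(extractPatches(array(0, c(1000, 1300, 1)), NULL,
    spec))
  expect_identical(nrow(org), 25L)
  expect_identical(25L * 260L * 200L, 1000L * 1300L)
})
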