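test_that("godec recovers an exact rank-1 matrix with zero cardinality", {
  set.seed(3)
  P <- outer(runif(8, 0.5, 1.5), runif(6, 0.5, 1.5))
  res <- godecDecompose(P, rpcaConfig("godec", rankBound = 1,
    cardinalityBound = 0))
  expect_equal(lowRank(res), P, tolerance = 1e-10)
  expect_true(all(sparsePart(res) == 0))
  expect_lt(res@relativeResidual, 1e-10)
})

test_that("godec isolates a dominant spike on a rank-1 background", {
  P <- outer(seq_len(10), seq_len(10)) / 10
  P[2, 3] <- P[2, 3] + 100
  res <- godecDecompose(P, rpcaConfig("godec", rankBound = 1,
    cardinalityBound = 1))
  nz <- which(sparsePart(res) != 0, arr.ind = TRUE)
  expect_identical(nrow(nz), 1L)
  expect_equal(as.vector(nz), c(2L, 3L))
  # the selected entry is the largest-magnitude residual of P - L
  resid <- abs(P - lowRank(res))
  expect_equal(which.max(resid), which(sparsePart(res) != 0))
})

test_that("zero input decomposes to zeros with residual 0 by convention", {
  Z <- matrix(0, 5, 5)
  for (k in c("godec", "pcp")) {
    res <- rpcaDecompose(Z, rpcaConfig(k, rankBound = 2,
      cardinalityBound = 3))
    expect_true(all(lowRank(res) == 0))
    expect_true(all(sparsePart(res) == 0))
    expect_identical(res@relativeResidual, 0)
  }
})

test_that("godec honors the cardinality budget and monotone residuals", {
  set.seed(11)
  for (trial in 1:6) {
    n <- sample(10:30, 1); m <- sample(10:30, 1)
    r <- sample(1:3, 1); k <- sample(0:20, 1)
    P <- matrix(rnorm(n * m), n, m)
    res <- godecDecompose(P, rpcaConfig("godec", rankBound = r,
      cardinalityBound = k, maxIter = 40))
    expect_lte(sum(sparsePart(res) != 0), k)
    expect_lte(numericalRank(lowRank(res)), r)
    expect_true(all(diff(res@residualTrace) <= 1e-10))
  }
})

test_that("godec rejects invalid input", {
  P <- matrix(1, 4, 4)
  bad <- P; bad[2, 2] <- NA
  expect_error(godecDecompose(bad, rpcaConfig("godec")), "finite")
  expect_error(
    godecDecompose(P, rpcaConfig("godec", rankBound = 9)), "rankBound")
  expect_error(godecDecompose(P, rpcaConfig("godec", rankBound = 2,
    cardinalityBound = 99)), "cardinality")
  expect_error(rpcaConfig("godec", tol = -1), "tol")
})

test_that("pcp reconstructs to tolerance and finds planted spikes", {
  fix <- plantedSpikeMatrix(50, 50, nSpikes = 2, magnitude = 50, seed = 5)
  res <- pcpDecompose(fix$P, rpcaConfig("pcp", tol = 1e-6))
  expect_true(res@converged)
  expect_lte(res@relativeResidual, 1e-6)
  S <- sparsePart(res)
  for (i in 1:2) expect_gt(S[fix$spikes[i, 1], fix$spikes[i, 2]], 1)
  # soft-thresholding leaves most entries exactly zero
  expect_gt(mean(S == 0), 0.5)
  # additivity contract
  expect_lte(norm(fix$P - lowRank(res) - S, "F") / norm(fix$P, "F"), 1e-6)
})

test_that("pcp reports non-convergence instead of raising", {
  fix <- plantedSpikeMatrix(20, 20, seed = 2)
  res <- pcpDecompose(fix$P, rpcaConfig("pcp", maxIter = 2, tol = 1e-12))
  expect_false(res@converged)
  expect_s4_class(res, "RpcaResult")
})

test_that("both kernels recover planted spike support (seeded property)", {
  for (seed in 1:5) {
    nSpk <- 3
    fix <- plantedSpikeMatrix(30, 25, nSpikes = nSpk, magnitude = 30,
      seed = seed)
    planted <- fix$spikes[, 1] + (fix$spikes[, 2] - 1) * 30
    g <- godecDecompose(fix$P, rpcaConfig("godec", rankBound = 1,
      cardinalityBound = nSpk))
    expect_setequal(which(sparsePart(g) != 0), planted)
    p <- pcpDecompose(fix$P, rpcaConfig("pcp"))
    expect_true(all(abs(sparsePart(p))[planted] > 1))
  }
})

test_that("godec default cardinality follows the 4 percent prevalence rule", {
  set.seed(1)
  P <- matrix(rnorm(400), 20, 20)
  res <- godecDecompose(P, rpcaConfig("godec", rankBound = 2))
  expect_lte(sum(sparsePart(res) != 0), ceiling(0.04 * 400))
})
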