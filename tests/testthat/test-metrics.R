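test_that("confusion counts enumerate the four cells", {
  em <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(c(em@pa, em@pb, em@pc, em@pd), c(1, 1, 1, 1))
  # agreement: no off-diagonal; disagreement: no diagonal
  set.seed(6)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  emA <- confusionCounts(t, t)
  expect_identical(emA@pb + emA@pc, 0)
  emD <- confusionCounts(1 - t, t)
  expect_identical(emD@pa + emD@pd, 0)
  expect_identical(nglseg:::emTotal(emA), 36)
  expect_error(confusionCounts(t, t[1:3, ]), "shape")
  expect_error(confusionCounts(t * 2, t), "binary")
})

test_that("accuracy is the diagonal fraction", {
  expect_equal(accuracy(errorMatrix(40, 10, 20, 30)), 0.7)
  t <- matrix(rbinom(25, 1, 0.5), 5, 5)
  expect_equal(accuracy(confusionCounts(t, t)), 1)
  expect_equal(accuracy(confusionCounts(1 - t, t)), 0)
  expect_error(accuracy(errorMatrix(0, 0, 0, 0)), "empty")
})

test_that("kappa is 1 for perfect, 0 for constant predictions, 0.4 on the worked matrix", {
  set.seed(31)
  t <- matrix(0, 10, 10); t[sample(100, 7)] <- 1
  expect_equal(cohensKappa(confusionCounts(t, t)), 1)
  expect_equal(cohensKappa(confusionCounts(matrix(1, 10, 10), t)), 0)
  expect_equal(cohensKappa(confusionCounts(matrix(0, 10, 10), t)), 0)
  # Po = 0.7, Pe = 0.5 -> K = 0.4
  expect_equal(cohensKappa(errorMatrix(40, 10, 20, 30)), 0.4)
})

test_that("kappa is symmetric in Pb and Pc and bounded in [-1, 1]", {
  set.seed(13)
  for (i in 1:1000) {
    v <- rmultinom(1, sample(4:200, 1), runif(4))[, 1]
    em <- errorMatrix(v[1], v[2], v[3], v[4])
    emSwap <- errorMatrix(v[1], v[3], v[2], v[4])
    k <- suppressWarnings(cohensKappa(em))
    if (is.na(k)) next
    expect_equal(suppressWarnings(cohensKappa(emSwap)), k)
    expect_gte(k, -1); expect_lte(k, 1)
    if (k == 1) expect_identical(v[2] + v[3], 0L)
    if (v[2] + v[3] == 0 && (v[1] > 0 && v[4] > 0))
      expect_equal(k, 1)
  }
  # degenerate identical marginals: Pe = 1, kappa undefined
  expect_warning(k <- cohensKappa(errorMatrix(9, 0, 0, 0)), "undefined")
  expect_true(is.na(k))
})

test_that("roc auc equals the worked four-pixel example and handles rectangles", {
  roc <- rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(roc@auc, 0.75)
  # perfect ranking and perfect hard scores
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))@auc, 1)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(1, 1, 0, 0))@auc, 1)
  # hard {0,1} scores degenerate to the three-point rectangle curve
  hard <- rocAuc(c(1, 0, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 1))
  expect_length(hard@fpr, 3L)
  expect_equal(hard@fpr[1], 0); expect_equal(hard@fpr[3], 1)
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("roc auc equals brute-force pairwise concordance on random grids", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:100, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(truth) == 0 || sum(truth) == n) next
    expect_equal(rocAuc(scores, truth)@auc, bruteForceAuc(scores, truth))
  }
})

test_that("roc auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- runif(400)
  truth <- rbinom(400, 1, 0.3)
  ours <- rocAuc(scores, truth)@auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
    direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("kappa agrees with an established implementation", {
  skip_if_not_installed("e1071")
  set.seed(29)
  for (i in 1:20) {
    pred <- rbinom(150, 1, 0.4)
    truth <- rbinom(150, 1, 0.3)
    tab <- table(factor(pred, 0:1), factor(truth, 0:1))
    ref <- e1071::classAgreement(tab)$kappa
    em <- confusionCounts(pred, truth)
    expect_equal(cohensKappa(em), ref, tolerance = 1e-12)
  }
})

test_that("tri-color result maps color hits, misses and false alarms", {
  truth <- matrix(0, 3, 3); truth[1, 1] <- 1; truth[2, 2] <- 1
  pred <- matrix(0, 3, 3); pred[1, 1] <- 1; pred[3, 3] <- 1
  img <- renderResultMap(pred, truth)
  isColor <- function(r, c, col) all(img[r, c, ] == col)
  expect_true(isColor(1, 1, c(1, 0, 0)))  # hit: red
  expect_true(isColor(3, 3, c(0, 0, 1)))  # false alarm: blue
  expect_true(isColor(2, 2, c(1, 1, 0)))  # miss: yellow
  expect_true(isColor(1, 2, c(0, 0, 0)))  # TN: black without source
  # perfect prediction: no blue, no yellow
  imgP <- renderResultMap(truth, truth)
  expect_identical(sum(imgP[, , 3] == 1 & imgP[, , 1] == 0), 0L)
  # all-positive prediction: blue count = Pb, no yellow
  imgA <- renderResultMap(matrix(1, 3, 3), truth)
  em <- confusionCounts(matrix(1, 3, 3), truth)
  expect_equal(sum(imgA[, , 3] == 1 & imgA[, , 1] == 0), em@pb)
  expect_identical(sum(imgA[, , 1] == 1 & imgA[, , 2] == 1), 0L)
})

test_that("evaluateSegmentation assembles consistent report rows", {
  set.seed(41)
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  scores <- matrix(runif(100), 10, 10)
  rep <- evaluateSegmentation(scores, truth, threshold = 0.5)
  # acc identity: acc = tpr * prevalence + (1 - fpr) * (1 - prevalence)
  prev <- mean(truth)
  expect_equal(rep$acc, rep$tpr * prev + (1 - rep$fpr) * (1 - prev))
  # perfect scores
  perf <- evaluateSegmentation(truth * 0.98 + 0.01, truth)
  expect_equal(unlist(perf), c(auc = 1, tpr = 1, fpr = 0, acc = 1,
    kappa = 1))
  # all-background prediction: tpr = fpr = 0
  low <- evaluateSegmentation(matrix(0.1, 10, 10) + truth * 0.2, truth,
    threshold = 0.9)
  expect_equal(low$tpr, 0); expect_equal(low$fpr, 0)
  # NA pixels (uncovered by tiling) are excluded
  scNA <- scores; scNA[1, ] <- NA
  repNA <- evaluateSegmentation(scNA, truth)
  expect_false(any(is.na(unlist(repNA))))
})
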