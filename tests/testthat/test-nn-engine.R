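# White-box checks of the training engine: the analytic gradients of every
# layer type are compared against central finite differences through the
# full network (convolution, batch norm in training mode, ReLU, max-pool,
# nearest upsampling, skip concatenation, sigmoid head, and the weighted
# loss), using the smallest architecture that exercises them all.

test_that("backward pass matches finite differences through every layer type", {
  set.seed(42)
  net <- buildModel("2l_usn", 1, 7)
  ops <- net@graph
  params <- net@params
  h <- 8L; w <- 8L
  X <- matrix(runif(h * w), h * w, 1)
  p <- as.numeric(runif(h * w) < 0.3)
  beta <- 0.9

  lossAt <- function(pp) {
    fwd <- nglseg:::nnForward(ops, pp, X, h, w, train = TRUE)
    balancedCE(p, fwd$score, beta)
  }
  fwd <- nglseg:::nnForward(ops, params, X, h, w, train = TRUE,
    keepCache = TRUE)
  dZ <- nglseg:::lossGradLogit(p, fwd$score, "bce", beta)
  g <- nglseg:::nnBackward(ops, params, fwd, dZ)

  eps <- 1e-6
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in intersect(names(params[[i]]), c("W", "b", "gamma",
      "beta"))) {
      for (j in sample(length(params[[i]][[nm]]),
        min(2, length(params[[i]][[nm]])))) {
        pp <- params; pp[[i]][[nm]][j] <- pp[[i]][[nm]][j] + eps
        pm <- params; pm[[i]][[nm]][j] <- pm[[i]][[nm]][j] - eps
        num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
        ana <- g[[i]][[nglseg:::.gradName[[nm]]]][j]
        expect_equal(ana, num, tolerance = 1e-3,
          label = sprintf("grad op %d (%s) %s[%d]", i, ops[[i]]$type, nm,
            j))
      }
    }
  }
})

test_that("ce logit gradient reduces to (p_hat - p)/n", {
  phat <- c(0.2, 0.7, 0.5)
  p <- c(0, 1, 1)
  expect_equal(nglseg:::lossGradLogit(p, phat, "ce", NA),
    (phat - p) / 3)
})

test_that("im2col/col2im are exact adjoints", {
  set.seed(3)
  h <- 6L; w <- 5L; cin <- 2L
  X <- matrix(rnorm(h * w * cin), h * w, cin)
  Y <- matrix(rnorm(h * w * 9 * cin), h * w, 9 * cin)
  # <im2col(X), Y> == <X, col2im(Y)>
  lhs <- sum(nglseg:::im2col(X, h, w) * Y)
  rhs <- sum(X * nglseg:::col2im(Y, h, w, cin))
  expect_equal(lhs, rhs)
})

test_that("max-pool forward picks window maxima and routes gradients back", {
  m <- matrix(c(1, 2, 5, 3,
                4, 0, 1, 2,
                7, 1, 0, 0,
                1, 8, 0, 9), 4, 4, byrow = TRUE)
  X <- matrix(as.vector(m), 16, 1)
  fp <- nglseg:::nnForwardPool(X, 4L, 4L)
  expect_equal(sort(fp$Y[, 1]), sort(c(4, 5, 8, 9)))
  dX <- nglseg:::nnBackwardPool(matrix(1, 4, 1), fp$chosen, 4L, 4L, 1L)
  expect_equal(sum(dX), 4)            # one unit per pool window
  expect_equal(which(dX != 0), sort(fp$chosen[, 1]))
})

test_that("nearest upsampling replicates pixels and its backward sums them", {
  X <- matrix(c(1, 2, 3, 4), 4, 1)   # 2 x 2 coarse grid
  up <- X[nglseg:::upIdx(2L, 2L), , drop = FALSE]
  expect_equal(matrix(up, 4, 4), rbind(c(1, 1, 3, 3), c(1, 1, 3, 3),
    c(2, 2, 4, 4), c(2, 2, 4, 4)))
  back <- rowsum(up, nglseg:::upIdx(2L, 2L))
  expect_equal(as.vector(back), 4 * as.vector(X))
})
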