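## Minimal CNN engine for the segmentation networks.
##
## Feature maps are stored as (n_pixels x channels) matrices in column-major
## pixel order (pixel id p = (col-1)*h + row, matching as.vector() of an
## h x w matrix). Convolution is im2col + one BLAS matrix multiply; pooling,
## upsampling and batch normalization are index/column operations. Everything
## is deterministic given the seed, and every backward pass is checked
## against finite differences in the test suite.
##
## All functions here are internal; the public surface is buildModel(),
## predictPatch() and trainModel().

.nnIdxCache <- new.env(parent = emptyenv())

cacheKey <- function(...) paste(..., sep = "x")

## 3x3 same-padding neighbor index, offset-major: block k (k = 1..9 over
## (dr, dc), dr fastest) holds, for every output pixel, the input pixel id of
## that offset, or n_pixels + 1 for out-of-image (a zero pad row).
convIdx <- function(h, w) {
  key <- cacheKey("conv", h, w)
  if (!is.null(.nnIdxCache[[key]])) return(.nnIdxCache[[key]])
  npix <- h * w
  rows <- rep.int(seq_len(h), w)
  cols <- rep(seq_len(w), each = h)
  idx <- integer(9L * npix)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- rows + dr
    cc <- cols + dc
    id <- (cc - 1L) * h + rr
    id[rr < 1L | rr > h | cc < 1L | cc > w] <- npix + 1L
    idx[((k - 1L) * npix + 1L):(k * npix)] <- id
  }
  .nnIdxCache[[key]] <- idx
  idx
}

## 2x2 max-pool child indices: four vectors of input pixel ids, one per
## corner of each pool window, in output pixel order.
poolIdx <- function(h, w) {
  key <- cacheKey("pool", h, w)
  if (!is.null(.nnIdxCache[[key]])) return(.nnIdxCache[[key]])
  ho <- h %/% 2L; wo <- w %/% 2L
  ro <- rep.int(seq_len(ho), wo)
  co <- rep(seq_len(wo), each = ho)
  at <- function(dr, dc) (2L * co - 2L + dc - 1L) * h + (2L * ro - 2L + dr)
  out <- list(at(1L, 1L), at(2L, 1L), at(1L, 2L), at(2L, 2L))
  .nnIdxCache[[key]] <- out
  out
}

## 2x nearest-neighbor upsampling: for each fine pixel, the source coarse
## pixel id. Input is the coarse grid (h x w), output 2h x 2w.
upIdx <- function(h, w) {
  key <- cacheKey("up", h, w)
  if (!is.null(.nnIdxCache[[key]])) return(.nnIdxCache[[key]])
  hf <- 2L * h; wf <- 2L * w
  rf <- rep.int(seq_len(hf), wf)
  cf <- rep(seq_len(wf), each = hf)
  idx <- (((cf + 1L) %/% 2L) - 1L) * h + ((rf + 1L) %/% 2L)
  .nnIdxCache[[key]] <- idx
  idx
}

## column-wise scale (and optional shift): X[, j] * s[j] + a[j]
colScale <- function(X, s, a = NULL) {
  Y <- X * rep(s, each = nrow(X))
  if (!is.null(a)) Y <- Y + rep(a, each = nrow(X))
  Y
}

## im2col: (npix x cin) -> (npix x 9*cin), column m = (c-1)*9 + k
im2col <- function(X, h, w) {
  npix <- nrow(X)
  Xp <- rbind(X, 0)[convIdx(h, w), , drop = FALSE]
  dim(Xp) <- c(npix, 9L * ncol(X))
  Xp
}

## scatter-add of the im2col gradient back onto input pixels
col2im <- function(dXp, h, w, cin) {
  npix <- h * w
  dim(dXp) <- c(9L * npix, cin)
  dX <- rowsum(dXp, convIdx(h, w))  # groups sorted ascending: 1..npix(+pad)
  dX[seq_len(npix), , drop = FALSE]
}

nnForwardConv <- function(X, h, w, par, cache = FALSE) {
  Xp <- im2col(X, h, w)
  Y <- Xp %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  if (cache) list(Y = Y, Xp = Xp) else list(Y = Y)
}

nnBackwardConv <- function(dY, cacheXp, par, h, w) {
  list(dW = crossprod(cacheXp, dY),
       db = colSums(dY),
       dX = col2im(dY %*% t(par$W), h, w, nrow(par$W) %/% 9L))
}

.bnEps <- 1e-5
.bnMomentum <- 0.1

nnForwardBn <- function(X, par, train) {
  if (train) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = nrow(X))
    v <- colMeans(Xc * Xc)
    invstd <- 1 / sqrt(v + .bnEps)
    xhat <- colScale(Xc, invstd)
    list(Y = colScale(xhat, par$gamma, par$beta), xhat = xhat,
      invstd = invstd,
      rm = (1 - .bnMomentum) * par$rm + .bnMomentum * mu,
      rv = (1 - .bnMomentum) * par$rv + .bnMomentum * v)
  } else {
    invstd <- 1 / sqrt(par$rv + .bnEps)
    xhat <- colScale(X - rep(par$rm, each = nrow(X)), invstd)
    list(Y = colScale(xhat, par$gamma, par$beta))
  }
}

nnBackwardBn <- function(dY, cache, par) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- colScale(dY, par$gamma)
  ## dX = invstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  dX <- dxhat - rep(colMeans(dxhat), each = n) -
    cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  list(dgamma = dgamma, dbeta = dbeta, dX = colScale(dX, cache$invstd))
}

nnForwardPool <- function(X, h, w) {
  pid <- poolIdx(h, w)
  npo <- length(pid[[1]])
  C <- ncol(X)
  Y <- X[pid[[1]], , drop = FALSE]
  CH <- matrix(pid[[1]], npo, C)
  for (k in 2:4) {
    A <- X[pid[[k]], , drop = FALSE]
    m <- A > Y          # ties keep the earliest candidate (deterministic)
    Y[m] <- A[m]
    CH[m] <- matrix(pid[[k]], npo, C)[m]
  }
  list(Y = Y, chosen = CH)
}

nnBackwardPool <- function(dY, chosen, h, w, C) {
  npixIn <- h * w
  dX <- matrix(0, npixIn, C)
  lin <- chosen + rep((seq_len(C) - 1L) * npixIn, each = nrow(chosen))
  dX[lin] <- dY   # one winner per disjoint window: no collisions
  dX
}

sigmoidStable <- function(z) 1 / (1 + exp(-z))

## ---- graph compilation -----------------------------------------------

## ops: list of list(type = conv|bn|relu|mp|up|concat|out, ...). concat ops
## carry `from`, the index of the op whose output is appended column-wise.
## Channel bookkeeping happens at build time.

newGraphBuilder <- function(inputChannels) {
  env <- new.env(parent = emptyenv())
  env$ops <- list()
  env$channels <- inputChannels
  env$rows <- list()
  env
}

gbAdd <- function(gb, op, code = NULL, filters = NA_integer_, stage = NA) {
  gb$ops[[length(gb$ops) + 1L]] <- op
  if (!is.null(code))
    gb$rows[[length(gb$rows) + 1L]] <-
      data.frame(code = code, filters = filters, stage = stage)
  length(gb$ops)
}

## one C + BN unit: 3x3 same conv -> batch norm -> ReLU
gbConvBnRelu <- function(gb, cout, stage) {
  gbAdd(gb, list(type = "conv", cin = gb$channels, cout = cout),
    code = "C", filters = cout, stage = stage)
  gbAdd(gb, list(type = "bn", c = cout), code = "BN", stage = stage)
  gbAdd(gb, list(type = "relu"))
  gb$channels <- cout
  invisible(NULL)
}

gbPool <- function(gb, stage = "encoder") {
  gbAdd(gb, list(type = "mp"), code = "MP", stage = stage)
}

gbUp <- function(gb, stage = "decoder") {
  gbAdd(gb, list(type = "up"), code = "UP", stage = stage)
}

gbConcat <- function(gb, from, fromChannels, stage = "decoder") {
  gbAdd(gb, list(type = "concat", from = from), code = "SC", stage = stage)
  gb$channels <- gb$channels + fromChannels
  invisible(NULL)
}

gbOut <- function(gb) {
  gbAdd(gb, list(type = "out", cin = gb$channels), code = "Out",
    filters = 1L, stage = "head")
  gb$channels <- 1L
  invisible(NULL)
}

## ---- parameter initialization and forward/backward --------------------

initParams <- function(ops, seed) {
  set.seed(seed)
  lapply(ops, function(op) {
    switch(op$type,
      conv = list(
        W = matrix(stats::rnorm(9L * op$cin * op$cout,
          sd = sqrt(2 / (9 * op$cin))), 9L * op$cin, op$cout),
        b = numeric(op$cout)),
      bn = list(gamma = rep(1, op$c), beta = numeric(op$c),
        rm = numeric(op$c), rv = rep(1, op$c)),
      out = list(
        W = matrix(stats::rnorm(op$cin, sd = sqrt(1 / op$cin)), op$cin, 1L),
        b = 0),
      NULL)
  })
}

countParams <- function(params) {
  sum(vapply(params, function(p) {
    if (is.null(p)) return(0)
    ## running BN statistics are state, not trainable parameters
    sum(lengths(p[names(p) %in% c("W", "b", "gamma", "beta")]))
  }, numeric(1)))
}

## Forward pass over the compiled graph. Returns the sigmoid score vector
## and, when keepCache, everything backward needs. In train mode, batch-norm
## batch statistics are used and updated running statistics are returned.
nnForward <- function(ops, params, X, h, w, train = FALSE,
                      keepCache = FALSE) {
  nOps <- length(ops)
  outs <- vector("list", nOps)
  caches <- vector("list", nOps)
  dims <- vector("list", nOps)
  bnNew <- vector("list", nOps)
  cur <- X
  for (i in seq_len(nOps)) {
    op <- ops[[i]]
    cur <- switch(op$type,
      conv = {
        fc <- nnForwardConv(cur, h, w, params[[i]], cache = keepCache)
        if (keepCache) caches[[i]] <- fc$Xp
        fc$Y
      },
      bn = {
        fb <- nnForwardBn(cur, params[[i]], train)
        if (train) bnNew[[i]] <- list(rm = fb$rm, rv = fb$rv)
        if (keepCache)
          caches[[i]] <- list(xhat = fb$xhat, invstd = fb$invstd)
        fb$Y
      },
      relu = {
        if (keepCache) caches[[i]] <- cur > 0
        pmax(cur, 0)
      },
      mp = {
        fp <- nnForwardPool(cur, h, w)
        if (keepCache) caches[[i]] <- fp$chosen
        h <- h %/% 2L; w <- w %/% 2L
        fp$Y
      },
      up = {
        Y <- cur[upIdx(h, w), , drop = FALSE]
        h <- 2L * h; w <- 2L * w
        Y
      },
      concat = cbind(cur, outs[[op$from]]),
      out = {
        z <- drop(cur %*% params[[i]]$W) + params[[i]]$b
        if (keepCache) caches[[i]] <- cur
        sigmoidStable(z)
      })
    dims[[i]] <- c(h, w)
    if (keepCache || op$type %in% c("relu", "conv", "bn"))
      outs[[i]] <- cur
  }
  list(score = cur, outs = outs, caches = caches, dims = dims,
    bnNew = bnNew)
}

## Backward pass from dZ, the loss gradient w.r.t. the pre-sigmoid logit.
## Returns gradients parallel to params.
nnBackward <- function(ops, params, fwd, dZ) {
  nOps <- length(ops)
  grads <- vector("list", nOps)
  extra <- vector("list", nOps)   # skip-connection gradient arriving later
  dCur <- NULL
  for (i in rev(seq_len(nOps))) {
    op <- ops[[i]]
    if (!is.null(extra[[i]])) {
      dCur <- if (is.null(dCur)) extra[[i]] else dCur + extra[[i]]
    }
    dimIn <- if (i > 1L) fwd$dims[[i - 1L]] else fwd$dims[[1L]]
    dCur <- switch(op$type,
      out = {
        ## dZ is already the loss gradient w.r.t. the pre-sigmoid logit
        Xin <- fwd$caches[[i]]
        grads[[i]] <- list(dW = crossprod(Xin, matrix(dZ)), db = sum(dZ))
        matrix(dZ) %*% t(params[[i]]$W)
      },
      conv = {
        g <- nnBackwardConv(dCur, fwd$caches[[i]], params[[i]],
          dimIn[1], dimIn[2])
        grads[[i]] <- g[c("dW", "db")]
        g$dX
      },
      bn = {
        g <- nnBackwardBn(dCur, fwd$caches[[i]], params[[i]])
        grads[[i]] <- g[c("dgamma", "dbeta")]
        g$dX
      },
      relu = dCur * fwd$caches[[i]],
      mp = nnBackwardPool(dCur, fwd$caches[[i]], dimIn[1], dimIn[2],
        ncol(dCur)),
      up = rowsum(dCur, upIdx(dimIn[1], dimIn[2])),
      concat = {
        cMain <- ncol(fwd$outs[[i]]) - ncol(fwd$outs[[op$from]])
        skipG <- dCur[, (cMain + 1L):ncol(dCur), drop = FALSE]
        extra[[op$from]] <- if (is.null(extra[[op$from]])) skipG else
          extra[[op$from]] + skipG
        dCur[, seq_len(cMain), drop = FALSE]
      })
  }
  grads
}

## Per-pixel gradient of the selected loss w.r.t. the pre-sigmoid logit,
## with mean-over-pixels reduction. For ce this is (phat - p)/n.
lossGradLogit <- function(p, phat, kind, beta) {
  wpos <- switch(kind, ce = 1, wce = beta, bce = beta)
  wneg <- switch(kind, ce = 1, wce = 1, bce = 1 - beta)
  (wneg * (1 - p) * phat - wpos * p * (1 - phat)) / length(p)
}

## ---- Adam -------------------------------------------------------------

adamInit <- function(params) {
  zero <- function(x) if (is.null(x)) NULL else lapply(x, function(v) v * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

## grads use names dW/db/dgamma/dbeta; params use W/b/gamma/beta
.gradName <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in intersect(names(params[[i]]), names(.gradName))) {
      g <- grads[[i]][[.gradName[[nm]]]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
        (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

accumulateGrads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]]
  }
  acc
}

scaleGrads <- function(g, f) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) g[[i]][[nm]] <- g[[i]][[nm]] * f
  }
  g
}
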