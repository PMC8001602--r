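## Error-matrix metrics, ROC/AUC and tri-color result maps.

#' Construct an error matrix from counts
#'
#' @param pa,pb,pc,pd non-negative whole-number counts: TP, FP, FN, TN in
#'   the row = detection, column = truth convention.
#' @return An \linkS4class{ErrorMatrix}.
#' @examples
#' em <- errorMatrix(40, 10, 20, 30)
#' accuracy(em); cohensKappa(em)
#' @export
errorMatrix <- function(pa, pb, pc, pd) {
  new("ErrorMatrix", pa = as.numeric(pa), pb = as.numeric(pb),
    pc = as.numeric(pc), pd = as.numeric(pd))
}

setMethod("show", "ErrorMatrix", function(object) {
  m <- matrix(c(object@pa, object@pc, object@pb, object@pd), 2, 2,
    dimnames = list(detection = c("NGL", "non-NGL"),
      truth = c("NGL", "non-NGL")))
  cat("ErrorMatrix (Pa = TP, Pb = FP, Pc = FN, Pd = TN):\n")
  print(m)
})

#' Confusion counts of a binary prediction
#'
#' Tallies the four cells of the error matrix over all pixels of a predicted
#' mask against its ground truth.
#'
#' @param predMask,truthMask binary (0/1) grids of identical shape.
#' @return An \linkS4class{ErrorMatrix} with \code{pa+pb+pc+pd} equal to the
#'   pixel count.
#' @export
confusionCounts <- function(predMask, truthMask) {
  if (!identical(dim(predMask), dim(truthMask)) ||
      length(predMask) != length(truthMask))
    stop("prediction and truth must have identical shapes")
  if (!all(predMask %in% c(0, 1)) || !all(truthMask %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  p <- as.vector(predMask); t <- as.vector(truthMask)
  errorMatrix(sum(p == 1 & t == 1), sum(p == 1 & t == 0),
    sum(p == 0 & t == 1), sum(p == 0 & t == 0))
}

emTotal <- function(em) em@pa + em@pb + em@pc + em@pd

#' @rdname accuracy
#' @export
setMethod("accuracy", "ErrorMatrix", function(object) {
  n <- emTotal(object)
  if (n == 0) stop("error matrix is empty (N = 0)")
  (object@pa + object@pd) / n
})

#' @rdname cohensKappa
#' @export
setMethod("cohensKappa", "ErrorMatrix", function(object) {
  n <- emTotal(object)
  if (n == 0) stop("error matrix is empty (N = 0)")
  po <- (object@pa + object@pd) / n
  pe <- (object@pa + object@pb) / n * (object@pa + object@pc) / n +
    (object@pc + object@pd) / n * (object@pb + object@pd) / n
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("kappa undefined: chance agreement Pe = 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
})

#' ROC curve and AUC of a score grid
#'
#' Sweeps the decision threshold over all distinct score values, collecting
#' (FPR, TPR) pairs anchored at (0,0) and (1,1), and integrates the area
#' under the curve with the trapezoidal rule (equivalently: pairwise
#' concordance probability with ties counted 1/2). A hard {0,1} score grid
#' degenerates to the three-point rectangle curve.
#'
#' @param scores numeric grid of detection scores (higher = more NGL-like).
#' @param truthMask binary grid of the same shape; both classes must be
#'   present.
#' @return A \linkS4class{RocCurve}.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))@auc  # 0.75
#' @export
rocAuc <- function(scores, truthMask) {
  if (!identical(dim(scores), dim(truthMask)) ||
      length(scores) != length(truthMask))
    stop("scores and truth must have identical shapes")
  t <- as.vector(truthMask)
  if (!all(t %in% c(0, 1))) stop("truth mask must be binary (0/1)")
  s <- as.vector(scores)
  nPos <- sum(t == 1); nNeg <- sum(t == 0)
  if (nPos == 0 || nNeg == 0)
    stop("truth mask must contain both classes")
  ## descending threshold sweep over distinct score values
  ord <- order(s, decreasing = TRUE)
  sSorted <- s[ord]; tSorted <- t[ord]
  cumTp <- cumsum(tSorted == 1)
  cumFp <- cumsum(tSorted == 0)
  last <- c(sSorted[-1] != sSorted[-length(sSorted)], TRUE)
  tpr <- c(0, cumTp[last] / nPos)
  fpr <- c(0, cumFp[last] / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  new("RocCurve", fpr = fpr, tpr = tpr, auc = auc)
}

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d point(s), AUC = %.4f\n", length(object@fpr),
    object@auc))
})

#' Tri-color detection result map
#'
#' Renders a prediction/truth pair as an RGB image: hits red, false alarms
#' blue, misses yellow; true-negative pixels show the grayscale of the
#' source scene (black if no source is given).
#'
#' @param predMask,truthMask binary grids of identical shape.
#' @param source optional \linkS4class{SceneImage} or grid supplying the
#'   background intensity for true negatives.
#' @return \code{h x w x 3} numeric array in [0, 1].
#' @export
renderResultMap <- function(predMask, truthMask, source = NULL) {
  if (!identical(dim(predMask), dim(truthMask)))
    stop("prediction and truth must have identical shapes")
  h <- nrow(predMask); w <- ncol(predMask)
  gray <- matrix(0, h, w)
  if (!is.null(source)) {
    px <- if (is(source, "SceneImage")) {
      sp <- source@pixels
      if (source@valueRange == "uint8") sp <- sp / 255
      sp
    } else if (is.matrix(source)) array(source, c(dim(source), 1L))
    else source
    gray <- apply(px, c(1, 2), mean)
  }
  r <- gray; g <- gray; b <- gray
  hit <- predMask == 1 & truthMask == 1
  fa <- predMask == 1 & truthMask == 0
  miss <- predMask == 0 & truthMask == 1
  r[hit] <- 1; g[hit] <- 0; b[hit] <- 0
  r[fa] <- 0; g[fa] <- 0; b[fa] <- 1
  r[miss] <- 1; g[miss] <- 1; b[miss] <- 0
  out <- array(0, c(h, w, 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Full evaluation of a score grid against ground truth
#'
#' Thresholds the scores (default 0.5 on the sigmoid scale), builds the
#' error matrix and assembles the five headline metrics: AUC from the raw
#' scores, TPR = Pa/(Pa+Pc) and FPR = Pb/(Pb+Pd) at the threshold, overall
#' accuracy and Cohen's kappa. Pixels where \code{scores} is \code{NA}
#' (e.g. uncovered by any tile) are excluded.
#'
#' @param scores numeric score grid.
#' @param truthMask binary grid of the same shape, both classes present
#'   among the evaluated pixels.
#' @param threshold hard-decision threshold on the scores.
#' @return One-row data.frame with columns \code{auc}, \code{tpr},
#'   \code{fpr}, \code{acc}, \code{kappa}.
#' @export
evaluateSegmentation <- function(scores, truthMask, threshold = 0.5) {
  if (!identical(dim(scores), dim(truthMask)) ||
      length(scores) != length(truthMask))
    stop("scores and truth must have identical shapes")
  keep <- !is.na(as.vector(scores))
  s <- as.vector(scores)[keep]
  t <- as.vector(truthMask)[keep]
  roc <- rocAuc(s, t)
  pred <- (s >= threshold) * 1
  em <- confusionCounts(pred, t)
  tpr <- if (em@pa + em@pc > 0) em@pa / (em@pa + em@pc) else NA_real_
  fpr <- if (em@pb + em@pd > 0) em@pb / (em@pb + em@pd) else NA_real_
  data.frame(auc = roc@auc, tpr = tpr, fpr = fpr, acc = accuracy(em),
    kappa = cohensKappa(em))
}
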