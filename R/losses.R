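## Binary cross-entropy losses with class-imbalance weights.
##
## Natural logarithms throughout; predictions are clamped to
## [eps, 1 - eps], eps = 1e-7, before taking logs; the reduction is the mean
## over all pixels.

.lossEps <- 1e-7

#' Select a training loss
#'
#' @param kind \code{"ce"} (plain binary cross-entropy), \code{"wce"}
#'   (positive class up-weighted by beta in (1,2)) or \code{"bce"} (positive
#'   weight beta, negative weight 1 - beta, beta in (0,1)).
#' @param beta the imbalance weight; ignored for \code{"ce"}. Default 0.99
#'   for \code{"bce"}, giving a positive/negative weight ratio of
#'   \code{beta/(1-beta) = 99} that counteracts the ~3\% NGL prevalence.
#' @return A \linkS4class{LossConfig}.
#' @export
lossConfig <- function(kind = c("bce", "wce", "ce"), beta = NULL) {
  kind <- match.arg(kind)
  if (is.null(beta))
    beta <- switch(kind, bce = 0.99, wce = 1.5, ce = NA_real_)
  new("LossConfig", kind = kind, beta = as.numeric(beta))
}

setMethod("show", "LossConfig", function(object) {
  if (object@kind == "ce") cat("LossConfig: ce\n")
  else cat(sprintf("LossConfig: %s, beta = %g\n", object@kind, object@beta))
})

checkLossInputs <- function(p, pHat) {
  if (!identical(dim(p), dim(pHat)) || length(p) != length(pHat))
    stop("p and pHat must have identical shapes")
  if (!all(p %in% c(0, 1))) stop("p must be binary (0/1)")
  pmin(pmax(pHat, .lossEps), 1 - .lossEps)
}

#' Binary cross-entropy
#'
#' Mean over pixels of \eqn{-[p \log \hat p + (1-p) \log(1-\hat p)]}. Zero
#' for a perfect prediction; \eqn{\ln 2} when \eqn{\hat p = 0.5} everywhere,
#' regardless of class prevalence.
#'
#' @param p binary ground-truth grid (0 = background, 1 = NGL).
#' @param pHat predicted probability grid, same shape.
#' @return Non-negative scalar.
#' @examples
#' binaryCE(1, 0.5)  # log(2)
#' @export
binaryCE <- function(p, pHat) {
  pHat <- checkLossInputs(p, pHat)
  -mean(p * log(pHat) + (1 - p) * log(1 - pHat))
}

#' Weighted cross-entropy
#'
#' Mean over pixels of \eqn{-[\beta p \log \hat p + (1-p) \log(1-\hat p)]}:
#' the positive (NGL) term is up-weighted by beta in (1,2), background
#' pixels contribute exactly as under \code{\link{binaryCE}}. As beta
#' approaches 1 the loss reduces to plain cross-entropy.
#'
#' @inheritParams binaryCE
#' @param beta positive-class weight in (1, 2).
#' @return Non-negative scalar.
#' @export
weightedCE <- function(p, pHat, beta) {
  if (!(beta > 1 && beta < 2)) stop("for wce, beta must lie in (1,2)")
  pHat <- checkLossInputs(p, pHat)
  -mean(beta * p * log(pHat) + (1 - p) * log(1 - pHat))
}

#' Balanced cross-entropy
#'
#' Mean over pixels of
#' \eqn{-[\beta p \log \hat p + (1-\beta)(1-p) \log(1-\hat p)]}: unit weight
#' is split between the classes, so the positive/negative gradient-weight
#' ratio is \eqn{\beta/(1-\beta)} (99 at the working value beta = 0.99). At
#' beta = 0.5 the loss equals exactly half of \code{\link{binaryCE}}.
#'
#' @inheritParams binaryCE
#' @param beta positive-class weight in (0, 1).
#' @return Non-negative scalar.
#' @examples
#' balancedCE(1, 0.5, beta = 0.99)  # 0.99 * log(2)
#' @export
balancedCE <- function(p, pHat, beta) {
  if (!(beta > 0 && beta < 1)) stop("for bce, beta must lie in (0,1)")
  pHat <- checkLossInputs(p, pHat)
  -mean(beta * p * log(pHat) + (1 - beta) * (1 - p) * log(1 - pHat))
}

#' Evaluate a configured loss
#'
#' @param cfg a \linkS4class{LossConfig}.
#' @inheritParams binaryCE
#' @return Non-negative scalar.
#' @export
evaluateLoss <- function(cfg, p, pHat) {
  switch(cfg@kind,
    ce = binaryCE(p, pHat),
    wce = weightedCE(p, pHat, cfg@beta),
    bce = balancedCE(p, pHat, cfg@beta))
}
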