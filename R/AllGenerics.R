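#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: \code{pixels}
#' and \code{valueRange} for scenes, \code{lowRank}/\code{sparsePart} for
#' decomposition results, \code{nPatches}/\code{patchOrigins} for patch sets,
#' and \code{architecture} for a network's symbolic spec.
#'
#' @param object an nglseg S4 object.
#' @return The slot contents (see each method).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("valueRange", function(object) standardGeneric("valueRange"))

#' @rdname accessors
#' @export
setGeneric("lowRank", function(object) standardGeneric("lowRank"))

#' @rdname accessors
#' @export
setGeneric("sparsePart", function(object) standardGeneric("sparsePart"))

#' @rdname accessors
#' @export
setGeneric("nPatches", function(object) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setGeneric("patchOrigins", function(object) standardGeneric("patchOrigins"))

#' @rdname accessors
#' @export
setGeneric("architecture", function(object) standardGeneric("architecture"))

#' Accuracy from an error matrix
#'
#' Overall accuracy \eqn{(Pa + Pd) / N}: the fraction of pixels on the
#' diagonal of the error matrix.
#'
#' @param object an \linkS4class{ErrorMatrix}.
#' @return numeric scalar in [0,1].
#' @examples
#' accuracy(errorMatrix(40, 10, 20, 30))  # 0.70
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' Cohen's kappa from an error matrix
#'
#' Chance-corrected agreement \eqn{K = (Po - Pe) / (1 - Pe)} where
#' \eqn{Po = (Pa + Pd)/N} is the observed agreement and
#' \eqn{Pe = \frac{(Pa+Pb)(Pa+Pc)}{N^2} + \frac{(Pc+Pd)(Pb+Pd)}{N^2}}
#' the agreement expected by chance from the marginals. Equals 1 for perfect
#' agreement and 0 when the prediction is constant (all NGL or all
#' background). Undefined (returned as \code{NA} with a warning) when both
#' marginals are degenerate and identical, i.e. \eqn{Pe = 1}.
#'
#' @param object an \linkS4class{ErrorMatrix}.
#' @return numeric scalar in [-1,1], or \code{NA} if undefined.
#' @examples
#' cohensKappa(errorMatrix(40, 10, 20, 30))  # 0.4
#' @export
setGeneric("cohensKappa", function(object) standardGeneric("cohensKappa"))
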