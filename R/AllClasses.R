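#' @import methods
NULL

## Central S4 data containers. Validity methods enforce the structural
## contracts that the numerical code relies on, so downstream functions can
## assume well-formed objects.

#' SceneImage: a multi-channel raster scene
#'
#' An in-memory raster with explicit value-range metadata. Pixels are stored
#' as a rank-3 numeric array \code{height x width x channels}; channel count
#' must be 1 (grayscale) or 3 (RGB). The declared range is either
#' \code{"unit"} (real values in [0, 1]) or \code{"uint8"} (integers in
#' 0..255). Each channel, viewed as a matrix, is the matrix P that the
#' low-rank + sparse decomposition operates on.
#'
#' @slot pixels numeric array, \code{height x width x channels}.
#' @slot valueRange character, \code{"unit"} or \code{"uint8"}.
#' @exportClass SceneImage
setClass("SceneImage",
  representation(pixels = "array", valueRange = "character"))

setValidity("SceneImage", function(object) {
  px <- object@pixels
  if (length(dim(px)) != 3L)
    return("pixels must be a height x width x channels array")
  if (!dim(px)[3] %in% c(1L, 3L))
    return("channel count must be 1 or 3")
  if (!all(is.finite(px)))
    return("pixels must be finite")
  if (!object@valueRange %in% c("unit", "uint8"))
    return("valueRange must be 'unit' or 'uint8'")
  lim <- rangeLimits(object@valueRange)
  if (min(px) < lim[1] || max(px) > lim[2])
    return(sprintf("pixel values outside declared %s range", object@valueRange))
  TRUE
})

#' EnhancedImage: a sparse-enhanced scene
#'
#' The result of sparse enhancement, E = clip(P + S), carrying the per-channel
#' decomposition results and the kernel that produced them. Extends
#' \linkS4class{SceneImage}, so an enhanced image can be used anywhere a scene
#' is expected.
#'
#' @slot kernelUsed character, the RPCA kernel name.
#' @slot perChannelResults list of \linkS4class{RpcaResult}, one per channel.
#' @exportClass EnhancedImage
setClass("EnhancedImage", contains = "SceneImage",
  representation(kernelUsed = "character", perChannelResults = "list"))

#' RpcaConfig: configuration for a low-rank + sparse decomposition
#'
#' Collects the kernel choice and its parameters. The GoDec kernel uses
#' \code{rankBound} (the rank budget r) and \code{cardinalityBound} (the
#' l0 budget k on the sparse part); the convex PCP kernel uses
#' \code{lambdaReg} (the l1 weight). \code{gamma} names the l0 regularization
#' weight of the combinatorial objective; it is carried for completeness but
#' never used numerically, because that objective is only ever solved through
#' its relaxations (rank/cardinality caps for GoDec, the convex program for
#' PCP).
#'
#' @slot kernel character, \code{"godec"} or \code{"pcp"}.
#' @slot rankBound integer rank budget (GoDec).
#' @slot cardinalityBound numeric l0 budget (GoDec); \code{NA} means choose
#'   \code{ceiling(0.04 * n_pixels)} at decomposition time, motivated by the
#'   3--4\% NGL prevalence the method assumes.
#' @slot lambdaReg numeric l1 weight (PCP); \code{NA} means
#'   \code{1/sqrt(max(rows, cols))}.
#' @slot gamma numeric, unused l0 weight (kept as metadata).
#' @slot maxIter integer iteration cap.
#' @slot tol numeric relative convergence tolerance.
#' @slot seed integer seed (recorded; both kernels are deterministic).
#' @exportClass RpcaConfig
setClass("RpcaConfig",
  representation(kernel = "character", rankBound = "integer",
    cardinalityBound = "numeric", lambdaReg = "numeric", gamma = "numeric",
    maxIter = "integer", tol = "numeric", seed = "integer"))

setValidity("RpcaConfig", function(object) {
  if (!object@kernel %in% c("godec", "pcp"))
    return("kernel must be 'godec' or 'pcp'")
  if (object@rankBound < 1L) return("rankBound must be positive")
  if (!is.na(object@cardinalityBound) && object@cardinalityBound < 0)
    return("cardinalityBound must be non-negative")
  if (!is.na(object@lambdaReg) && object@lambdaReg <= 0)
    return("lambdaReg must be positive")
  if (object@maxIter < 1L) return("maxIter must be positive")
  if (object@tol <= 0) return("tol must be positive")
  TRUE
})

#' RpcaResult: output of a low-rank + sparse decomposition
#'
#' Holds the decomposition P ~ L + S together with convergence diagnostics.
#' \code{residualTrace} records the relative residual
#' \eqn{\|P - L - S\|_F / \|P\|_F} after each iteration (for GoDec this
#' sequence is non-increasing by construction).
#'
#' @slot L numeric matrix, the low-rank part.
#' @slot S numeric matrix, the sparse part.
#' @slot iterations integer, iterations performed.
#' @slot relativeResidual numeric, final relative residual (0 for zero input
#'   by convention).
#' @slot residualTrace numeric vector of per-iteration relative residuals.
#' @slot converged logical, whether the tolerance was met within maxIter.
#' @slot kernel character, kernel that produced the result.
#' @exportClass RpcaResult
setClass("RpcaResult",
  representation(L = "matrix", S = "matrix", iterations = "integer",
    relativeResidual = "numeric", residualTrace = "numeric",
    converged = "logical", kernel = "character"))

setValidity("RpcaResult", function(object) {
  if (!identical(dim(object@L), dim(object@S)))
    return("L and S must have identical dimensions")
  if (object@relativeResidual < 0)
    return("relativeResidual must be non-negative")
  TRUE
})

#' TileSpec: sliding-window geometry
#'
#' Window size and strides for patch extraction, in pixels. Windows are
#' half-open \code{[r, r+h) x [c, c+w)} with 0-based origins. The study
#' geometry uses a 260 (wide) x 200 (tall) window on a 1300 x 1000 scene:
#' strides (65, 50) for training (289 overlapping patches) and (260, 200) for
#' testing (25 non-overlapping patches).
#'
#' @slot windowW,windowH integer window width/height in pixels.
#' @slot strideX,strideY integer horizontal/vertical strides in pixels.
#' @exportClass TileSpec
setClass("TileSpec",
  representation(windowW = "integer", windowH = "integer",
    strideX = "integer", strideY = "integer"))

setValidity("TileSpec", function(object) {
  v <- c(object@windowW, object@windowH, object@strideX, object@strideY)
  if (any(v < 1L)) return("window dimensions and strides must be positive")
  TRUE
})

#' PatchSet: ordered co-registered image/mask windows
#'
#' Patches are stored in row-major order by (origin_row, origin_col), origins
#' 0-based. Mask windows may be absent (e.g. when tiling a scene for
#' prediction only).
#'
#' @slot origins data.frame with integer columns \code{row}, \code{col}
#'   (0-based origins).
#' @slot imageWindows list of \code{h x w x channels} arrays.
#' @slot maskWindows list of \code{h x w} binary matrices (possibly empty).
#' @slot windowW,windowH integer window dimensions.
#' @slot sourceHeight,sourceWidth integer extent of the source scene.
#' @exportClass PatchSet
setClass("PatchSet",
  representation(origins = "data.frame", imageWindows = "list",
    maskWindows = "list", windowW = "integer", windowH = "integer",
    sourceHeight = "integer", sourceWidth = "integer"))

setValidity("PatchSet", function(object) {
  n <- nrow(object@origins)
  if (length(object@imageWindows) != n)
    return("one image window per origin required")
  if (length(object@maskWindows) > 0 && length(object@maskWindows) != n)
    return("maskWindows must be empty or match origins")
  if (n > 0) {
    if (any(object@origins$row < 0L) || any(object@origins$col < 0L))
      return("origins must be non-negative (0-based)")
    if (any(object@origins$row + object@windowH > object@sourceHeight) ||
        any(object@origins$col + object@windowW > object@sourceWidth))
      return("every window must lie fully inside the source image")
    ord <- order(object@origins$row, object@origins$col)
    if (!identical(ord, seq_len(n)))
      return("patches must be ordered row-major by (origin_row, origin_col)")
  }
  TRUE
})

#' ArchitectureSpec: symbolic layer sequence of a segmentation network
#'
#' Describes a network as the ordered sequence of layer codes used in the
#' architecture tables of encoder-decoder segmentation models: \code{C}
#' (3x3 same-padding convolution + ReLU), \code{BN} (batch normalization),
#' \code{MP} (2x2 max pooling), \code{UP} (2x nearest-neighbor upsampling),
#' \code{SC} (skip-connection concatenation) and \code{Out} (1x1 convolution
#' with sigmoid activation, single channel).
#'
#' @slot name character, one of \code{segnet, unet, 3l_sn, 3l_usn, 2l_usn,
#'   2l_conv_usn}.
#' @slot layerTable data.frame with columns \code{code}, \code{filters},
#'   \code{stage} (encoder/decoder/head).
#' @slot poolingDepth integer number of 2x downsampling stages.
#' @slot skipPairs data.frame with columns \code{encoderLevel},
#'   \code{decoderLevel}; zero rows for skip-free models.
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
  representation(name = "character", layerTable = "data.frame",
    poolingDepth = "integer", skipPairs = "data.frame"))

setValidity("ArchitectureSpec", function(object) {
  lt <- object@layerTable
  if (sum(lt$code == "MP") != object@poolingDepth)
    return("pooling count must equal poolingDepth")
  if (sum(lt$code == "UP") != object@poolingDepth)
    return("upsampling count must equal poolingDepth")
  if (lt$code[nrow(lt)] != "Out")
    return("final layer must be Out")
  TRUE
})

#' SegmentationNetwork: a trainable pixel classifier
#'
#' An opaque trainable map from a \code{h x w x channels} patch (values in
#' [0,1]) to a \code{h x w} grid of NGL probabilities in (0,1). Spatial
#' dimensions must be divisible by \code{2^poolingDepth}. Parameters live in
#' \code{params}, a list parallel to the compiled op graph in \code{graph};
#' use \code{\link{predictPatch}} to run the forward pass and
#' \code{\link{trainModel}} to fit.
#'
#' @slot spec \linkS4class{ArchitectureSpec}.
#' @slot graph list, compiled op graph (internal representation).
#' @slot params list, trainable parameters and batch-norm statistics.
#' @slot inputChannels integer.
#' @slot seed integer used for parameter initialization.
#' @slot trained logical.
#' @exportClass SegmentationNetwork
setClass("SegmentationNetwork",
  representation(spec = "ArchitectureSpec", graph = "list", params = "list",
    inputChannels = "integer", seed = "integer", trained = "logical"))

#' ErrorMatrix: pixel-level confusion counts
#'
#' The four counts from which every scalar detection metric derives, in the
#' row = detection, column = truth convention: \code{pa} = detected NGL and
#' truly NGL (TP), \code{pb} = detected NGL but truly background (FP),
#' \code{pc} = detected background but truly NGL (FN), \code{pd} = detected
#' background and truly background (TN).
#'
#' @slot pa,pb,pc,pd numeric non-negative counts.
#' @exportClass ErrorMatrix
setClass("ErrorMatrix",
  representation(pa = "numeric", pb = "numeric", pc = "numeric",
    pd = "numeric"))

setValidity("ErrorMatrix", function(object) {
  v <- c(object@pa, object@pb, object@pc, object@pd)
  if (any(v < 0)) return("counts must be non-negative")
  if (any(v != round(v))) return("counts must be whole numbers")
  TRUE
})

#' RocCurve: receiver operating characteristic curve
#'
#' Threshold-swept (FPR, TPR) points, sorted by FPR and anchored at (0,0) and
#' (1,1), with the trapezoidal area under the curve. Hard {0,1} score grids
#' degenerate to the three-point "rectangle" curve.
#'
#' @slot fpr,tpr numeric vectors in [0,1], sorted by fpr.
#' @slot auc numeric in [0,1].
#' @exportClass RocCurve
setClass("RocCurve",
  representation(fpr = "numeric", tpr = "numeric", auc = "numeric"))

setValidity("RocCurve", function(object) {
  if (length(object@fpr) != length(object@tpr))
    return("fpr and tpr must have equal length")
  if (any(object@fpr < -1e-12) || any(object@fpr > 1 + 1e-12) ||
      any(object@tpr < -1e-12) || any(object@tpr > 1 + 1e-12))
    return("fpr and tpr must lie in [0,1]")
  if (is.unsorted(object@fpr)) return("points must be sorted by fpr")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  TRUE
})

#' LossConfig: loss functional selection
#'
#' Selects one of the three binary cross-entropy variants. For \code{wce} the
#' positive-class weight beta must lie in (1,2); for \code{bce} in (0,1); for
#' plain \code{ce} beta is unused. Note the two betas are distinct parameters
#' that share a symbol: WCE up-weights positives above 1, BCE splits unit
#' weight between the classes.
#'
#' @slot kind character, \code{"ce"}, \code{"wce"} or \code{"bce"}.
#' @slot beta numeric.
#' @exportClass LossConfig
setClass("LossConfig", representation(kind = "character", beta = "numeric"))

setValidity("LossConfig", function(object) {
  if (!object@kind %in% c("ce", "wce", "bce"))
    return("kind must be 'ce', 'wce' or 'bce'")
  if (object@kind == "wce" && !(object@beta > 1 && object@beta < 2))
    return("for wce, beta must lie in (1,2)")
  if (object@kind == "bce" && !(object@beta > 0 && object@beta < 1))
    return("for bce, beta must lie in (0,1)")
  TRUE
})

#' SyntheticSceneConfig: parameters of the synthetic canopy generator
#'
#' Defines a seeded synthetic scene: a smooth low-rank canopy background plus
#' Gaussian texture noise, with sparse clustered bright light-green disc
#' targets covering roughly \code{targetPrevalence} of the pixels (the
#' generator emulates scenes where the positive class is about 3--4\% of
#' pixels).
#'
#' @slot height,width integer scene extent in pixels.
#' @slot channels integer, 1 or 3.
#' @slot backgroundRank integer rank of the smooth background.
#' @slot backgroundNoiseSd numeric Gaussian noise sd (unit scale).
#' @slot nTargetClusters integer number of target clusters.
#' @slot clusterRadius numeric length-2 admissible disc radius range (px).
#' @slot targetPrevalence numeric target pixel fraction in (0, 0.5).
#' @slot targetColorShift numeric per-channel additive offsets (unit scale),
#'   by default toward bright light green.
#' @slot distractor logical; if TRUE, add a non-target high-frequency texture
#'   region in the lower-right corner (a false-alarm hazard analogous to a
#'   mixed-species image corner).
#' @slot seed integer.
#' @exportClass SyntheticSceneConfig
setClass("SyntheticSceneConfig",
  representation(height = "integer", width = "integer", channels = "integer",
    backgroundRank = "integer", backgroundNoiseSd = "numeric",
    nTargetClusters = "integer", clusterRadius = "numeric",
    targetPrevalence = "numeric", targetColorShift = "numeric",
    distractor = "logical", seed = "integer"))

setValidity("SyntheticSceneConfig", function(object) {
  if (object@height < 8L || object@width < 8L)
    return("scene must be at least 8 x 8")
  if (!object@channels %in% c(1L, 3L)) return("channels must be 1 or 3")
  if (object@backgroundRank < 1L) return("backgroundRank must be positive")
  if (object@backgroundNoiseSd < 0) return("backgroundNoiseSd must be >= 0")
  if (object@nTargetClusters < 0L) return("nTargetClusters must be >= 0")
  if (length(object@clusterRadius) != 2L ||
      object@clusterRadius[1] > object@clusterRadius[2] ||
      object@clusterRadius[1] <= 0)
    return("clusterRadius must be a positive increasing length-2 range")
  if (object@nTargetClusters > 0L &&
      !(object@targetPrevalence > 0 && object@targetPrevalence < 0.5))
    return("targetPrevalence must lie in (0, 0.5)")
  if (length(object@targetColorShift) != object@channels)
    return("targetColorShift must have one entry per channel")
  TRUE
})
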