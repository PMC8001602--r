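## The six segmentation architectures.
##
## All convolutions are 3x3, same padding, followed by batch normalization
## and ReLU; pooling is 2x2 max; upsampling is parameter-free 2x nearest
## neighbor; skip connections are channel concatenation applied after each
## upsampling, before the decoder convolutions; the head is a 1x1 sigmoid
## convolution with a single output channel. The SegNet baseline follows the
## canonical 13 + 13 convolution plan. The shallow hybrids keep two
## convolutions per level at widths 64/128/256 and reduce the pooling depth
## so that tiny-target detail survives the encoder.

.modelNames <- c("segnet", "unet", "3l_sn", "3l_usn", "2l_usn",
  "2l_conv_usn")

.hybridWidths <- c(64L, 128L, 256L)

modelPoolingDepth <- function(name) {
  switch(name, segnet = 5L, unet = 4L, "3l_sn" = 3L, "3l_usn" = 3L,
    "2l_usn" = 2L, "2l_conv_usn" = 2L)
}

## Encoder/decoder plan for a U-SegNet-style hybrid of a given depth.
buildHybrid <- function(gb, depth, skips, bottleneckConv = FALSE) {
  widths <- .hybridWidths[seq_len(depth)]
  taps <- integer(depth)
  for (lv in seq_len(depth)) {
    gbConvBnRelu(gb, widths[lv], "encoder")
    gbConvBnRelu(gb, widths[lv], "encoder")
    taps[lv] <- length(gb$ops)       # relu output feeding the skip
    gbPool(gb)
  }
  if (bottleneckConv)
    gbConvBnRelu(gb, .hybridWidths[depth + 1L], "encoder")
  for (lv in rev(seq_len(depth))) {
    gbUp(gb)
    if (skips) gbConcat(gb, taps[lv], widths[lv])
    gbConvBnRelu(gb, widths[lv], "decoder")
    gbConvBnRelu(gb, widths[lv], "decoder")
  }
  gbOut(gb)
  if (skips)
    data.frame(encoderLevel = seq_len(depth),
               decoderLevel = rev(seq_len(depth)))
  else
    data.frame(encoderLevel = integer(0), decoderLevel = integer(0))
}

buildSegnet <- function(gb) {
  enc <- list(c(64, 64), c(128, 128), c(256, 256, 256), c(512, 512, 512),
    c(512, 512, 512))
  dec <- list(c(512, 512, 512), c(512, 512, 256), c(256, 256, 128),
    c(128, 64), c(64, 64))
  for (blk in enc) {
    for (f in blk) gbConvBnRelu(gb, f, "encoder")
    gbPool(gb)
  }
  for (blk in dec) {
    gbUp(gb)
    for (f in blk) gbConvBnRelu(gb, f, "decoder")
  }
  gbOut(gb)
  data.frame(encoderLevel = integer(0), decoderLevel = integer(0))
}

buildUnet <- function(gb) {
  widths <- c(64L, 128L, 256L, 512L)
  taps <- integer(4)
  for (lv in 1:4) {
    gbConvBnRelu(gb, widths[lv], "encoder")
    gbConvBnRelu(gb, widths[lv], "encoder")
    taps[lv] <- length(gb$ops)
    gbPool(gb)
  }
  gbConvBnRelu(gb, 1024L, "encoder")
  gbConvBnRelu(gb, 1024L, "encoder")
  for (lv in 4:1) {
    gbUp(gb)
    gbConcat(gb, taps[lv], widths[lv])
    gbConvBnRelu(gb, widths[lv], "decoder")
    gbConvBnRelu(gb, widths[lv], "decoder")
  }
  gbOut(gb)
  data.frame(encoderLevel = 1:4, decoderLevel = 4:1)
}

#' Build a segmentation network
#'
#' Constructs one of the six architectures as a symbolic layer sequence plus
#' an initialized trainable network. Pooling depths: 5 (segnet), 4 (unet),
#' 3 (3l_sn, 3l_usn), 2 (2l_usn, 2l_conv_usn). Skip connections are present
#' exactly for unet and the USN variants. \code{2l_conv_usn} is identical to
#' \code{2l_usn} except for one extra convolution + batch-norm unit at the
#' bottleneck encoder stage.
#'
#' @param name one of \code{"segnet"}, \code{"unet"}, \code{"3l_sn"},
#'   \code{"3l_usn"}, \code{"2l_usn"}, \code{"2l_conv_usn"}.
#' @param inputChannels 1 or 3.
#' @param seed integer; fixes parameter initialization, so equal seeds give
#'   identical networks and identical first forward passes.
#' @return A \linkS4class{SegmentationNetwork}; its
#'   \linkS4class{ArchitectureSpec} is available via
#'   \code{architecture(network)}.
#' @examples
#' net <- buildModel("3l_usn", inputChannels = 3, seed = 1)
#' describeArchitecture(architecture(net))
#' @export
buildModel <- function(name, inputChannels = 3L, seed = 1L) {
  if (!name %in% .modelNames)
    stop("unknown model '", name, "'; expected one of: ",
      paste(.modelNames, collapse = ", "))
  if (!inputChannels %in% c(1L, 3L)) stop("inputChannels must be 1 or 3")
  gb <- newGraphBuilder(as.integer(inputChannels))
  skipPairs <- switch(name,
    segnet = buildSegnet(gb),
    unet = buildUnet(gb),
    "3l_sn" = buildHybrid(gb, 3L, skips = FALSE),
    "3l_usn" = buildHybrid(gb, 3L, skips = TRUE),
    "2l_usn" = buildHybrid(gb, 2L, skips = TRUE),
    "2l_conv_usn" = buildHybrid(gb, 2L, skips = TRUE,
      bottleneckConv = TRUE))
  layerTable <- do.call(rbind, gb$rows)
  spec <- new("ArchitectureSpec", name = name, layerTable = layerTable,
    poolingDepth = modelPoolingDepth(name), skipPairs = skipPairs)
  params <- initParams(gb$ops, seed)
  new("SegmentationNetwork", spec = spec, graph = gb$ops, params = params,
    inputChannels = as.integer(inputChannels), seed = as.integer(seed),
    trained = FALSE)
}

#' @rdname accessors
#' @export
setMethod("architecture", "SegmentationNetwork", function(object)
  object@spec)

#' Number of trainable parameters
#' @param network a \linkS4class{SegmentationNetwork}.
#' @return numeric scalar (weights + biases + batch-norm scale/shift).
#' @export
nParameters <- function(network) countParams(network@params)

#' Summarize an architecture
#'
#' Counts the layer codes of a symbolic architecture (convolutions exclude
#' the 1x1 Out head). Deterministic for a fixed spec.
#'
#' @param spec an \linkS4class{ArchitectureSpec} or a
#'   \linkS4class{SegmentationNetwork} (in which case the trainable parameter
#'   count is included).
#' @return Named list with \code{name}, \code{conv}, \code{bn}, \code{mp},
#'   \code{up}, \code{skip}, \code{poolingDepth} and, for a network,
#'   \code{nParameters}.
#' @examples
#' describeArchitecture(architecture(buildModel("segnet")))
#' @export
describeArchitecture <- function(spec) {
  net <- NULL
  if (is(spec, "SegmentationNetwork")) {
    net <- spec
    spec <- spec@spec
  }
  lt <- spec@layerTable
  out <- list(name = spec@name,
    conv = sum(lt$code == "C"),
    bn = sum(lt$code == "BN"),
    mp = sum(lt$code == "MP"),
    up = sum(lt$code == "UP"),
    skip = nrow(spec@skipPairs),
    poolingDepth = spec@poolingDepth)
  if (!is.null(net)) out$nParameters <- nParameters(net)
  out
}

setMethod("show", "ArchitectureSpec", function(object) {
  d <- describeArchitecture(object)
  cat(sprintf(
    "ArchitectureSpec '%s': %d conv, %d BN, %d MP, %d UP, %d skip link(s), pooling depth %d\n",
    d$name, d$conv, d$bn, d$mp, d$up, d$skip, d$poolingDepth))
})

setMethod("show", "SegmentationNetwork", function(object) {
  d <- describeArchitecture(object)
  cat(sprintf(
    "SegmentationNetwork '%s' (%s): %d conv / %d MP / %d UP / %d skip, %s parameters, %d input channel(s)\n",
    d$name, if (object@trained) "trained" else "untrained", d$conv, d$mp,
    d$up, d$skip, format(d$nParameters, big.mark = ","),
    object@inputChannels))
})

checkPatchForNetwork <- function(network, patch) {
  if (is.matrix(patch)) patch <- array(patch, c(dim(patch), 1L))
  d <- dim(patch)
  if (d[3] != network@inputChannels)
    stop("patch has ", d[3], " channel(s); network expects ",
      network@inputChannels)
  div <- 2L^network@spec@poolingDepth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("patch height and width must be divisible by 2^poolingDepth = ",
      div)
  if (min(patch) < 0 || max(patch) > 1)
    stop("patch values must lie in [0, 1]; rescale uint8 data first")
  patch
}

#' Forward pass on a single patch
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics) on one patch and returns the per-pixel NGL probability grid.
#' Output values are strictly inside (0, 1) and the spatial shape equals the
#' input shape.
#'
#' @param network a \linkS4class{SegmentationNetwork}.
#' @param patch \code{h x w x channels} array with values in [0, 1]; h and w
#'   must be divisible by \code{2^poolingDepth}.
#' @return \code{h x w} numeric matrix of scores in (0, 1).
#' @examples
#' net <- buildModel("2l_usn", inputChannels = 1)
#' p <- predictPatch(net, array(0, c(16, 16, 1)))
#' range(p)
#' @export
predictPatch <- function(network, patch) {
  patch <- checkPatchForNetwork(network, patch)
  d <- dim(patch)
  X <- matrix(patch, d[1] * d[2], d[3])
  fwd <- nnForward(network@graph, network@params, X, d[1], d[2],
    train = FALSE, keepCache = FALSE)
  matrix(fwd$score, d[1], d[2])
}

#' Save and load a trained network
#'
#' Networks are serialized with R's native RDS format (parameters,
#' batch-norm statistics and the symbolic architecture together).
#'
#' @param network a \linkS4class{SegmentationNetwork}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{saveNetwork} returns \code{path} invisibly;
#'   \code{loadNetwork} returns the restored
#'   \linkS4class{SegmentationNetwork}.
#' @export
saveNetwork <- function(network, path) {
  stopifnot(is(network, "SegmentationNetwork"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  network <- readRDS(path)
  stopifnot(is(network, "SegmentationNetwork"))
  network
}

#' Export an architecture as JSON
#'
#' Writes the symbolic layer sequence, pooling depth and skip pairs in a
#' framework-neutral JSON form, for reproducibility records.
#'
#' @param spec an \linkS4class{ArchitectureSpec} (or a
#'   \linkS4class{SegmentationNetwork}, whose spec is used).
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to \code{path}).
#' @export
architectureJson <- function(spec, path = NULL) {
  if (is(spec, "SegmentationNetwork")) spec <- spec@spec
  obj <- list(name = spec@name, poolingDepth = spec@poolingDepth,
    layers = spec@layerTable, skipPairs = spec@skipPairs)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
    pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
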