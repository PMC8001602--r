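## Sliding-window patch extraction and prediction stitching.
##
## Coordinates are 0-based and windows are half-open [r, r+h) x [c, c+w).
## The study geometry quotes its window as "260 x 200" for training and
## "200 x 260" for testing; both are interpreted as width 260 x height 200,
## the only reading under which a 1300-wide x 1000-tall scene yields the
## documented 289 training and 25 test patches. Border remainders that do
## not fit a full window are dropped.

#' Create a sliding-window specification
#'
#' @param windowW,windowH window width and height in pixels.
#' @param strideX,strideY horizontal and vertical strides in pixels.
#' @return A \linkS4class{TileSpec}.
#' @examples
#' trainSpec <- tileSpec(260, 200, 65, 50)    # 289 patches on 1300 x 1000
#' testSpec  <- tileSpec(260, 200, 260, 200)  # 25 non-overlapping patches
#' @export
tileSpec <- function(windowW, windowH, strideX = windowW, strideY = windowH) {
  new("TileSpec", windowW = as.integer(windowW),
    windowH = as.integer(windowH), strideX = as.integer(strideX),
    strideY = as.integer(strideY))
}

setMethod("show", "TileSpec", function(object) {
  cat(sprintf("TileSpec: window %d x %d (w x h), strides (%d, %d)\n",
    object@windowW, object@windowH, object@strideX, object@strideY))
})

#' Number of sliding-window patches
#'
#' Closed-form count \code{(floor((W - w)/sx) + 1) * (floor((H - h)/sy) + 1)}
#' of full windows placed on an \code{H x W} scene; partial border windows
#' are dropped.
#'
#' @param spec a \linkS4class{TileSpec}.
#' @param height,width scene extent in pixels.
#' @return integer patch count.
#' @examples
#' patchCount(tileSpec(260, 200, 65, 50), 1000, 1300)    # 289
#' patchCount(tileSpec(260, 200, 260, 200), 1000, 1300)  # 25
#' @export
patchCount <- function(spec, height, width) {
  if (spec@windowW > width || spec@windowH > height)
    stop("window must not exceed the image extent")
  as.integer((floor((width - spec@windowW) / spec@strideX) + 1L) *
    (floor((height - spec@windowH) / spec@strideY) + 1L))
}

patchOriginGrid <- function(spec, height, width) {
  if (spec@windowW > width || spec@windowH > height)
    stop("window must not exceed the image extent")
  rows <- seq.int(0L, height - spec@windowH, by = spec@strideY)
  cols <- seq.int(0L, width - spec@windowW, by = spec@strideX)
  ## row-major ordering by (origin_row, origin_col)
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

#' Extract sliding-window patches
#'
#' Slides the window over the scene (and its co-registered mask, if given)
#' and collects every fully contained window, in row-major order by
#' (origin_row, origin_col).
#'
#' @param image a \linkS4class{SceneImage} or \code{h x w (x c)} array.
#' @param mask optional binary \code{h x w} matrix co-registered with
#'   \code{image}; use \code{NULL} when tiling for prediction only.
#' @param spec a \linkS4class{TileSpec}.
#' @return A \linkS4class{PatchSet}.
#' @examples
#' sc <- SceneImage(array(runif(64 * 96 * 3), c(64, 96, 3)))
#' ps <- extractPatches(sc, mask = NULL, spec = tileSpec(32, 32))
#' nPatches(ps)
#' @export
extractPatches <- function(image, mask = NULL, spec) {
  px <- if (is(image, "SceneImage")) image@pixels else image
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  h <- dim(px)[1]; w <- dim(px)[2]
  if (!is.null(mask)) {
    if (!identical(dim(mask), c(h, w)))
      stop("mask shape must equal the image height x width")
    if (!all(mask %in% c(0, 1)))
      stop("mask must be binary (0/1)")
  }
  org <- patchOriginGrid(spec, h, w)
  n <- nrow(org)
  imgWin <- vector("list", n)
  mskWin <- if (is.null(mask)) list() else vector("list", n)
  for (i in seq_len(n)) {
    r <- org$row[i]; c0 <- org$col[i]
    rr <- (r + 1L):(r + spec@windowH)
    cc <- (c0 + 1L):(c0 + spec@windowW)
    imgWin[[i]] <- px[rr, cc, , drop = FALSE]
    if (!is.null(mask)) mskWin[[i]] <- mask[rr, cc]
  }
  new("PatchSet", origins = org, imageWindows = imgWin, maskWindows = mskWin,
    windowW = spec@windowW, windowH = spec@windowH,
    sourceHeight = as.integer(h), sourceWidth = as.integer(w))
}

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchSet", function(object) nrow(object@origins))

#' @rdname accessors
#' @export
setMethod("patchOrigins", "PatchSet", function(object) object@origins)

#' @describeIn accessors number of patches in a PatchSet.
#' @export
setMethod("length", "PatchSet", function(x) nrow(x@origins))

setMethod("show", "PatchSet", function(object) {
  cat(sprintf(
    "PatchSet: %d patch(es) of %d x %d (w x h) from a %d x %d scene%s\n",
    nrow(object@origins), object@windowW, object@windowH,
    object@sourceHeight, object@sourceWidth,
    if (length(object@maskWindows)) ", with masks" else ""))
})

#' Image window of one patch
#' @param patches a \linkS4class{PatchSet}.
#' @param i patch index (1-based, row-major order).
#' @return \code{h x w x c} array.
#' @export
imageWindow <- function(patches, i) patches@imageWindows[[i]]

#' Mask window of one patch
#' @param patches a \linkS4class{PatchSet}.
#' @param i patch index (1-based, row-major order).
#' @return \code{h x w} binary matrix.
#' @export
maskWindow <- function(patches, i) {
  if (length(patches@maskWindows) == 0)
    stop("this PatchSet carries no mask windows")
  patches@maskWindows[[i]]
}

#' Stitch per-patch predictions into a full-scene grid
#'
#' Places each patch's score grid back at its origin. Requires a
#' non-overlapping specification (stride >= window on both axes);
#' overlap-averaging is deliberately unsupported. Pixels not covered by any
#' window are returned as \code{NA} so they can be excluded from evaluation.
#'
#' @param scores list of \code{h x w} numeric matrices, aligned with
#'   \code{origins} (e.g. from predicting each window of a
#'   \linkS4class{PatchSet}).
#' @param origins data.frame with 0-based \code{row}, \code{col} columns, or
#'   a \linkS4class{PatchSet} whose origins should be used.
#' @param extent \code{c(height, width)} of the target scene.
#' @param spec the non-overlapping \linkS4class{TileSpec} used to tile.
#' @return \code{height x width} numeric matrix; uncovered pixels are
#'   \code{NA}.
#' @export
stitchPredictions <- function(scores, origins, extent, spec) {
  if (spec@strideX < spec@windowW || spec@strideY < spec@windowH)
    stop("stitching requires a non-overlapping spec (stride >= window)")
  if (is(origins, "PatchSet")) origins <- origins@origins
  if (length(scores) != nrow(origins))
    stop("one score grid per origin required")
  out <- matrix(NA_real_, extent[1], extent[2])
  for (i in seq_along(scores)) {
    sgrid <- scores[[i]]
    if (!identical(dim(sgrid), c(spec@windowH, spec@windowW)))
      stop("score grid ", i, " does not match the window size")
    r <- origins$row[i]; c0 <- origins$col[i]
    out[(r + 1L):(r + spec@windowH), (c0 + 1L):(c0 + spec@windowW)] <- sgrid
  }
  out
}
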