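## Scene construction, accessors and raster I/O.

rangeLimits <- function(valueRange) {
  if (valueRange == "unit") c(0, 1) else c(0, 255)
}

#' Create a SceneImage
#'
#' Wraps a pixel grid in a \linkS4class{SceneImage} with declared value-range
#' metadata. A plain matrix is promoted to a single-channel array.
#'
#' @param pixels numeric matrix (\code{h x w}) or array (\code{h x w x c},
#'   c in {1, 3}).
#' @param valueRange \code{"unit"} for real values in [0,1] (default) or
#'   \code{"uint8"} for integers in 0..255.
#' @return A \linkS4class{SceneImage}.
#' @examples
#' sc <- SceneImage(matrix(runif(12), 3, 4))
#' dim(pixels(sc))
#' @export
SceneImage <- function(pixels, valueRange = c("unit", "uint8")) {
  valueRange <- match.arg(valueRange)
  if (is.matrix(pixels))
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  storage.mode(pixels) <- "double"
  new("SceneImage", pixels = pixels, valueRange = valueRange)
}

#' @rdname accessors
#' @export
setMethod("pixels", "SceneImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("valueRange", "SceneImage", function(object) object@valueRange)

#' @describeIn SceneImage scene extent \code{c(height, width, channels)}.
#' @param x a SceneImage.
#' @export
setMethod("dim", "SceneImage", function(x) dim(x@pixels))

setMethod("show", "SceneImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s: %d x %d, %d channel(s), %s range\n", class(object),
    d[1], d[2], d[3], object@valueRange))
})

setMethod("show", "EnhancedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EnhancedImage: %d x %d, %d channel(s), %s range, kernel '%s'\n",
    d[1], d[2], d[3], object@valueRange, object@kernelUsed))
})

clipToRange <- function(pixels, valueRange) {
  lim <- rangeLimits(valueRange)
  pixels[pixels < lim[1]] <- lim[1]
  pixels[pixels > lim[2]] <- lim[2]
  if (valueRange == "uint8") pixels <- round(pixels)
  pixels
}

#' Read a scene from a raster file
#'
#' Reads PNG (via the \pkg{png} package) or TIFF (via \pkg{tiff}, if
#' installed) into a \linkS4class{SceneImage}. Values are returned in unit
#' range unless \code{valueRange = "uint8"} is requested, in which case they
#' are rescaled to 0..255 integers. Alpha channels are dropped. Geo-tags in
#' TIFF files are not interpreted or preserved.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param valueRange declared range of the returned scene.
#' @return A \linkS4class{SceneImage}.
#' @export
readScene <- function(path, valueRange = c("unit", "uint8")) {
  valueRange <- match.arg(valueRange)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported raster format: .", ext))
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] %in% c(2L, 4L))  # drop alpha
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE]
  if (dim(px)[3] == 2L) px <- px[, , 1L, drop = FALSE]
  if (valueRange == "uint8") px <- round(px * 255)
  SceneImage(px, valueRange)
}

#' Write a scene to a raster file
#'
#' Writes a \linkS4class{SceneImage} (or a plain matrix/array, assumed unit
#' range) as PNG or TIFF. uint8 scenes are rescaled to unit range for
#' encoding.
#'
#' @param scene a \linkS4class{SceneImage}, matrix or array.
#' @param path output file path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeScene <- function(scene, path) {
  if (is(scene, "SceneImage")) {
    px <- scene@pixels
    if (scene@valueRange == "uint8") px <- px / 255
  } else {
    px <- if (is.matrix(scene)) array(scene, c(dim(scene), 1L)) else scene
  }
  px <- clipToRange(px, "unit")
  if (dim(px)[3] == 1L) px <- px[, , 1L]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(px, path)
    },
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' Read a binary mask from a PNG/TIFF file
#'
#' Any strictly positive pixel (first channel) is treated as NGL.
#'
#' @param path raster file path.
#' @return Integer 0/1 matrix.
#' @export
readMask <- function(path) {
  sc <- readScene(path)
  m <- sc@pixels[, , 1L]
  (m > 0) * 1L
}
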