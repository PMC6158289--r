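#' Construct an ImageStack
#'
#' @param pixels numeric 4-D array \code{[row, col, channel, frame]}, or a
#'   3-D array \code{[row, col, frame]} for a single channel.
#' @param pixelSize physical pixel size, micrometres per pixel.
#' @param frameInterval time between frames, seconds.
#' @param channelNames character vector of channel names; defaults to
#'   \code{"organizer"}, \code{"cargo"}, then \code{"ch3"}, ... as needed.
#' @return an [ImageStack-class]
#' @examples
#' px <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
#' ImageStack(px, pixelSize = 0.5, frameInterval = 2)
#' @export
ImageStack <- function(pixels, pixelSize = 1, frameInterval = 1,
                       channelNames = NULL) {
  if (length(dim(pixels)) == 3L)
    dim(pixels) <- c(dim(pixels)[1:2], 1L, dim(pixels)[3])
  if (is.null(channelNames)) {
    nc <- dim(pixels)[3L]
    channelNames <- c("organizer", "cargo", paste0("ch", seq_len(nc)))[seq_len(nc)]
  }
  new("ImageStack", pixels = pixels, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      channelNames = as.character(channelNames))
}

#' @rdname ImageStack-class
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@pixels)[4L])

#' @rdname ImageStack-class
#' @export
setMethod("nChannels", "ImageStack", function(x) dim(x@pixels)[3L])

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' @rdname ImageStack-class
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname ImageStack-class
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@pixels))

.channelIndex <- function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i))
      stop("unknown channel '", channel, "'; have: ",
           paste(x@channelNames, collapse = ", "))
    i
  } else {
    i <- as.integer(channel)
    if (i < 1L || i > nChannels(x)) stop("channel index out of range")
    i
  }
}

#' @rdname getFrame
#' @export
setMethod("getFrame", "ImageStack", function(x, frame, channel) {
  f <- as.integer(frame) + 1L
  if (f < 1L || f > nFrames(x)) stop("frame index out of range (0-based)")
  x@pixels[, , .channelIndex(x, channel), f]
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat("ImageStack: ", d[2], " x ", d[1], " px, ", d[3], " channel(s) [",
      paste(object@channelNames, collapse = ", "), "], ", d[4], " frame(s)\n",
      "  calibration: ", object@pixelSize, " um/px, ",
      object@frameInterval, " s/frame\n", sep = "")
})

#' @rdname timeAverage
#' @export
setMethod("timeAverage", "ImageStack", function(x, ...) {
  if (nFrames(x) < 2L) stop("time average requires at least 2 frames")
  avg <- apply(x@pixels, c(1, 2, 3), mean)
  dim(avg) <- c(dim(avg), 1L)
  initialize(x, pixels = avg)
})

#' Read a multi-page TIFF into an ImageStack
#'
#' Pages are de-interleaved channel-major within each frame: with
#' \code{nChannels = 2}, pages 1, 2 are frame 0 (channel 1, channel 2),
#' pages 3, 4 frame 1, and so on.  The page count must be divisible by the
#' channel count.
#'
#' @param path TIFF file path.
#' @param nChannels number of interleaved channels.
#' @param pixelSize,frameInterval physical calibration (the plain-baseline
#'   TIFF reader carries no calibration; values must be supplied, defaults 1).
#' @param channelNames optional channel names.
#' @param scale multiplicative factor applied to the stored [0, 1] TIFF
#'   samples to recover intensity units; must match the \code{scale} used by
#'   [writeStack()].
#' @return an [ImageStack-class]
#' @seealso [writeStack()]
#' @export
readStack <- function(path, nChannels = 1L, pixelSize = 1, frameInterval = 1,
                      channelNames = NULL, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  nChannels <- as.integer(nChannels)
  if (np %% nChannels != 0L)
    stop("page count (", np, ") is not divisible by channel count (",
         nChannels, ")")
  nf <- np %/% nChannels
  d <- dim(pages[[1L]])[1:2]
  px <- array(0, c(d[1L], d[2L], nChannels, nf))
  for (f in seq_len(nf))
    for (ch in seq_len(nChannels)) {
      pg <- pages[[(f - 1L) * nChannels + ch]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # collapse grayscale-as-RGB
      px[, , ch, f] <- pg * scale
    }
  ImageStack(px, pixelSize = pixelSize, frameInterval = frameInterval,
             channelNames = channelNames)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Pages are channel-major interleaved (frame 0 channel 1, frame 0
#' channel 2, ...).  Intensities are divided by \code{scale} and stored as
#' 16-bit unsigned samples by default; pass \code{bitsPerSample = 32} for
#' lossless float output.
#'
#' @param x an [ImageStack-class]
#' @param path output file path
#' @param scale intensity units mapped to TIFF full scale; defaults to the
#'   smallest power of two not below the stack maximum, returned invisibly so
#'   round-trips are reproducible.
#' @param bitsPerSample 16 (unsigned, quantized) or 32 (IEEE float).
#' @return invisibly, the scale used.
#' @export
writeStack <- function(x, path, scale = NULL, bitsPerSample = 16L) {
  stopifnot(is(x, "ImageStack"))
  if (is.null(scale)) scale <- max(2^ceiling(log2(max(x@pixels, 1))), 1)
  pages <- vector("list", nFrames(x) * nChannels(x))
  k <- 1L
  for (f in seq_len(nFrames(x)))
    for (ch in seq_len(nChannels(x))) {
      pages[[k]] <- pmin(pmax(x@pixels[, , ch, f] / scale, 0), 1)
      k <- k + 1L
    }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(scale)
}
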