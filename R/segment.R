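#' Segment organizer waves into complementary binary masks
#'
#' Reproduces the standard wave-segmentation chain on the organizer channel,
#' frame by frame: median filter (disc, default radius 4 px) ->
#' pseudo-flat-field correction (default sigma 75 px) -> automatic threshold
#' (Huang, or Li for dense-bundle channels) -> wave mask = pixels strictly
#' above the threshold; the complement mask is its logical inverse.  The
#' masks are meant to be applied to the ORIGINAL unfiltered images by
#' [computeWaveStats()]; the filtered images are used only to find the
#' threshold.
#'
#' Frames that are constant after filtering admit no threshold; they are
#' marked invalid (all-\code{FALSE} mask, \code{NA} threshold), reported via
#' a message, and excluded from downstream statistics.
#'
#' Because the threshold is computed on the min-max scaled histogram,
#' segmentation is invariant under multiplication of the input intensities
#' by a positive constant.
#'
#' @param stack an [ImageStack-class]
#' @param organizerChannel channel name or index of the organizer (wave)
#'   channel; default \code{"organizer"}.
#' @param method \code{"huang"} (default) or \code{"li"}.
#' @param medianRadius disc radius of the despeckling median filter (px).
#' @param flatfieldRadius sigma of the pseudo-flat-field blur (px).
#' @return a [WaveMaskPair-class]
#' @examples
#' sc <- generatePlanarScene(sceneParams("planar", nFrames = 10, rngSeed = 1))
#' masks <- segmentWave(imageStack(sc))
#' mean(waveMask(masks) == trueMask(groundTruth(sc)))
#' @export
segmentWave <- function(stack, organizerChannel = "organizer",
                        method = c("huang", "li"),
                        medianRadius = 4L, flatfieldRadius = 75) {
  stopifnot(is(stack, "ImageStack"))
  method <- match.arg(method)
  thrFun <- switch(method, huang = thresholdHuang, li = thresholdLi)
  nf <- nFrames(stack)
  d <- dim(stack@pixels)
  wm <- array(FALSE, c(d[1L], d[2L], nf))
  thr <- rep(NA_real_, nf)
  valid <- rep(TRUE, nf)
  for (f in seq_len(nf)) {
    img <- getFrame(stack, f - 1L, organizerChannel)
    filt <- medianFilterDisc(img, medianRadius)
    filt <- pseudoFlatFieldCorrect(filt, flatfieldRadius)
    if (max(filt) - min(filt) <= 1e-9 * max(abs(filt))) {
      valid[f] <- FALSE
      message("frame ", f - 1L, " constant after filtering; marked invalid")
      next
    }
    thr[f] <- thrFun(filt)
    wm[, , f] <- filt > thr[f]
  }
  new("WaveMaskPair", waveMask = wm, thresholdMethod = method,
      thresholdValues = thr, validFrames = valid,
      parameters = list(organizerChannel = organizerChannel,
                        medianRadius = medianRadius,
                        flatfieldRadius = flatfieldRadius))
}

#' @rdname WaveMaskPair-class
#' @export
setMethod("waveMask", "WaveMaskPair", function(x) x@waveMask)

#' @rdname WaveMaskPair-class
#' @export
setMethod("complementMask", "WaveMaskPair", function(x) !x@waveMask)

#' @rdname WaveMaskPair-class
#' @export
setMethod("thresholdValues", "WaveMaskPair", function(x) x@thresholdValues)

#' @rdname WaveMaskPair-class
#' @export
setMethod("validFrames", "WaveMaskPair", function(x) x@validFrames)

setMethod("show", "WaveMaskPair", function(object) {
  d <- dim(object@waveMask)
  cat("WaveMaskPair: ", d[3], " frame(s), ", d[2], " x ", d[1], " px, method '",
      object@thresholdMethod, "'\n  valid frames: ", sum(object@validFrames),
      "/", d[3], "; mean wave area fraction: ",
      signif(mean(object@waveMask[, , object@validFrames]), 3), "\n", sep = "")
})

#' Write masks as 8-bit TIFF (0/255) and thresholds as CSV
#'
#' @param masks a [WaveMaskPair-class]
#' @param tiffPath output TIFF path (one page per frame, wave mask)
#' @param csvPath optional CSV path for per-frame thresholds
#' @return invisibly \code{NULL}
#' @export
writeMasks <- function(masks, tiffPath, csvPath = NULL) {
  d <- dim(masks@waveMask)
  pages <- lapply(seq_len(d[3L]), function(f) masks@waveMask[, , f] * 1.0)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 8L)
  if (!is.null(csvPath))
    utils::write.csv(data.frame(frame = seq_len(d[3L]) - 1L,
                                threshold = masks@thresholdValues,
                                valid = masks@validFrames,
                                method = masks@thresholdMethod),
                     csvPath, row.names = FALSE)
  invisible(NULL)
}
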