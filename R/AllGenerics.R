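#' @rdname ImageStack-class
#' @param object,x an object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ImageStack-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname ImageStack-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Extract one image plane
#'
#' @param x an [ImageStack-class]
#' @param frame 0-based frame index
#' @param channel channel name or 1-based channel index
#' @return numeric matrix \code{[row, col]}
#' @export
setGeneric("getFrame", function(x, frame, channel) standardGeneric("getFrame"))

#' @rdname WaveMaskPair-class
#' @param x a [WaveMaskPair-class]
#' @export
setGeneric("waveMask", function(x) standardGeneric("waveMask"))

#' @rdname WaveMaskPair-class
#' @export
setGeneric("complementMask", function(x) standardGeneric("complementMask"))

#' @rdname WaveMaskPair-class
#' @export
setGeneric("thresholdValues", function(x) standardGeneric("thresholdValues"))

#' @rdname WaveMaskPair-class
#' @export
setGeneric("validFrames", function(x) standardGeneric("validFrames"))

#' @rdname SyntheticScene-class
#' @param x a [SyntheticScene-class]
#' @export
setGeneric("imageStack", function(x) standardGeneric("imageStack"))

#' @rdname SyntheticScene-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SyntheticScene-class
#' @export
setGeneric("sceneParameters", function(x) standardGeneric("sceneParameters"))

#' Per-pixel time average of a stack
#'
#' Arithmetic mean over frames, per pixel and channel, as used for the
#' steady-state concentration-gradient analysis in oscillating compartments.
#'
#' @param x an [ImageStack-class] with at least two frames
#' @param ... unused
#' @return an [ImageStack-class] with a single frame
#' @export
setGeneric("timeAverage", function(x, ...) standardGeneric("timeAverage"))

#' Wave contrast of a channel
#'
#' The average signal in the wave minimum above the signal in the wave
#' maximum, divided by the signal in the wave maximum:
#' \deqn{(I_{min(MinD)} - I_{max(MinD)}) / I_{max(MinD)}.}
#' Positive for cargo anticorrelated with the organizer wave; negative for
#' the organizer channel on its own masks.  Invariant under multiplication
#' of all intensities by a positive constant.
#'
#' @param x a [WaveIntensityStats-class]
#' @param channel channel name
#' @return numeric vector, one contrast value per valid frame (NA for frames
#'   with non-positive \code{I_max})
#' @export
setGeneric("contrast", function(x, channel) standardGeneric("contrast"))

#' @rdname WaveIntensityStats-class
#' @param x a [WaveIntensityStats-class]
#' @export
setGeneric("frameStats", function(x) standardGeneric("frameStats"))
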