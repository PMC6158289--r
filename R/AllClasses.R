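#' @import methods
NULL

#' ImageStack: calibrated multi-channel fluorescence time-lapse
#'
#' The common currency of all analysis stages: a four-dimensional pixel array
#' holding one image per (frame, channel), together with its physical
#' calibration.  Pixels are stored as \code{[row, col, channel, frame]} in
#' native R (column-major) order; all user-facing coordinates in tabular
#' inputs (ROIs, line selections) are 0-based to match the conventions of the
#' image-processing tools this package interoperates with, and are converted
#' internally.
#'
#' @slot pixels numeric 4-D array \code{[row, col, channel, frame]}, all
#'   values non-negative (camera counts / intensity units).
#' @slot pixelSize numeric(1), physical pixel edge length in micrometres per
#'   pixel; strictly positive.
#' @slot frameInterval numeric(1), time between frames in seconds; strictly
#'   positive.
#' @slot channelNames character vector naming the channels, length equal to
#'   \code{dim(pixels)[3]}.  By convention the organizer (e.g. MinD) channel
#'   is named \code{"organizer"} and the regulated species \code{"cargo"}.
#'
#' @seealso [ImageStack()] for construction, [readStack()]/[writeStack()] for
#'   TIFF I/O, [getFrame()] for pixel access.
#' @export
setClass("ImageStack",
  representation(
    pixels = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    channelNames = "character"
  )
)

setValidity("ImageStack", function(object) {
  msg <- NULL
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msg <- c(msg, "'pixels' must be a 4-D array [row, col, channel, frame]")
  else {
    if (length(object@channelNames) != d[3L])
      msg <- c(msg, sprintf("found %d channel names for %d channels",
                            length(object@channelNames), d[3L]))
    if (anyNA(object@pixels) || min(object@pixels) < 0)
      msg <- c(msg, "pixel intensities must be non-negative and non-missing")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (um/px)")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "'frameInterval' must be a single positive number (s)")
  if (is.null(msg)) TRUE else msg
})

#' WaveMaskPair: complementary binary wave masks
#'
#' Per-frame segmentation of the organizer channel into the wave maximum
#' (pixels occupied by the organizer wave, \code{max(MinD)}) and its logical
#' complement (the wave minimum, \code{min(MinD)}).  Only the wave mask is
#' stored; the complement is derived, so complementarity (union = all pixels,
#' intersection = empty) holds by construction and is exposed through
#' [complementMask()].
#'
#' @slot waveMask logical 3-D array \code{[row, col, frame]}; \code{TRUE}
#'   inside the organizer wave.
#' @slot thresholdMethod character(1), \code{"huang"} or \code{"li"}.
#' @slot thresholdValues numeric per frame, the threshold applied (in
#'   intensity units of the filtered image); \code{NA} for invalid frames.
#' @slot validFrames logical per frame; frames that were constant after
#'   filtering are marked invalid and excluded from downstream statistics.
#' @slot parameters list of the segmentation parameters used (median radius,
#'   flat-field radius), recorded for provenance.
#' @export
setClass("WaveMaskPair",
  representation(
    waveMask = "array",
    thresholdMethod = "character",
    thresholdValues = "numeric",
    validFrames = "logical",
    parameters = "list"
  )
)

setValidity("WaveMaskPair", function(object) {
  msg <- NULL
  d <- dim(object@waveMask)
  if (length(d) != 3L || !is.logical(object@waveMask))
    msg <- c(msg, "'waveMask' must be a logical 3-D array [row, col, frame]")
  else {
    if (length(object@thresholdValues) != d[3L])
      msg <- c(msg, "one threshold per frame required")
    if (length(object@validFrames) != d[3L])
      msg <- c(msg, "one validity flag per frame required")
  }
  if (!object@thresholdMethod %in% c("huang", "li"))
    msg <- c(msg, "'thresholdMethod' must be 'huang' or 'li'")
  if (is.null(msg)) TRUE else msg
})

#' WaveIntensityStats: masked per-frame intensity statistics
#'
#' For every valid frame and channel, the mean intensity over the full image
#' (\code{I_full}), over the wave minimum (\code{I_min}, complement mask) and
#' over the wave maximum (\code{I_max}, wave mask), computed on the original
#' unfiltered images.  Houses the quantities written in the field as
#' \eqn{I^{cargo}}, \eqn{I_{min(MinD)}^{cargo}} and
#' \eqn{I_{max(MinD)}^{cargo}}.
#'
#' @slot frameStats data.frame with columns \code{frame} (0-based),
#'   \code{channel}, \code{I_full}, \code{I_min}, \code{I_max}, \code{valid}.
#' @slot channelNames character, the channels covered.
#' @slot zeroRemoval logical(1); \code{TRUE} when the historical
#'   zero-removal masked mean was used (see [maskedMeanZeroRemoved()]).
#' @export
setClass("WaveIntensityStats",
  representation(
    frameStats = "data.frame",
    channelNames = "character",
    zeroRemoval = "logical"
  )
)

setValidity("WaveIntensityStats", function(object) {
  need <- c("frame", "channel", "I_full", "I_min", "I_max", "valid")
  if (!all(need %in% names(object@frameStats)))
    return(paste("frameStats must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' SceneParams: full parameterization of a synthetic scene
#'
#' Everything needed to regenerate a synthetic two-channel time-lapse
#' bit-identically: wave geometry, cargo model, imaging artifacts and the RNG
#' seed.  Construct with [sceneParams()], which supplies mode-appropriate
#' defaults and validates the invariants.
#'
#' @slot mode character(1): \code{"planar"}, \code{"collision"},
#'   \code{"spiral_like"} or \code{"compartment"}.
#' @slot width,height integer image size in pixels (width = columns).
#' @slot nFrames integer number of frames.
#' @slot pixelSize,frameInterval physical calibration (um/px, s).
#' @slot wavelength wave period in pixels; \code{waveSpeed} in px/frame.
#' @slot dutyCycle fraction of the wave period during which the organizer is
#'   above half-maximum, in (0, 1).
#' @slot riseFrac,fallFrac widths of the slow leading ramp and the steep
#'   trailing ramp of the wave pulse, as fractions of one period.  Setting
#'   both to 0 gives a square (binary) pulse.
#' @slot organizerBackground,organizerAmplitude intensity units.
#' @slot cargoMode \code{"transient"} (instantaneous occupancy depletion) or
#'   \code{"anchored"} (mass-conserved lateral transport).
#' @slot cargoBaseline intensity units.
#' @slot kappa dimensionless depletion strength in [0, 1).
#' @slot cargoDiffusion cargo diffusion coefficient, px^2/frame.
#' @slot barrierCoupling drift strength down the organizer gradient,
#'   px^2/frame (the "propagating diffusion barrier" coupling).
#' @slot oscPeriod compartment-mode pole-to-pole oscillation period, frames.
#' @slot forcingOffFrame 0-based frame index from which the organizer is
#'   switched off (emulating vanadate-induced detachment), or \code{NA}.
#' @slot illuminationSigma width (px) of the Gaussian illumination vignette,
#'   or \code{NA} for uniform illumination.
#' @slot photonGain electrons per intensity unit for Poisson shot noise, or
#'   \code{NA} to disable shot noise.
#' @slot readNoiseSigma additive Gaussian read noise SD, intensity units
#'   (0 disables).
#' @slot bleachTau exponential photobleaching time constant in frames, or
#'   \code{NA} to disable bleaching.
#' @slot rngSeed integer seed; identical params (including seed) give
#'   bit-identical stacks.
#' @export
setClass("SceneParams",
  representation(
    mode = "character",
    width = "integer", height = "integer", nFrames = "integer",
    pixelSize = "numeric", frameInterval = "numeric",
    wavelength = "numeric", waveSpeed = "numeric", dutyCycle = "numeric",
    riseFrac = "numeric", fallFrac = "numeric",
    organizerBackground = "numeric", organizerAmplitude = "numeric",
    cargoMode = "character", cargoBaseline = "numeric",
    kappa = "numeric", cargoDiffusion = "numeric", barrierCoupling = "numeric",
    oscPeriod = "numeric",
    forcingOffFrame = "numeric",
    illuminationSigma = "numeric", photonGain = "numeric",
    readNoiseSigma = "numeric", bleachTau = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  msg <- NULL
  if (!object@mode %in% c("planar", "collision", "spiral_like", "compartment"))
    msg <- c(msg, "unknown mode")
  if (!object@cargoMode %in% c("transient", "anchored"))
    msg <- c(msg, "cargoMode must be 'transient' or 'anchored'")
  if (object@width < 8L || object@height < 8L)
    msg <- c(msg, "all dimensions must be at least 8 px")
  if (object@kappa < 0 || object@kappa >= 1)
    msg <- c(msg, "kappa must lie in [0, 1)")
  if (object@dutyCycle <= 0 || object@dutyCycle >= 1)
    msg <- c(msg, "dutyCycle must lie in (0, 1)")
  if (object@riseFrac < 0 || object@fallFrac < 0 ||
      object@dutyCycle + (object@riseFrac + object@fallFrac) / 2 > 1)
    msg <- c(msg, "pulse ramps must be non-negative and fit within one period")
  if (object@mode == "planar" &&
      object@waveSpeed * object@nFrames < object@wavelength)
    msg <- c(msg, "waveSpeed * nFrames must span at least one wavelength in planar mode")
  if (object@mode == "compartment" && object@height >= object@width)
    msg <- c(msg, "compartment mode requires rod geometry (height < width)")
  if (object@organizerAmplitude <= 0 || object@cargoBaseline <= 0)
    msg <- c(msg, "amplitudes must be positive")
  if (object@cargoDiffusion < 0 || object@barrierCoupling < 0)
    msg <- c(msg, "cargoDiffusion and barrierCoupling must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: noise-free fields and masks of a synthetic scene
#'
#' @slot cleanOrganizer,cleanCargo numeric 3-D arrays \code{[row, col, frame]}
#'   of the noise-free fields (before illumination, bleaching and noise).
#' @slot trueMask logical 3-D array; organizer field above half of its
#'   amplitude.
#' @slot totalCargoMass numeric per frame, sum of the clean cargo field;
#'   constant across frames for anchored cargo with reflecting boundaries.
#' @slot illuminationField matrix, the multiplicative illumination applied
#'   (all ones when disabled).
#' @slot bleachFactors numeric per frame, the multiplicative bleach factors.
#' @export
setClass("GroundTruth",
  representation(
    cleanOrganizer = "array",
    cleanCargo = "array",
    trueMask = "array",
    totalCargoMass = "numeric",
    illuminationField = "matrix",
    bleachFactors = "numeric"
  )
)

#' SyntheticScene: a generated stack with its ground truth
#'
#' @slot stack the [ImageStack-class] as an instrument would record it.
#' @slot truth the [GroundTruth-class] fields.
#' @slot params the [SceneParams-class] that generated the scene.
#' @export
setClass("SyntheticScene",
  representation(
    stack = "ImageStack",
    truth = "GroundTruth",
    params = "SceneParams"
  )
)

#' AxialProfile: intensity profile along a compartment's long axis
#'
#' @slot positions numeric, pixel positions along the long axis (0-based,
#'   strictly increasing).
#' @slot values numeric matrix \code{[position, channel]} of mean intensities
#'   (averaged over the short axis).
#' @slot channelNames character.
#' @slot source character(1) compartment identifier.
#' @export
setClass("AxialProfile",
  representation(
    positions = "numeric",
    values = "matrix",
    channelNames = "character",
    source = "character"
  )
)

setValidity("AxialProfile", function(object) {
  msg <- NULL
  if (length(object@positions) != nrow(object@values))
    msg <- c(msg, "positions and values rows must match")
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (ncol(object@values) != length(object@channelNames))
    msg <- c(msg, "one channel name per value column required")
  if (is.null(msg)) TRUE else msg
})

#' UnitBoxProfile: time-averaged profile on the organizer-defined unit box
#'
#' The axial profile linearly remapped so the organizer's two polar maxima
#' sit at x = -0.5 and x = +0.5 (x = 0 is mid-compartment), each channel
#' normalized by its own mean over the box, with the quadratic fit
#' \eqn{f(x) = a x^2 + b} and classification per channel.  On a unit box the
#' profile depth and the curvature 2a differ only by a constant prefactor.
#'
#' @slot x numeric grid on [-0.5, 0.5].
#' @slot values numeric matrix \code{[grid point, channel]}, mean-normalized.
#' @slot channelNames character.
#' @slot fits data.frame with columns \code{channel}, \code{a}, \code{b},
#'   \code{curvature} (= 2a), \code{depth} (= a/4, f(+-0.5) - f(0)),
#'   \code{classification}.
#' @slot boxEdges numeric(2), the polar-maxima positions (px) defining the box.
#' @export
setClass("UnitBoxProfile",
  representation(
    x = "numeric",
    values = "matrix",
    channelNames = "character",
    fits = "data.frame",
    boxEdges = "numeric"
  )
)

#' Kymograph: space-time intensity image along a line selection
#'
#' @slot values numeric matrix \code{[time, position]}.
#' @slot line numeric(4) \code{c(x0, y0, x1, y1)} endpoints in 0-based pixel
#'   coordinates.
#' @slot spatialStep micrometres per kymograph column.
#' @slot timeStep seconds per kymograph row.
#' @export
setClass("Kymograph",
  representation(
    values = "matrix",
    line = "numeric",
    spatialStep = "numeric",
    timeStep = "numeric"
  )
)

#' PooledResult: per-experiment pooling of image means
#'
#' Unweighted mean over per-experiment means, with the sample standard
#' deviation across experiments (reported only for two or more experiments).
#'
#' @slot groupMeans numeric, one mean per independent experiment.
#' @slot grandMean numeric(1).
#' @slot sd numeric(1); \code{NA} when fewer than two experiments.
#' @slot nGroups,nValues integer counts of experiments and pooled images.
#' @export
setClass("PooledResult",
  representation(
    groupMeans = "numeric",
    grandMean = "numeric",
    sd = "numeric",
    nGroups = "integer",
    nValues = "integer"
  )
)
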