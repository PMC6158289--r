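#' Masked mean intensity with historical zero removal
#'
#' Reproduces the quantification step used with complementary wave masks:
#' the binary mask is multiplied pixelwise with the original image, ALL
#' zero-valued products are removed, and the mean of the remaining values is
#' returned.  Note the documented quirk of this code path: zero removal
#' discards out-of-mask pixels \emph{and} genuinely zero-valued pixels inside
#' the mask, which biases the mean upward whenever true zeros exist.  Set
#' \code{zeroRemoval = FALSE} for the corrected mask-membership mean (mean
#' over all in-mask pixels, zeros included).
#'
#' @param image numeric matrix
#' @param mask logical or 0/1 matrix, same size, with at least one TRUE pixel
#' @param zeroRemoval logical; default TRUE reproduces the historical
#'   behaviour described above.
#' @return mean intensity of the retained pixels
#' @examples
#' maskedMeanZeroRemoved(matrix(1:4, 2, byrow = TRUE),
#'                       matrix(c(1, 0, 0, 1), 2, byrow = TRUE))  # mean(1, 4)
#' @export
maskedMeanZeroRemoved <- function(image, mask, zeroRemoval = TRUE) {
  stopifnot(all(dim(image) == dim(mask)))
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  if (zeroRemoval) {
    prod <- image * mask
    kept <- prod[prod != 0]
    if (length(kept) == 0L)
      stop("all masked products are zero: signal absent in mask")
    mean(kept)
  } else {
    mean(image[mask])
  }
}

#' Per-frame masked intensity statistics
#'
#' For every valid frame and every channel of the ORIGINAL (unfiltered)
#' stack, computes the mean over the full image (\code{I_full}), over the
#' wave minimum (\code{I_min}, complement mask) and over the wave maximum
#' (\code{I_max}, wave mask).
#'
#' @param stack an [ImageStack-class] (the original data, not the filtered
#'   segmentation input)
#' @param masks a [WaveMaskPair-class] with the same frame count
#' @param zeroRemoval passed to [maskedMeanZeroRemoved()]
#' @return a [WaveIntensityStats-class]
#' @export
computeWaveStats <- function(stack, masks, zeroRemoval = TRUE) {
  stopifnot(is(stack, "ImageStack"), is(masks, "WaveMaskPair"))
  nf <- nFrames(stack)
  if (dim(masks@waveMask)[3L] != nf)
    stop("mask frames (", dim(masks@waveMask)[3L],
         ") do not align with stack frames (", nf, ")")
  rows <- list()
  for (f in seq_len(nf)) {
    mvalid <- masks@validFrames[f]
    wmask <- masks@waveMask[, , f]
    for (ch in channelNames(stack)) {
      img <- getFrame(stack, f - 1L, ch)
      ok <- mvalid && any(wmask) && !all(wmask)
      row <- data.frame(frame = f - 1L, channel = ch,
                        I_full = NA_real_, I_min = NA_real_, I_max = NA_real_,
                        valid = ok, stringsAsFactors = FALSE)
      if (ok) {
        imin <- tryCatch(maskedMeanZeroRemoved(img, !wmask, zeroRemoval),
                         error = function(e) NA_real_)
        imax <- tryCatch(maskedMeanZeroRemoved(img, wmask, zeroRemoval),
                         error = function(e) NA_real_)
        if (is.na(imin) || is.na(imax)) row$valid <- FALSE
        row$I_full <- mean(img); row$I_min <- imin; row$I_max <- imax
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  fs <- do.call(rbind, rows)
  if (!any(fs$valid)) stop("no valid frames for intensity statistics")
  new("WaveIntensityStats", frameStats = fs,
      channelNames = channelNames(stack), zeroRemoval = zeroRemoval)
}

#' @rdname WaveIntensityStats-class
#' @export
setMethod("frameStats", "WaveIntensityStats", function(x) x@frameStats)

setMethod("show", "WaveIntensityStats", function(object) {
  fs <- object@frameStats
  cat("WaveIntensityStats: ", length(unique(fs$frame)), " frame(s), channels: ",
      paste(object@channelNames, collapse = ", "),
      if (object@zeroRemoval) " (zero-removal means)" else "", "\n", sep = "")
  for (ch in object@channelNames) {
    sub <- fs[fs$channel == ch & fs$valid, ]
    if (nrow(sub))
      cat(sprintf("  %-10s I_full %.4g  I_min %.4g  I_max %.4g  (means over %d frames)\n",
                  ch, mean(sub$I_full), mean(sub$I_min), mean(sub$I_max), nrow(sub)))
  }
})

#' @rdname contrast
#' @export
setMethod("contrast", "WaveIntensityStats", function(x, channel) {
  fs <- x@frameStats
  sub <- fs[fs$channel == channel, ]
  if (nrow(sub) == 0L) stop("unknown channel '", channel, "'")
  out <- rep(NA_real_, nrow(sub))
  ok <- sub$valid & !is.na(sub$I_max) & sub$I_max > 0
  out[ok] <- (sub$I_min[ok] - sub$I_max[ok]) / sub$I_max[ok]
  out
})

#' Intensity ratio between two conditions
#'
#' Elementwise ratio of the three statistics (full, wave minimum, wave
#' maximum) between a condition with the organizer present and one without,
#' formed on per-condition mean statistics (per-experiment-mean convention;
#' set \code{perFrame = TRUE} for per-frame ratios instead).
#'
#' @param statsWith,statsWithout [WaveIntensityStats-class] objects for the
#'   two conditions
#' @param channel channel name
#' @param perFrame logical; \code{FALSE} (default) ratios the across-frame
#'   means, \code{TRUE} returns per-frame ratios (frame counts must match).
#' @return named numeric \code{c(full, min, max)} (or a data.frame when
#'   \code{perFrame})
#' @export
intensityRatio <- function(statsWith, statsWithout, channel, perFrame = FALSE) {
  pick <- function(s) {
    fs <- frameStats(s)
    fs[fs$channel == channel & fs$valid, ]
  }
  a <- pick(statsWith); b <- pick(statsWithout)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("no valid frames in a condition")
  if (perFrame) {
    if (nrow(a) != nrow(b)) stop("frame counts differ")
    data.frame(frame = a$frame, full = a$I_full / b$I_full,
               min = a$I_min / b$I_min, max = a$I_max / b$I_max)
  } else {
    den <- c(mean(b$I_full), mean(b$I_min), mean(b$I_max))
    if (any(den <= 0)) stop("denominator statistics must be positive")
    stats::setNames(c(mean(a$I_full), mean(a$I_min), mean(a$I_max)) / den,
                    c("full", "min", "max"))
  }
}

#' Normalize intensities to a reference standard
#'
#' Divides measured values by a reference fluorophore intensity and by the
#' fluorescent (labeled) protein fraction: because only the labeled fraction
#' fluoresces, the measured intensity underestimates total protein by that
#' fraction, so the correction is a division.
#'
#' @param values numeric
#' @param referenceValues positive numeric (scalar or same length)
#' @param fluorescentFraction labeled fraction in (0, 1]
#' @return normalized values
#' @export
normalizeToReference <- function(values, referenceValues,
                                 fluorescentFraction = 1) {
  if (any(referenceValues <= 0)) stop("reference must be positive")
  if (fluorescentFraction <= 0 || fluorescentFraction > 1)
    stop("fluorescentFraction must lie in (0, 1]")
  values / referenceValues / fluorescentFraction
}

#' Pool image means across independent experiments
#'
#' Each group holds the per-image means of one independent experiment and
#' condition.  Pooling is unweighted: per-group means first, then the grand
#' mean and the sample standard deviation across groups (SD is reported only
#' for two or more groups, matching the mean-and-SD-of-experiments
#' convention of the field's figures).
#'
#' @param groupedValues list of numeric vectors, one per experiment
#' @return a [PooledResult-class]
#' @examples
#' poolExperiments(list(1, 2, 3))  # grand mean 2, SD 1
#' @export
poolExperiments <- function(groupedValues) {
  if (!is.list(groupedValues) || length(groupedValues) < 1L)
    stop("need at least one group")
  if (any(vapply(groupedValues, length, 1L) == 0L))
    stop("empty group")
  gm <- vapply(groupedValues, function(v) mean(as.numeric(v)), numeric(1))
  new("PooledResult", groupMeans = unname(gm), grandMean = mean(gm),
      sd = if (length(gm) >= 2L) stats::sd(gm) else NA_real_,
      nGroups = length(gm),
      nValues = sum(vapply(groupedValues, length, 1L)))
}

setMethod("show", "PooledResult", function(object) {
  cat("PooledResult: ", object@nGroups, " experiment(s), ", object@nValues,
      " image means\n  grand mean ", signif(object@grandMean, 4),
      if (!is.na(object@sd)) paste0(" +/- ", signif(object@sd, 4), " (SD)"),
      "\n", sep = "")
})

#' Membrane area coverage of a surface-bound species
#'
#' Percent of available membrane area covered by molecules of a given
#' surface density and molecular footprint
#' (1 um^2 = 1e6 nm^2).  For lipid-anchored streptavidin at
#' 6.6e3 molecules/um^2 with a 25 nm^2 footprint this gives 16.5%, i.e.
#' "about 17%" after half-up integer rounding.
#'
#' @param density molecules per square micrometre (non-negative)
#' @param footprint molecular footprint in square nanometres (positive)
#' @return coverage in percent
#' @examples
#' coverageFraction(6.6e3, 25)  # 16.5
#' @export
coverageFraction <- function(density, footprint) {
  if (any(density < 0)) stop("density must be non-negative")
  if (any(footprint <= 0)) stop("footprint must be positive")
  density * footprint / 1e6 * 100
}
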