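# Kymograph extraction and stack-level corrections: per-frame mean
# normalization (dense-bundle preprocessing), histogram-matching bleach
# correction, and a spectral wavelength/velocity estimator.

.bilinear <- function(img, xs, ys) {
  # xs, ys: 0-based pixel coordinates, clamped to the image
  nr <- nrow(img); nc <- ncol(img)
  xs <- pmin(pmax(xs, 0), nc - 1)
  ys <- pmin(pmax(ys, 0), nr - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- xs - x0; fy <- ys - y0
  v00 <- img[cbind(y0 + 1, x0 + 1)]; v01 <- img[cbind(y0 + 1, x1 + 1)]
  v10 <- img[cbind(y1 + 1, x0 + 1)]; v11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Extract a kymograph along a line selection
#'
#' Per frame, intensities are sampled by bilinear interpolation at 1-px steps
#' along the line and averaged over \code{width} perpendicular offsets
#' (centered on the line).
#'
#' @param stack an [ImageStack-class]
#' @param channel channel name or index
#' @param line numeric(4) \code{c(x0, y0, x1, y1)}, 0-based pixel coordinates
#'   of the endpoints (inside the image)
#' @param width perpendicular averaging width in pixels (default 3)
#' @return a [Kymograph-class] with one row per frame
#' @export
extractKymograph <- function(stack, channel, line, width = 3L) {
  stopifnot(is(stack, "ImageStack"), length(line) == 4L, width >= 1L)
  d <- dim(stack@pixels)
  if (any(line[c(1, 3)] < 0) || any(line[c(1, 3)] > d[2L] - 1) ||
      any(line[c(2, 4)] < 0) || any(line[c(2, 4)] > d[1L] - 1))
    stop("line endpoints must lie inside the image")
  dx <- line[3L] - line[1L]; dy <- line[4L] - line[2L]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate line (length 0)")
  nS <- floor(len) + 1L
  tPar <- (0:(nS - 1L)) / len
  ux <- dx / len; uy <- dy / len          # along-line unit vector
  px <- -uy; py <- ux                     # perpendicular unit vector
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  out <- matrix(0, nFrames(stack), nS)
  for (f in seq_len(nFrames(stack))) {
    img <- getFrame(stack, f - 1L, channel)
    acc <- numeric(nS)
    for (o in offs) {
      xs <- line[1L] + tPar * len * ux + o * px
      ys <- line[2L] + tPar * len * uy + o * py
      acc <- acc + .bilinear(img, xs, ys)
    }
    out[f, ] <- acc / width
  }
  new("Kymograph", values = out, line = as.numeric(line),
      spatialStep = pixelSize(stack), timeStep = frameInterval(stack))
}

setMethod("show", "Kymograph", function(object) {
  cat("Kymograph: ", nrow(object@values), " frames x ", ncol(object@values),
      " positions (", object@spatialStep, " um/px, ", object@timeStep,
      " s/frame)\n", sep = "")
})

#' Gaussian blur and per-frame mean normalization
#'
#' Blurs every frame of the given channel and divides it by its own mean,
#' the standard preprocessing for kymographs of dense filament bundles:
#' every output frame has mean 1, and two frames differing only by a global
#' intensity factor become identical.
#'
#' @param stack an [ImageStack-class]
#' @param channel channel name or index
#' @param blurSigma Gaussian blur sigma in pixels (default 2)
#' @return an [ImageStack-class] with the processed channel replacing the
#'   original (other channels untouched)
#' @export
normalizeByFrameMean <- function(stack, channel, blurSigma = 2) {
  stopifnot(is(stack, "ImageStack"))
  ci <- .channelIndex(stack, channel)
  px <- stack@pixels
  for (f in seq_len(nFrames(stack))) {
    img <- gaussianBlur(px[, , ci, f], blurSigma)
    m <- mean(img)
    if (m <= 0) stop("zero-mean frame ", f - 1L, " cannot be normalized")
    px[, , ci, f] <- img / m
  }
  initialize(stack, pixels = px)
}

#' Bleach correction by histogram matching
#'
#' Transforms each frame's intensities by the monotone map that matches its
#' empirical distribution to a reference frame's distribution.  The map is
#' built on 65,536-level empirical CDFs (16-bit native resolution, avoiding
#' the quantization artifacts of 8-bit maps on float data).  Matching a
#' frame to itself is the identity within quantization, and the operation is
#' idempotent.  A constant frame has no defined map and is set to the
#' reference median with a warning.
#'
#' @param stack an [ImageStack-class]
#' @param channel channel name or index
#' @param referenceFrame 0-based index of the reference frame (default 0)
#' @return an [ImageStack-class] with the corrected channel
#' @export
bleachCorrectHistogramMatch <- function(stack, channel, referenceFrame = 0L) {
  stopifnot(is(stack, "ImageStack"))
  ci <- .channelIndex(stack, channel)
  ref <- getFrame(stack, referenceFrame, ci)
  refSorted <- sort(as.numeric(ref))
  nlev <- 65536L
  px <- stack@pixels
  for (f in seq_len(nFrames(stack))) {
    img <- px[, , ci, f]
    lo <- min(img); hi <- max(img)
    if (hi <= lo) {
      warning("constant frame ", f - 1L, "; set to reference median")
      px[, , ci, f] <- stats::median(refSorted)
      next
    }
    lev <- pmin(floor((img - lo) / (hi - lo) * nlev), nlev - 1L)
    counts <- cumsum(tabulate(lev + 1L, nbins = nlev))  # integer CDF
    # map each level to the reference quantile of its CDF value (integer
    # indices avoid off-by-one-level float rounding at tie groups)
    q <- refSorted[pmax(1L, counts)]
    px[, , ci, f] <- matrix(q[lev + 1L], nrow(img), ncol(img))
  }
  initialize(stack, pixels = px)
}

#' Estimate wave wavelength and velocity from a kymograph
#'
#' Finds the dominant spatiotemporal frequency as the peak of the 2-D power
#' spectrum of the mean-subtracted kymograph, excluding the zero-frequency
#' row and column.  Wavelength = spatialStep / spatial frequency; velocity =
#' (temporal frequency / spatial frequency) x spatialStep / timeStep, signed
#' so that a wave moving toward increasing positions has positive velocity.
#' Estimates are reported at spectral-bin resolution.  If no off-origin peak
#' exceeds 3 x the median power, the result is undetermined (\code{NA}s).
#'
#' @param kymo a [Kymograph-class] (or a plain matrix \code{[time, position]}
#'   with \code{spatialStep}/\code{timeStep} supplied)
#' @param spatialStep,timeStep overrides when \code{kymo} is a matrix
#' @return list with \code{wavelength} (um), \code{velocity} (um/s),
#'   \code{wavelengthPx} (px), \code{velocityPxPerFrame} (px/frame)
#' @export
estimateWavelengthVelocity <- function(kymo, spatialStep = NULL,
                                       timeStep = NULL) {
  if (is(kymo, "Kymograph")) {
    K <- kymo@values
    spatialStep <- kymo@spatialStep
    timeStep <- kymo@timeStep
  } else {
    K <- kymo
    if (is.null(spatialStep) || is.null(timeStep))
      stop("spatialStep and timeStep required for a plain matrix")
  }
  Tn <- nrow(K); Nx <- ncol(K)
  P <- Mod(stats::fft(K - mean(K)))^2
  ft <- ifelse(0:(Tn - 1) <= Tn / 2, 0:(Tn - 1), 0:(Tn - 1) - Tn) / Tn
  fx <- ifelse(0:(Nx - 1) <= Nx / 2, 0:(Nx - 1), 0:(Nx - 1) - Nx) / Nx
  keep <- outer(rep(TRUE, Tn), fx > 0)      # positive spatial half-plane
  P0 <- P
  P0[!keep] <- 0
  medP <- stats::median(P[outer(ft != 0, fx != 0)])
  pk <- which(P0 == max(P0), arr.ind = TRUE)[1L, ]
  if (max(P0) <= 0 || max(P0) < 3 * medP)
    return(list(wavelength = NA_real_, velocity = NA_real_,
                wavelengthPx = NA_real_, velocityPxPerFrame = NA_real_))
  fxPk <- fx[pk[2L]]; ftPk <- ft[pk[1L]]
  # K(t, x) ~ exp(2i pi (fx x + ft t)) peaks at ft = -fx v for w(x - v t)
  vPx <- -ftPk / fxPk
  list(wavelength = spatialStep / fxPk,
       velocity = vPx * spatialStep / timeStep,
       wavelengthPx = 1 / fxPk,
       velocityPxPerFrame = vPx)
}

#' Write a kymograph as TIFF and CSV
#'
#' @param kymo a [Kymograph-class]
#' @param tiffPath single-page TIFF output (intensities scaled to [0, 1])
#' @param csvPath optional CSV output (rows = frames)
#' @return invisibly \code{NULL}
#' @export
writeKymograph <- function(kymo, tiffPath, csvPath = NULL) {
  v <- kymo@values
  rng <- range(v)
  sc <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  tiff::writeTIFF(sc, tiffPath, bits.per.sample = 16L)
  if (!is.null(csvPath)) {
    df <- as.data.frame(v)
    names(df) <- paste0("pos_px_", seq_len(ncol(v)) - 1L)
    utils::write.csv(cbind(frame = seq_len(nrow(v)) - 1L, df), csvPath,
                     row.names = FALSE)
  }
  invisible(NULL)
}
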