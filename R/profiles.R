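# Time-averaged axial profile analysis for rod-shaped microcompartments:
# project on the long axis, clip at the compartment edges found on the
# organizer profile, locate the two polar organizer maxima (quartic fit, then
# a local quadratic fit in a 40-px window), project both channels onto the
# organizer-defined unit box, and classify the quadratic curvature.

#' Project an averaged image onto the compartment long axis
#'
#' Mean over the short axis at each long-axis position, for every channel.
#' The ROI is an axis-aligned rectangle in 0-based pixel coordinates with
#' half-open intervals; the long axis is whichever side is longer, so a
#' transposed (vertical) compartment is handled identically.
#'
#' @param avgStack an [ImageStack-class], typically the single-frame result
#'   of [timeAverage()] (the first frame is used)
#' @param roi numeric(4) \code{c(x, y, width, height)}, 0-based, half-open
#' @param source compartment identifier stored in the profile
#' @return an [AxialProfile-class]
#' @export
projectLongAxis <- function(avgStack, roi, source = "compartment") {
  stopifnot(is(avgStack, "ImageStack"), length(roi) == 4L)
  x0 <- as.integer(roi[1L]); y0 <- as.integer(roi[2L])
  w <- as.integer(roi[3L]); h <- as.integer(roi[4L])
  d <- dim(avgStack@pixels)
  if (x0 < 0L || y0 < 0L || x0 + w > d[2L] || y0 + h > d[1L])
    stop("roi outside image")
  horizontal <- w >= h
  if (max(w, h) < 50L) stop("long side of roi must be at least 50 px")
  nch <- nChannels(avgStack)
  vals <- matrix(0, max(w, h), nch)
  for (ch in seq_len(nch)) {
    sub <- avgStack@pixels[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), ch, 1L]
    vals[, ch] <- if (horizontal) colMeans(sub) else rowMeans(sub)
  }
  pos <- (if (horizontal) x0 else y0) + 0:(max(w, h) - 1L)
  new("AxialProfile", positions = as.numeric(pos), values = vals,
      channelNames = channelNames(avgStack), source = source)
}

setMethod("show", "AxialProfile", function(object) {
  cat("AxialProfile '", object@source, "': ", length(object@positions),
      " positions, channels: ", paste(object@channelNames, collapse = ", "),
      "\n", sep = "")
})

.movingAverage <- function(v, width) {
  if (width <= 1L) return(v)
  as.numeric(stats::filter(v, rep(1 / width, width), sides = 2)) -> s
  s[is.na(s)] <- v[is.na(s)]   # keep raw values where the window clips
  s
}

#' Clip an axial profile at the compartment edges
#'
#' Edges are located on the organizer profile: the left edge is the first
#' position where the signal exceeds (flank background + k x flank SD) while
#' the first spatial derivative (central difference after light smoothing)
#' is positive; the right edge is symmetric.  Compartments without such
#' crossings (e.g. no oscillating organizer) are rejected, mirroring the
#' manual exclusion of compartments without oscillations.
#'
#' @param profile an [AxialProfile-class]
#' @param organizerChannel channel used for edge detection
#' @param backgroundWindow number of flank positions used to estimate the
#'   background level and SD (default 10)
#' @param k threshold in background SDs (default 3)
#' @param smoothWidth moving-average width before differentiation (default 3)
#' @return the clipped [AxialProfile-class]
#' @export
detectEdgesAndClip <- function(profile, organizerChannel = "organizer",
                               backgroundWindow = 10L, k = 3,
                               smoothWidth = 3L) {
  ch <- match(organizerChannel, profile@channelNames)
  if (is.na(ch)) stop("unknown organizer channel")
  v <- profile@values[, ch]
  n <- length(v)
  if (n < 3L * backgroundWindow) stop("profile too short for edge detection")
  bgL <- v[seq_len(backgroundWindow)]
  bgR <- v[(n - backgroundWindow + 1L):n]
  bg <- mean(c(bgL, bgR))
  sdBg <- stats::sd(c(bgL, bgR))
  eps <- 1e-9 * max(abs(v), 1)
  thr <- bg + k * max(sdBg, eps)
  s <- .movingAverage(v, smoothWidth)
  deriv <- c(s[2L] - s[1L], (s[3:n] - s[1:(n - 2L)]) / 2, s[n] - s[n - 1L])
  left <- which(v > thr & deriv > 0)
  right <- which(v > thr & deriv < 0)
  if (length(left) == 0L || length(right) == 0L)
    stop("no compartment edge found (profile rejected; ",
         "compartment without organizer signal)")
  li <- min(left); ri <- max(right)
  if (ri - li < 2L) stop("degenerate clip region")
  new("AxialProfile", positions = profile@positions[li:ri],
      values = profile@values[li:ri, , drop = FALSE],
      channelNames = profile@channelNames, source = profile@source)
}

#' Locate the two polar organizer maxima
#'
#' Two-step localization on the clipped organizer profile: (1) a
#' least-squares quartic over the whole profile provides rough estimates as
#' its two interior local maxima; (2) a least-squares parabola over a window
#' (default 40 px) centered on each estimate refines the maximum as the
#' parabola vertex, clamped to the window.  If a window's parabola opens
#' upward, the window's discrete argmax is used instead with a warning.
#'
#' @param profile a clipped [AxialProfile-class]
#' @param organizerChannel channel holding the organizer signal
#' @param window refinement window width in pixels (default 40; two disjoint
#'   windows must fit, so the profile must be longer than 2 x window)
#' @return numeric(2), the refined maxima positions (px), increasing
#' @export
locatePolarMaxima <- function(profile, organizerChannel = "organizer",
                              window = 40L) {
  ch <- match(organizerChannel, profile@channelNames)
  if (is.na(ch)) stop("unknown organizer channel")
  xs <- profile@positions
  v <- profile@values[, ch]
  if (length(xs) <= 2L * window)
    stop("clipped profile must be longer than ", 2L * window, " px")
  # stage 1: quartic fit, interior maxima from the cubic derivative roots
  xc <- xs - mean(xs)
  fit <- stats::lm(v ~ poly(xc, 4, raw = TRUE))
  b <- stats::coef(fit)                      # b0 + b1 x + ... + b4 x^4
  dcoef <- c(b[2L], 2 * b[3L], 3 * b[4L], 4 * b[5L])  # derivative coeffs
  roots <- polyroot(dcoef)
  re <- Re(roots)[abs(Im(roots)) < 1e-6 * max(abs(roots), 1)]
  re <- re[re > min(xc) & re < max(xc)]
  curv <- function(x) 2 * b[3L] + 6 * b[4L] * x + 12 * b[5L] * x^2
  maxima <- sort(re[curv(re) < 0])
  if (length(maxima) < 2L)
    stop("quartic fit has fewer than two interior maxima; ",
         "compartment rejected")
  rough <- range(maxima) + mean(xs)
  # stage 2: quadratic refinement in a window around each rough estimate
  refine <- function(x0) {
    sel <- which(xs >= x0 - window / 2 & xs <= x0 + window / 2)
    xw <- xs[sel]; vw <- v[sel]
    q <- stats::coef(stats::lm(vw ~ xw + I(xw^2)))
    if (!is.finite(q[3L]) || q[3L] >= 0) {
      warning("refinement parabola opens upward; using discrete argmax")
      return(xw[which.max(vw)])
    }
    min(max(-q[2L] / (2 * q[3L]), min(xw)), max(xw))
  }
  sort(c(refine(rough[1L]), refine(rough[2L])))
}

#' Project a profile onto the organizer-defined unit box
#'
#' Linearly maps \code{[xLeft, xRight]} (the organizer's polar maxima) to
#' \code{[-0.5, 0.5]}, resamples every channel by linear interpolation onto a
#' fixed grid and divides each channel by its own mean over the box.  Both
#' spectral channels are remapped with the SAME organizer-defined box.
#'
#' @param profile an [AxialProfile-class]
#' @param xLeft,xRight box edges in profile position units, inside the
#'   profile, \code{xLeft < xRight}
#' @param gridSize number of resampling points (default 101)
#' @return a [UnitBoxProfile-class] without fits (see [fitQuadratic()])
#' @export
projectUnitBox <- function(profile, xLeft, xRight, gridSize = 101L) {
  stopifnot(xLeft < xRight)
  xs <- profile@positions
  if (xLeft < min(xs) || xRight > max(xs))
    stop("box edges must lie inside the clipped profile")
  grid <- seq(-0.5, 0.5, length.out = gridSize)
  src <- xLeft + (grid + 0.5) * (xRight - xLeft)
  vals <- matrix(0, gridSize, ncol(profile@values))
  for (ch in seq_len(ncol(profile@values))) {
    y <- stats::approx(xs, profile@values[, ch], xout = src)$y
    m <- mean(y)
    if (m == 0) stop("zero-mean channel on the unit box")
    vals[, ch] <- y / m
  }
  new("UnitBoxProfile", x = grid, values = vals,
      channelNames = profile@channelNames,
      fits = data.frame(), boxEdges = c(xLeft, xRight))
}

#' Fit the unit-box quadratic and classify curvature
#'
#' Least-squares fit of \eqn{f(x) = a x^2 + b} on the unit-box grid for every
#' channel.  Reports \code{a}, \code{b}, the overall curvature \code{2a} and
#' the profile depth \code{a/4} (= f(+-0.5) - f(0)); on a unit box these
#' differ only by constant prefactors.  Classification: \code{a < -tolerance}
#' is \code{center_enriched}, \code{|a| <= tolerance} \code{homogeneous},
#' \code{a > tolerance} \code{polar}.
#'
#' @param unitProfile a [UnitBoxProfile-class] (at least 10 grid points)
#' @param tolerance near-zero band for the homogeneous class (default 0.15)
#' @return the [UnitBoxProfile-class] with its \code{fits} slot filled
#' @export
fitQuadratic <- function(unitProfile, tolerance = 0.15) {
  x <- unitProfile@x
  if (length(x) < 10L) stop("need at least 10 samples for the quadratic fit")
  if (max(x) - min(x) <= 0) stop("degenerate grid")
  rows <- lapply(seq_len(ncol(unitProfile@values)), function(ch) {
    y <- unitProfile@values[, ch]
    co <- stats::coef(stats::lm(y ~ I(x^2)))
    a <- unname(co[2L]); b <- unname(co[1L])
    data.frame(channel = unitProfile@channelNames[ch], a = a, b = b,
               curvature = 2 * a, depth = a / 4,
               classification = classifyProfile(a, tolerance),
               stringsAsFactors = FALSE)
  })
  unitProfile@fits <- do.call(rbind, rows)
  unitProfile
}

#' Classify a unit-box curvature coefficient
#'
#' @param a quadratic coefficient of the unit-box fit
#' @param tolerance positive near-zero band
#' @return \code{"center_enriched"} (a < -tolerance), \code{"homogeneous"}
#'   (|a| <= tolerance) or \code{"polar"} (a > tolerance)
#' @export
classifyProfile <- function(a, tolerance = 0.15) {
  stopifnot(tolerance > 0)
  ifelse(a < -tolerance, "center_enriched",
         ifelse(a > tolerance, "polar", "homogeneous"))
}

setMethod("show", "UnitBoxProfile", function(object) {
  cat("UnitBoxProfile: ", length(object@x), " grid points, box [",
      signif(object@boxEdges[1L], 5), ", ", signif(object@boxEdges[2L], 5),
      "] px\n", sep = "")
  if (nrow(object@fits)) {
    f <- object@fits
    for (i in seq_len(nrow(f)))
      cat(sprintf("  %-10s a = %+.3f  b = %.3f  curvature = %+.3f  depth = %+.3f  [%s]\n",
                  f$channel[i], f$a[i], f$b[i], f$curvature[i], f$depth[i],
                  f$classification[i]))
  }
})

#' Full compartment-profile analysis of a time-lapse stack
#'
#' Convenience chain: [timeAverage()] -> [projectLongAxis()] ->
#' [detectEdgesAndClip()] -> [locatePolarMaxima()] -> [projectUnitBox()] ->
#' [fitQuadratic()].
#'
#' @param stack an [ImageStack-class] of an oscillating compartment
#' @param roi compartment rectangle \code{c(x, y, width, height)}, 0-based
#' @param organizerChannel organizer channel name
#' @param tolerance classification tolerance (see [classifyProfile()])
#' @param window maxima-refinement window (px)
#' @param gridSize unit-box resampling grid size
#' @param ... further arguments for [detectEdgesAndClip()]
#' @return a fitted [UnitBoxProfile-class]
#' @export
analyzeCompartment <- function(stack, roi, organizerChannel = "organizer",
                               tolerance = 0.15, window = 40L,
                               gridSize = 101L, ...) {
  avg <- timeAverage(stack)
  prof <- projectLongAxis(avg, roi)
  clipped <- detectEdgesAndClip(prof, organizerChannel, ...)
  mx <- locatePolarMaxima(clipped, organizerChannel, window = window)
  ub <- projectUnitBox(clipped, mx[1L], mx[2L], gridSize = gridSize)
  fitQuadratic(ub, tolerance = tolerance)
}
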