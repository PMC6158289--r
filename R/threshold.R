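# Automatic thresholding on a 256-bin histogram over the per-image min-max
# range, matching the common 8-bit implementations these methods are known
# from.  Both functions return the threshold mapped back to intensity units;
# pixels strictly above the threshold belong to the wave (ties go to the
# complement).

.histogram256 <- function(image) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: no threshold exists")
  # bin index 0..255; top value lands in bin 255
  b <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  counts <- tabulate(b + 1L, nbins = 256L)
  list(counts = counts, lo = lo, hi = hi)
}

# threshold between bin t and t+1 (t in 0..254), mapped to intensity units
.binToIntensity <- function(t, h) h$lo + (t + 1) / 256 * (h$hi - h$lo)

#' Huang fuzzy thresholding
#'
#' Returns the threshold minimizing Huang's measure of fuzziness (Shannon
#' entropy of the fuzzy membership to the two classes) over a 256-bin
#' histogram of the min-max scaled image.  The result is mapped back to
#' intensity units; equal-minimum candidates are resolved to the middle of
#' the tying range (deterministic).  Invariant, up to the same affine map,
#' under affine intensity rescaling.
#'
#' @param image numeric matrix with at least two distinct values
#' @return threshold in intensity units; pixels \code{> threshold} form the
#'   wave mask
#' @references Huang & Wang (1995) Image thresholding by minimizing the
#'   measures of fuzziness. Pattern Recognition 28, 41-51.
#' @export
thresholdHuang <- function(image) {
  h <- .histogram256(image)
  cnt <- h$counts
  g <- 0:255
  W  <- cumsum(cnt)         # class-0 pixel count up to bin t
  S  <- cumsum(cnt * g)     # class-0 intensity sum
  n  <- W[256L]; Stot <- S[256L]
  C  <- 255                 # membership scale: full histogram range
  ts <- 0:254
  E <- vapply(ts, function(t) {
    w0 <- W[t + 1L]; w1 <- n - w0
    mu0 <- if (w0 > 0) S[t + 1L] / w0 else 0
    mu1 <- if (w1 > 0) (Stot - S[t + 1L]) / w1 else 0
    mem <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    s <- -mem * log(mem) - (1 - mem) * log(1 - mem)
    s[!is.finite(s)] <- 0   # mem == 1 contributes zero entropy
    sum(cnt * s)
  }, numeric(1))
  best <- ts[E <= min(E) + 1e-12 * max(abs(E), 1)]
  .binToIntensity(stats::median(best), h)
}

#' Li minimum cross-entropy thresholding
#'
#' Li & Lee's iterative minimum cross-entropy method on the 256-bin
#' histogram: starting from the image mean, the threshold is updated as
#' \eqn{t' = (m_0 - m_1) / (\log m_0 - \log m_1)} with \eqn{m_0, m_1} the
#' means of the two classes, until successive thresholds differ by less than
#' half a bin.
#'
#' @param image numeric matrix with at least two distinct values
#' @param maxIter iteration cap (the fixed point converges in well under 64
#'   steps on 256-bin histograms)
#' @return threshold in intensity units, with the number of fixed-point
#'   iterations attached as attribute \code{"iterations"}
#' @references Li & Tam (1998) An iterative algorithm for minimum cross
#'   entropy thresholding. Pattern Recognition Letters 19, 771-776.
#' @export
thresholdLi <- function(image, maxIter = 64L) {
  h <- .histogram256(image)
  cnt <- h$counts
  g <- 0:255 + 0.5          # positive bin centers so logs are defined
  t <- sum(cnt * g) / sum(cnt)
  iters <- 0L
  for (i in seq_len(maxIter)) {
    iters <- i
    below <- g <= t
    w0 <- sum(cnt[below]); w1 <- sum(cnt[!below])
    if (w0 == 0 || w1 == 0) break
    m0 <- sum(cnt[below] * g[below]) / w0
    m1 <- sum(cnt[!below] * g[!below]) / w1
    tNew <- (m0 - m1) / (log(m0) - log(m1))
    if (!is.finite(tNew)) break
    done <- abs(tNew - t) < 0.5
    t <- tNew
    if (done) break
  }
  # t is in bin-center units; map back through the bin grid
  structure(h$lo + t / 256 * (h$hi - h$lo), iterations = iters)
}
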