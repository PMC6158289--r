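# Spatial filters used by the segmentation chain.  Both filters use
# whole-sample reflection at the image border (pixel sequence ... 2,1,0,1,2);
# the Gaussian blur is built as a dense separable operator so that sigma may
# exceed the image size (the flat-field correction uses sigma = 75 px on
# images of comparable extent), with reflection folded as many times as
# needed.

# fold 0-based indices into [0, n-1] by whole-sample reflection
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n - 2L
  r <- ((i %% p) + p) %% p
  ifelse(r >= n, p - r, r)
}

# dense 1-D Gaussian convolution operator with reflective boundary
.gaussOperator <- function(n, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  A <- matrix(0, n, n)
  idx <- seq_len(n) - 1L
  for (j in seq_along(k)) {
    cols <- .reflectIndex(idx + (j - 1L - radius), n) + 1L
    A[cbind(seq_len(n), cols)] <- A[cbind(seq_len(n), cols)] + k[j]
  }
  A
}

#' Gaussian blur with reflective boundaries
#'
#' Separable Gaussian convolution; the image border is extended by
#' whole-sample reflection, so a constant image is returned unchanged and
#' the kernel may be (much) larger than the image.
#'
#' @param image numeric matrix
#' @param sigma Gaussian standard deviation in pixels
#' @return blurred matrix of the same size
#' @export
gaussianBlur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  Ar <- .gaussOperator(nrow(image), sigma)
  Ac <- .gaussOperator(ncol(image), sigma)
  Ar %*% image %*% t(Ac)
}

#' Median filter with a disc structuring element
#'
#' Each pixel is replaced by the median over a disc of the given radius
#' (offsets with \code{dx^2 + dy^2 <= radius^2}); edges are handled by
#' reflection.  This is the despeckling step applied to the organizer
#' channel before thresholding (radius 3-6 px typical; default 4 in
#' [segmentWave()]).
#'
#' @param image numeric matrix
#' @param radius disc radius in pixels, at least 1
#' @return filtered matrix
#' @export
medianFilterDisc <- function(image, radius) {
  stopifnot(is.matrix(image))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be at least 1")
  if (radius > min(dim(image)) / 2)
    stop("radius (", radius, ") larger than half the image side")
  off <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  nr <- nrow(image); nc <- ncol(image)
  ri <- .reflectIndex(outer(0:(nr - 1), off$dy, `+`), nr) + 1L   # [nr, noff]
  ci <- .reflectIndex(outer(0:(nc - 1), off$dx, `+`), nc) + 1L
  stackv <- matrix(0, nr * nc, nrow(off))
  for (j in seq_len(nrow(off)))
    stackv[, j] <- image[ri[, j], ci[, j]]
  matrix(matrixStats::rowMedians(stackv), nr, nc)
}

#' Pseudo-flat-field correction
#'
#' Removes uneven illumination by dividing the image pixelwise by a
#' Gaussian-blurred copy of itself (sigma = \code{radius}), then multiplying
#' by the mean of the blurred copy so the output preserves the input's
#' global intensity scale (mean-preserving convention).
#'
#' @param image numeric matrix with at least one positive pixel
#' @param radius blur sigma in pixels (75 px is the conventional choice for
#'   full-field wave images)
#' @return corrected matrix, same global mean as the input (up to the
#'   correlation between image and illumination estimate)
#' @export
pseudoFlatFieldCorrect <- function(image, radius) {
  stopifnot(is.matrix(image), radius >= 1)
  if (max(image) <= 0) stop("image must contain at least one positive pixel")
  bg <- gaussianBlur(image, radius)
  if (any(bg <= 0)) {
    warning("blurred copy contains non-positive values; applying small floor")
    floorv <- 1e-12 * max(bg)
    bg <- pmax(bg, if (floorv > 0) floorv else 1e-12)
  }
  image / bg * mean(bg)
}
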