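# Small scene builders shared across tests.  Wavelengths/sizes are scaled
# down from the defaults to keep runs fast; the relationships under test do
# not depend on absolute scene size.

smallPlanar <- function(..., nFrames = 6L, wavelength = 32, waveSpeed = 8,
                        rngSeed = 1L) {
  sceneParams("planar", nFrames = nFrames, wavelength = wavelength,
              waveSpeed = waveSpeed, rngSeed = rngSeed, ...)
}

squarePulsePlanar <- function(kappa, rngSeed = 1L, ...) {
  smallPlanar(kappa = kappa, riseFrac = 0, fallFrac = 0, rngSeed = rngSeed, ...)
}

# WaveMaskPair built from a ground-truth mask (bypasses segmentation)
truthMasks <- function(scene) {
  tm <- trueMask(groundTruth(scene))
  new("WaveMaskPair", waveMask = tm, thresholdMethod = "huang",
      thresholdValues = rep(NA_real_, dim(tm)[3]),
      validFrames = rep(TRUE, dim(tm)[3]), parameters = list())
}

# brute-force masked mean with the zero-removal quirk, written as a plain
# double loop so it is independent of the vectorized implementation
bruteForceMaskedMean <- function(image, mask) {
  vals <- c()
  for (i in seq_len(nrow(image)))
    for (j in seq_len(ncol(image))) {
      p <- image[i, j] * (if (mask[i, j]) 1 else 0)
      if (p != 0) vals <- c(vals, p)
    }
  mean(vals)
}

# spatial variance of each frame of a [row, col, frame] array
frameVariances <- function(a) apply(a, 3, function(m) stats::var(as.numeric(m)))

compartmentRoi <- function(params) {
  c(10, 2, params@width - 20, params@height - 4)
}
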