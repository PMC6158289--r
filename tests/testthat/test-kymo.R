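test_that("kymograph sampling follows the line and averaging width", {
  img <- matrix(rep(1:40, each = 20), 20, 40)      # columns ramp 1..40
  px <- array(img, c(20, 40, 1, 3))
  st <- ImageStack(px)
  # static stack: all rows identical
  k <- extractKymograph(st, 1, c(2, 10, 37, 10), width = 3)
  expect_equal(k@values[1, ], k@values[3, ])
  # width 1 on an axis-aligned line equals the raw pixel row
  k1 <- extractKymograph(st, 1, c(0, 5, 39, 5), width = 1)
  expect_equal(k1@values[1, ], as.numeric(img[6, ]))
  expect_error(extractKymograph(st, 1, c(5, 5, 5, 5)), "degenerate")
  expect_error(extractKymograph(st, 1, c(-1, 5, 39, 5)), "inside")
})

test_that("frame-mean normalization yields unit-mean frames", {
  set.seed(5)
  px <- array(runif(32 * 32 * 1 * 3, 10, 50), c(32, 32, 1, 3))
  px[, , 1, 2] <- px[, , 1, 1] * 3.7          # global factor only
  st <- ImageStack(px)
  nm <- normalizeByFrameMean(st, 1, blurSigma = 2)
  for (f in 0:2)
    expect_equal(mean(getFrame(nm, f, 1)), 1, tolerance = 1e-9)
  expect_equal(getFrame(nm, 1, 1), getFrame(nm, 0, 1), tolerance = 1e-12)
  # constant frames map to all-ones
  pc <- array(4, c(16, 16, 1, 2))
  nc2 <- normalizeByFrameMean(ImageStack(pc), 1)
  expect_equal(getFrame(nc2, 0, 1), matrix(1, 16, 16))
})

test_that("histogram matching inverts pure bleaching", {
  set.seed(6)
  ref <- matrix(runif(48 * 48, 50, 200), 48, 48)
  px <- array(0, c(48, 48, 1, 3))
  px[, , 1, 1] <- ref
  px[, , 1, 2] <- ref * 0.5                  # pure intensity loss
  px[, , 1, 3] <- ref * 0.25
  st <- ImageStack(px)
  bc <- bleachCorrectHistogramMatch(st, 1, 0)
  for (f in 1:2) {
    corrected <- getFrame(bc, f, 1)
    expect_lt(abs(mean(corrected) - mean(ref)) / mean(ref), 0.01)
    ks <- suppressWarnings(stats::ks.test(as.numeric(corrected),
                                          as.numeric(ref))$statistic)
    expect_lt(unname(ks), 0.02)
  }
  # the reference maps to itself within quantization
  expect_equal(getFrame(bc, 0, 1), ref, tolerance = 1e-4)
  # idempotency
  bc2 <- bleachCorrectHistogramMatch(bc, 1, 0)
  expect_equal(bc2@pixels, bc@pixels, tolerance = 1e-9)
})

test_that("constant frames fall back to the reference median", {
  px <- array(0, c(16, 16, 1, 2))
  px[, , 1, 1] <- matrix(1:256 / 8, 16)
  px[, , 1, 2] <- 3
  st <- ImageStack(px)
  expect_warning(bc <- bleachCorrectHistogramMatch(st, 1, 0), "constant")
  expect_equal(getFrame(bc, 1, 1),
               matrix(median(px[, , 1, 1]), 16, 16))
})

test_that("spectral estimator recovers wavelength and velocity within 5%", {
  p <- sceneParams("planar", width = 200L, nFrames = 100L, wavelength = 50,
                   waveSpeed = 0.5, pixelSize = 0.8, frameInterval = 2,
                   rngSeed = 2L)
  sc <- generatePlanarScene(p)
  k <- extractKymograph(imageStack(sc), "organizer",
                        c(0, 64, 199, 64), width = 3)
  est <- estimateWavelengthVelocity(k)
  expect_lt(abs(est$wavelengthPx - 50) / 50, 0.05)
  expect_lt(abs(est$velocityPxPerFrame - 0.5) / 0.5, 0.05)
  expect_equal(est$wavelength, est$wavelengthPx * 0.8)
  expect_equal(est$velocity, est$velocityPxPerFrame * 0.8 / 2)

  # invariance to global intensity scaling
  est2 <- estimateWavelengthVelocity(k@values * 7, spatialStep = 0.8,
                                     timeStep = 2)
  expect_equal(est2$wavelengthPx, est$wavelengthPx)
  expect_equal(est2$velocityPxPerFrame, est$velocityPxPerFrame)

  # static stripes: zero velocity
  kS <- matrix(rep(sin((0:199) / 5), each = 64), 64, 200, byrow = FALSE)
  kS <- matrix(rep(sin((0:199) / 5), 64), 64, 200, byrow = TRUE)
  estS <- estimateWavelengthVelocity(kS, spatialStep = 1, timeStep = 1)
  expect_equal(estS$velocityPxPerFrame, 0)

  # reversing time negates the velocity
  kR <- k; kR@values <- k@values[nrow(k@values):1, ]
  estR <- estimateWavelengthVelocity(kR)
  expect_equal(estR$velocityPxPerFrame, -est$velocityPxPerFrame)

  # a featureless (constant) kymograph is reported undetermined
  estN <- estimateWavelengthVelocity(matrix(5, 64, 64),
                                     spatialStep = 1, timeStep = 1)
  expect_true(is.na(estN$wavelength))
})
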