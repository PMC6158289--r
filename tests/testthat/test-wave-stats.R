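test_that("zero-removal masked mean reproduces the documented code path", {
  img <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(maskedMeanZeroRemoved(img, matrix(1, 2, 2)), 2.5)
  expect_equal(maskedMeanZeroRemoved(img, matrix(c(1, 0, 0, 1), 2, byrow = TRUE)),
               2.5)
  imgZ <- matrix(c(0, 2, 3, 4), 2, 2, byrow = TRUE)
  maskTop <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  # the genuine zero inside the mask is dropped by the historical rule ...
  expect_equal(maskedMeanZeroRemoved(imgZ, maskTop), 2.0)
  # ... and kept by the corrected mask-membership mean
  expect_equal(maskedMeanZeroRemoved(imgZ, maskTop, zeroRemoval = FALSE), 1.0)
  expect_error(maskedMeanZeroRemoved(img, matrix(0, 2, 2)), "empty")
  expect_error(maskedMeanZeroRemoved(img * 0, matrix(1, 2, 2)), "zero")
})

test_that("masked mean agrees exactly with a brute-force loop", {
  set.seed(13)
  for (i in 1:200) {
    img <- matrix(sample(0:8, 256, replace = TRUE), 16, 16)
    mask <- matrix(sample(c(TRUE, FALSE), 256, replace = TRUE), 16, 16)
    if (!any(mask) || all(img[mask] == 0)) next
    expect_identical(maskedMeanZeroRemoved(img, mask),
                     bruteForceMaskedMean(img, mask))
  }
})

test_that("wave statistics recover the generator's closed forms", {
  sc <- generatePlanarScene(squarePulsePlanar(kappa = 0.5))
  stats <- computeWaveStats(imageStack(sc), truthMasks(sc))
  fs <- frameStats(stats)
  cargo <- fs[fs$channel == "cargo", ]
  expect_equal(cargo$I_min, rep(100, nrow(cargo)))
  expect_equal(cargo$I_max, rep(50, nrow(cargo)))
  expect_equal(contrast(stats, "cargo"), rep(1, nrow(cargo)))
  # the organizer on its own masks has negative contrast
  expect_true(all(contrast(stats, "organizer") < 0))
})

test_that("statistics are linear in intensity and contrast is scale-free", {
  sc <- generatePlanarScene(smallPlanar(kappa = 0.3, nFrames = 4L))
  st <- imageStack(sc)
  masks <- segmentWave(st)
  s1 <- computeWaveStats(st, masks)
  st2 <- ImageStack(st@pixels * 2, channelNames = channelNames(st))
  s2 <- computeWaveStats(st2, segmentWave(st2))
  for (col in c("I_full", "I_min", "I_max"))
    expect_equal(frameStats(s2)[[col]], 2 * frameStats(s1)[[col]])
  expect_equal(contrast(s2, "cargo"), contrast(s1, "cargo"))
})

test_that("uniform channels give identical full/min/max means", {
  px <- array(0, c(16, 16, 2, 2))
  px[, , 1, ] <- rep(c(10, 80), each = 128)    # binary organizer
  px[, , 2, ] <- 42
  st <- ImageStack(px, channelNames = c("organizer", "cargo"))
  stats <- computeWaveStats(st, segmentWave(st, medianRadius = 1,
                                            flatfieldRadius = 8))
  fs <- frameStats(stats)
  cargo <- fs[fs$channel == "cargo" & fs$valid, ]
  expect_equal(cargo$I_full, cargo$I_min)
  expect_equal(cargo$I_full, cargo$I_max)
})

test_that("full-image mean is the area-weighted mean of the masked means", {
  sc <- generatePlanarScene(smallPlanar(kappa = 0.4, nFrames = 5L,
                                        rngSeed = 7L))
  st <- imageStack(sc)
  masks <- segmentWave(st)
  stats <- computeWaveStats(st, masks, zeroRemoval = FALSE)
  fs <- frameStats(stats)
  for (f in unique(fs$frame)) {
    wm <- waveMask(masks)[, , f + 1]
    area <- mean(wm)
    for (ch in c("organizer", "cargo")) {
      row <- fs[fs$frame == f & fs$channel == ch, ]
      if (!row$valid) next
      expect_equal(row$I_full, area * row$I_max + (1 - area) * row$I_min,
                   tolerance = 1e-12)
    }
  }
})

test_that("intensity ratios compare conditions against the kappa = 0 baseline", {
  pOn <- squarePulsePlanar(kappa = 0.5)
  pOff <- squarePulsePlanar(kappa = 0)
  scOn <- generatePlanarScene(pOn)
  scOff <- generatePlanarScene(pOff)
  sOn <- computeWaveStats(imageStack(scOn), truthMasks(scOn))
  sOff <- computeWaveStats(imageStack(scOff), truthMasks(scOn))
  r <- intensityRatio(sOn, sOff, "cargo")
  # full-image ratio = 1 - kappa * <Dn>, from the generator's clean fields
  Dn <- trueMask(groundTruth(scOn)) * 1   # square pulse: Dn is binary
  expect_equal(unname(r["full"]), 1 - 0.5 * mean(Dn), tolerance = 1e-10)
  expect_equal(unname(r["min"]), 1, tolerance = 1e-10)
  expect_equal(unname(r["max"]), 0.5, tolerance = 1e-10)
  # identical conditions give unit ratios
  r0 <- intensityRatio(sOn, sOn, "cargo")
  expect_equal(unname(r0), c(1, 1, 1))
})

test_that("anchored scenes preserve the full-image intensity ratio", {
  pOn <- sceneParams("planar", cargoMode = "anchored", nFrames = 60L,
                     waveSpeed = 1, rngSeed = 3L)
  scOn <- generatePlanarScene(pOn)
  fullOn <- mean(cleanCargo(groundTruth(scOn))[, , 60])
  expect_equal(fullOn / pOn@cargoBaseline, 1, tolerance = 1e-9)
})

test_that("reference normalization divides by standard and labeled fraction", {
  expect_equal(normalizeToReference(1, 1, 1), 1)
  expect_equal(normalizeToReference(10, 5, 0.5), 4)
  v <- c(3.2, 7.7)
  expect_equal(normalizeToReference(v, 2, 0.8) * 2 * 0.8, v)
  expect_error(normalizeToReference(1, 0), "positive")
  expect_error(normalizeToReference(1, 1, 0), "fluorescentFraction")
})

test_that("experiment pooling uses unweighted per-experiment means", {
  pr <- poolExperiments(list(1, 2, 3))
  expect_equal(pr@grandMean, 2)
  expect_equal(pr@sd, 1)
  expect_equal(pr@nGroups, 3L)

  one <- poolExperiments(list(c(4, 6)))
  expect_equal(one@grandMean, 5)
  expect_true(is.na(one@sd))

  g <- list(c(1, 5), c(2, 2, 2), 7)
  p1 <- poolExperiments(g)
  p2 <- poolExperiments(g[c(3, 1, 2)])
  expect_equal(p1@grandMean, p2@grandMean)
  expect_equal(p1@sd, p2@sd)
  expect_error(poolExperiments(list(numeric(0))), "empty")
})

test_that("membrane coverage arithmetic matches the worked example", {
  expect_equal(coverageFraction(6.6e3, 25), 16.5)
  expect_equal(floor(coverageFraction(6.6e3, 25) + 0.5), 17)  # half-up
  expect_equal(coverageFraction(0, 25), 0)
  expect_equal(coverageFraction(4e4, 25), 100)
  expect_error(coverageFraction(-1, 25), "non-negative")
})
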