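test_that("identical parameters and seed give bit-identical stacks", {
  p <- withDefaultNoise(smallPlanar(rngSeed = 5L))
  s1 <- generatePlanarScene(p)
  s2 <- generatePlanarScene(p)
  expect_identical(imageStack(s1)@pixels, imageStack(s2)@pixels)
})

test_that("uncoupled noiseless cargo stays constant at baseline", {
  p <- smallPlanar(kappa = 0, cargoMode = "transient")
  sc <- generatePlanarScene(p)
  cargo <- cleanCargo(groundTruth(sc))
  expect_equal(max(abs(cargo - p@cargoBaseline)), 0)
  # and the recorded stack equals the clean fields exactly with all noise off
  expect_equal(getFrame(imageStack(sc), 2, "cargo"), cargo[, , 3])
  expect_equal(getFrame(imageStack(sc), 2, "organizer"),
               cleanOrganizer(groundTruth(sc))[, , 3])
})

test_that("noise layers are individually applied in the documented order", {
  base <- smallPlanar(kappa = 0.3, rngSeed = 9L)
  clean <- cleanCargo(groundTruth(generatePlanarScene(base)))

  pb <- base; pb@bleachTau <- 50
  scb <- generatePlanarScene(pb)
  expect_equal(getFrame(imageStack(scb), 3, "cargo"),
               clean[, , 4] * exp(-3 / 50))
  expect_equal(bleachFactors(groundTruth(scb)), exp(-(0:5) / 50))

  pi_ <- base; pi_@illuminationSigma <- 100
  sci <- generatePlanarScene(pi_)
  expect_equal(getFrame(imageStack(sci), 0, "cargo"),
               clean[, , 1] * illuminationField(groundTruth(sci)))

  pr <- base; pr@readNoiseSigma <- 2
  scr <- generatePlanarScene(pr)
  resid <- getFrame(imageStack(scr), 0, "cargo") - clean[, , 1]
  expect_gt(stats::sd(resid), 1.5)
  expect_lt(stats::sd(resid), 2.5)
})

test_that("anchored cargo conserves total mass to 1e-6 relative", {
  for (mode in c("planar", "collision", "compartment")) {
    p <- if (mode == "compartment")
      sceneParams(mode, cargoMode = "anchored", nFrames = 40L, rngSeed = 2L)
    else
      sceneParams(mode, cargoMode = "anchored", nFrames = 20L,
                  wavelength = 32, waveSpeed = 2, rngSeed = 2L)
    sc <- switch(mode,
                 planar = generatePlanarScene(p),
                 collision = generateCollisionScene(p),
                 compartment = generateCompartmentScene(p))
    mass <- totalCargoMass(groundTruth(sc))
    expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)
  }
})

test_that("transient square-pulse scenes satisfy the closed-form contrast", {
  sc <- generatePlanarScene(squarePulsePlanar(kappa = 0.5))
  gt <- groundTruth(sc)
  f <- 3L
  img <- getFrame(imageStack(sc), f, "cargo")
  tm <- trueMask(gt)[, , f + 1L]
  iMin <- maskedMeanZeroRemoved(img, !tm)
  iMax <- maskedMeanZeroRemoved(img, tm)
  expect_equal((iMin - iMax) / iMax, 1.0)           # kappa/(1-kappa)
  expect_equal(iMin, 100); expect_equal(iMax, 50)
})

test_that("organizer and cargo are anticorrelated on every frame after burn-in", {
  pt <- smallPlanar(kappa = 0.4, nFrames = 8L)
  gt <- groundTruth(generatePlanarScene(pt))
  ct <- vapply(2:8, function(f)
    cor(as.numeric(cleanOrganizer(gt)[, , f]),
        as.numeric(cleanCargo(gt)[, , f])), numeric(1))
  expect_true(all(ct < 0))

  pa <- sceneParams("planar", cargoMode = "anchored", nFrames = 60L,
                    waveSpeed = 1, rngSeed = 3L)
  gta <- groundTruth(generatePlanarScene(pa))
  ca <- vapply(20:60, function(f)
    cor(as.numeric(cleanOrganizer(gta)[, , f]),
        as.numeric(cleanCargo(gta)[, , f])), numeric(1))
  expect_true(all(ca < 0))
})

test_that("explicit-solver misuse and invalid parameters are rejected", {
  p <- sceneParams("planar", cargoMode = "anchored", nFrames = 100L)
  expect_error(generatePlanarScene(p, solverTimeStep = 10),
               "stable bound")
  expect_error(sceneParams("planar", kappa = 1.2), "kappa")
  expect_error(sceneParams("planar", width = 4L), "8 px")
  expect_error(sceneParams("planar", nFrames = 10L, waveSpeed = 0.5,
                           wavelength = 50), "wavelength")
  expect_error(sceneParams("compartment", width = 20L, height = 24L),
               "rod geometry")
})

test_that("true mask area tracks the duty cycle", {
  p <- smallPlanar(nFrames = 4L)
  tm <- trueMask(groundTruth(generatePlanarScene(p)))
  expect_lt(abs(mean(tm) - p@dutyCycle), 0.05)
})

test_that("colliding anchored waves build a central cargo ridge", {
  p <- sceneParams("collision", nFrames = 120L, rngSeed = 4L)
  cg <- cleanCargo(groundTruth(generateCollisionScene(p)))
  W <- dim(cg)[2]
  band <- which(abs((0:(W - 1)) - (W - 1) / 2) <= 0.05 * W)
  last <- dim(cg)[3]
  expect_gt(mean(cg[, band, last]) / mean(cg[, , last]), 1)
})

test_that("forcing-off relaxes anchored cargo monotonically toward uniformity", {
  p <- sceneParams("collision", nFrames = 150L, forcingOffFrame = 60,
                   rngSeed = 4L)
  cg <- cleanCargo(groundTruth(generateCollisionScene(p)))
  v <- frameVariances(cg)
  expect_true(all(diff(v[62:150]) <= 1e-9 * v[62]))
})

test_that("transient collision cargo re-homogenizes instantly after forcing-off", {
  p <- sceneParams("collision", cargoMode = "transient", nFrames = 80L,
                   forcingOffFrame = 60, rngSeed = 4L)
  cg <- cleanCargo(groundTruth(generateCollisionScene(p)))
  W <- dim(cg)[2]
  band <- which(abs((0:(W - 1)) - (W - 1) / 2) <= 0.05 * W)
  enrich <- mean(cg[, band, 70]) / mean(cg[, , 70]) - 1
  expect_lt(abs(enrich), 0.01)
})

test_that("compartment organizer time average has polar maxima and a central dip", {
  p <- sceneParams("compartment", rngSeed = 6L)
  org <- cleanOrganizer(groundTruth(generateCompartmentScene(p)))
  avg <- apply(org, c(1, 2), mean)
  prof <- colMeans(avg[7:18, ])
  L <- p@width
  center <- prof[round(L / 2)]
  poleL <- max(prof[1:round(L / 3)])
  poleR <- max(prof[round(2 * L / 3):L])
  expect_lt(center, poleL)
  expect_lt(center, poleR)
})

test_that("spiral-like anchored scenes deplete the spiral core", {
  p <- sceneParams("spiral_like", width = 96L, height = 96L, nFrames = 80L,
                   wavelength = 30, rngSeed = 8L)
  cg <- cleanCargo(groundTruth(generateSpiralScene(p)))
  n <- dim(cg)[1]
  x <- matrix(0:(n - 1), n, n, byrow = TRUE); y <- t(x)
  core <- sqrt((x - (n - 1) / 2)^2 + (y - (n - 1) / 2)^2) < 10
  last <- dim(cg)[3]
  expect_lt(mean(cg[, , last][core]), mean(cg[, , last]))
})

test_that("scene parameters round-trip through their YAML config", {
  p <- withDefaultNoise(sceneParams("compartment", cargoMode = "anchored",
                                    kappa = 0.07, rngSeed = 12L))
  f <- tempfile(fileext = ".yaml")
  writeSceneParams(p, f)
  q <- readSceneParams(f)
  for (s in slotNames(p)) expect_equal(slot(q, s), slot(p, s), info = s)
})
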