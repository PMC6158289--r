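# A two-bump axial profile with analytically known maxima, embedding an
# arbitrary unit-box quadratic in the cargo channel (the organizer maxima at
# xl/xr define the box).
twoBumpProfile <- function(a = 0, xl = 40, xr = 160, n = 200, bumpSd = 15,
                           noiseSd = 0, seed = NULL) {
  xs <- 0:(n - 1)
  org <- 1000 * exp(-((xs - xl) / bumpSd)^2) +
         1000 * exp(-((xs - xr) / bumpSd)^2) +
         50 * (xs > xl - 20 & xs < xr + 20)
  mid <- (xl + xr) / 2
  cargo <- ifelse(xs >= xl & xs <= xr,
                  a * ((xs - mid) / (xr - xl))^2 + 1, 1 + a * 0.25) * 100
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cargo <- cargo + rnorm(n, 0, noiseSd * 100)
  }
  new("AxialProfile", positions = as.numeric(xs),
      values = cbind(organizer = org, cargo = cargo),
      channelNames = c("organizer", "cargo"), source = "synthetic")
}

test_that("time averaging is an arithmetic per-pixel mean", {
  A <- matrix(runif(64, 1, 5), 8, 8)
  px <- array(0, c(8, 8, 1, 2))
  px[, , 1, 1] <- A; px[, , 1, 2] <- 3 * A
  st <- ImageStack(px)
  expect_equal(getFrame(timeAverage(st), 0, 1), 2 * A)
  # frame-order invariance
  px2 <- px[, , , 2:1, drop = FALSE]
  expect_equal(timeAverage(ImageStack(px2))@pixels, timeAverage(st)@pixels)
  expect_error(timeAverage(ImageStack(px[, , , 1, drop = FALSE])), "2 frames")
})

test_that("long-axis projection averages the short axis in either orientation", {
  prof1d <- sin((0:79) / 10) + 2
  img <- matrix(rep(prof1d, each = 20), 20, 80)      # constant short axis
  px <- array(img, c(20, 80, 1, 2))
  st <- ImageStack(px)
  avg <- timeAverage(st)
  p <- projectLongAxis(avg, c(0, 0, 80, 20))
  expect_equal(as.numeric(p@values[, 1]), prof1d, tolerance = 1e-12)
  # transposed ROI orientation handled identically
  pxT <- array(t(img), c(80, 20, 1, 2))
  pT <- projectLongAxis(timeAverage(ImageStack(pxT)), c(0, 0, 20, 80))
  expect_equal(pT@values, p@values)
  expect_error(projectLongAxis(avg, c(0, 0, 100, 20)), "outside")
  expect_error(projectLongAxis(avg, c(0, 0, 40, 10)), "50 px")
})

test_that("compartment edges are found within a pixel of a step", {
  n <- 150
  v <- c(rep(1, 40), rep(100, 70), rep(1, 40)) + (0:(n - 1)) * 1e-6
  prof <- new("AxialProfile", positions = as.numeric(0:(n - 1)),
              values = cbind(organizer = v),
              channelNames = "organizer", source = "step")
  clipped <- detectEdgesAndClip(prof)
  expect_lte(abs(min(clipped@positions) - 40), 1)
  expect_lte(abs(max(clipped@positions) - 109), 1)
  # intensity doubling leaves the edges unchanged (relative criterion)
  prof2 <- prof; prof2@values <- prof@values * 2
  clipped2 <- detectEdgesAndClip(prof2)
  expect_equal(range(clipped2@positions), range(clipped@positions))
  # all-background profiles are rejected
  flat <- prof
  set.seed(1); flat@values[, 1] <- rnorm(n, 10, 0.1)
  expect_error(detectEdgesAndClip(flat), "rejected")
})

test_that("polar maxima are recovered within half a pixel", {
  prof <- twoBumpProfile()
  mx <- locatePolarMaxima(prof)
  expect_lt(abs(mx[1] - 40), 0.5)
  expect_lt(abs(mx[2] - 160), 0.5)
  # mirror symmetry
  profM <- new("AxialProfile", positions = prof@positions,
               values = prof@values[nrow(prof@values):1, , drop = FALSE],
               channelNames = prof@channelNames, source = "mirror")
  mxM <- locatePolarMaxima(profM)
  expect_equal(sort(199 - mxM), mx, tolerance = 0.2)
  # additive offsets do not move the maxima
  profO <- prof; profO@values[, 1] <- profO@values[, 1] + 500
  expect_equal(locatePolarMaxima(profO), mx, tolerance = 1e-6)
  expect_error(locatePolarMaxima(prof, window = 120L), "longer")
})

test_that("unit-box projection uses one organizer-defined box for all channels", {
  prof <- twoBumpProfile(a = 0.3)
  mx <- locatePolarMaxima(prof)
  ub <- projectUnitBox(prof, mx[1], mx[2])
  expect_equal(ub@boxEdges, mx)
  expect_equal(range(ub@x), c(-0.5, 0.5))
  expect_equal(dim(ub@values), c(101L, 2L))
  # x = -0.5 maps exactly to the profile value at the left box edge
  atLeft <- approx(prof@positions, prof@values[, 2], xout = mx[1])$y
  expect_equal(ub@values[1, 2] * mean(approx(prof@positions, prof@values[, 2],
               xout = mx[1] + (ub@x + 0.5) * diff(mx))$y), atLeft)
  # each channel is normalized to unit mean
  expect_equal(colMeans(ub@values), c(1, 1), tolerance = 1e-9)
  expect_error(projectUnitBox(prof, 10, 300), "inside")
})

test_that("quadratic fits are exact on quadratics and robust to noise", {
  x <- seq(-0.5, 0.5, length.out = 101)
  ub <- new("UnitBoxProfile", x = x,
            values = cbind(0.5 * x^2 + 1, rep(2, 101)),
            channelNames = c("q", "const"), fits = data.frame(),
            boxEdges = c(0, 1))
  fit <- fitQuadratic(ub)
  expect_equal(fit@fits$a[1], 0.5, tolerance = 1e-12)
  expect_equal(fit@fits$b[1], 1, tolerance = 1e-12)
  expect_equal(fit@fits$curvature[1], 1)
  expect_equal(fit@fits$depth[1], 0.125)
  expect_equal(fit@fits$a[2], 0, tolerance = 1e-12)

  # Monte-Carlo: sigma = 0.05 noise, 200 seeds
  aTrue <- 0.3
  aHat <- vapply(1:200, function(s) {
    set.seed(s)
    y <- aTrue * x^2 + 1 + rnorm(101, 0, 0.05)
    u <- new("UnitBoxProfile", x = x, values = cbind(y),
             channelNames = "q", fits = data.frame(), boxEdges = c(0, 1))
    fitQuadratic(u)@fits$a
  }, numeric(1))
  expect_lt(abs(mean(aHat) - aTrue), 0.02)
  expect_lt(sd(aHat), 0.08)
})

test_that("curvature classification respects the tolerance band", {
  expect_identical(classifyProfile(0), "homogeneous")
  expect_identical(classifyProfile(0.149), "homogeneous")
  expect_identical(classifyProfile(0.2), "polar")
  expect_identical(classifyProfile(-0.2), "center_enriched")
  expect_identical(classifyProfile(c(-1, 0, 1)),
                   c("center_enriched", "homogeneous", "polar"))
  expect_error(classifyProfile(0, tolerance = 0), "tolerance")
})

test_that("exact unit-box quadratics survive the embed-project-fit chain", {
  for (a in c(-0.5, -0.1, 0, 0.1, 0.5)) {
    prof <- twoBumpProfile(a = a)
    mx <- locatePolarMaxima(prof)
    fit <- fitQuadratic(projectUnitBox(prof, mx[1], mx[2]))
    expect_lt(abs(fit@fits$a[2] - a), 0.05)
  }
})

test_that("compartment scenes classify organizer, anchored and transient correctly", {
  for (cm in c("anchored", "transient")) {
    p <- withDefaultNoise(sceneParams("compartment", cargoMode = cm,
                                      rngSeed = 31L))
    sc <- generateCompartmentScene(p)
    ub <- analyzeCompartment(imageStack(sc), compartmentRoi(p))
    f <- ub@fits
    expect_identical(f$classification[f$channel == "organizer"], "polar")
    expect_identical(f$classification[f$channel == "cargo"],
                     if (cm == "anchored") "center_enriched" else "homogeneous")
  }
})
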