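# Synthetic two-channel fluorescence scenes with ground truth.
#
# The organizer channel is an analytic traveling/oscillating field; the cargo
# channel follows one of two models:
#   transient: instantaneous occupancy depletion C = baseline * (1 - kappa*Dn),
#     with Dn the per-frame min-max normalized organizer field (a transiently
#     binding species re-equilibrates much faster than the wave moves);
#   anchored: mass-conserved lateral transport
#     dC/dt = div(D_c grad C + chi * C * grad Dn),
#     i.e. diffusion plus drift down the organizer gradient -- the simplest
#     conservative realization of a propagating diffusion barrier.  This is a
#     modeling choice of the generator, not a mechanistic claim.
#
# Imaging artifacts are layered in fixed order on the clean fields:
# illumination (multiplicative vignette) -> bleaching exp(-t/tau) ->
# Poisson shot noise at the stated gain -> additive Gaussian read noise.
# Every layer is independently disableable; with all layers off the stack
# equals the clean fields exactly.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.smoothstep <- function(z) {
  z <- pmin(pmax(z, 0), 1)
  z * z * (3 - 2 * z)
}

#' Periodic asymmetric wave pulse
#'
#' Unit-amplitude pulse on phase in [0, 1): a slow linear rise over
#' \code{riseFrac}, a plateau, and a steep linear fall over \code{fallFrac}
#' (front/rear asymmetry of a propagating wave with sharp rear detachment).
#' The plateau length is chosen so the pulse exceeds half-maximum over
#' exactly \code{dutyCycle} of the period.  With both ramps zero the pulse
#' is square (binary).
#'
#' @param phase numeric, wave phase (any real; evaluated mod 1)
#' @param dutyCycle fraction of the period above half-maximum, in (0, 1)
#' @param riseFrac,fallFrac ramp widths as fractions of the period
#' @return pulse values in [0, 1]
#' @export
wavePulse <- function(phase, dutyCycle, riseFrac = 0.10, fallFrac = 0.02) {
  p <- phase - floor(phase)
  plateau <- dutyCycle - (riseFrac + fallFrac) / 2
  if (plateau < 0) stop("ramps too wide for this duty cycle")
  # a point watching the wave pass sees p decrease in time, so the layout in
  # p is: steep ramp (the detaching rear) first, plateau, then the slow ramp
  # that spatially leads the front
  w <- numeric(length(p))
  if (fallFrac > 0) {
    i <- p < fallFrac
    w[i] <- p[i] / fallFrac
  }
  i <- p >= fallFrac & p < fallFrac + plateau
  w[i] <- 1
  if (riseFrac > 0) {
    i <- p >= fallFrac + plateau & p < fallFrac + plateau + riseFrac
    w[i] <- 1 - (p[i] - fallFrac - plateau) / riseFrac
  }
  if (fallFrac == 0) w[p < plateau] <- 1   # square pulse: plateau starts at 0
  dim(w) <- dim(phase)
  w
}

#' Construct scene parameters
#'
#' Returns a [SceneParams-class] with mode-appropriate defaults.  All noise
#' layers are off by default (clean scenes); apply [withDefaultNoise()] for a
#' realistic imaging-noise stack.  Defaults define the standard study
#' conditions of this package (see the methods vignette for rationale):
#' planar/collision/spiral scenes use strong transient depletion
#' (kappa = 0.5), compartment scenes the weak-depletion regime
#' (kappa = 0.03) under which the transient time average is near-flat.
#'
#' @param mode \code{"planar"}, \code{"collision"}, \code{"spiral_like"} or
#'   \code{"compartment"}
#' @param ... named overrides for any [SceneParams-class] slot
#'   (\code{width}, \code{nFrames}, \code{kappa}, \code{cargoMode},
#'   \code{rngSeed}, ...)
#' @return a validated [SceneParams-class]
#' @examples
#' sceneParams("planar", kappa = 0.2, rngSeed = 7)
#' @export
sceneParams <- function(mode = c("planar", "collision", "spiral_like",
                                 "compartment"), ...) {
  mode <- match.arg(mode)
  def <- list(
    width = 128L, height = 128L, nFrames = 100L,
    pixelSize = 1, frameInterval = 2,
    wavelength = 50, waveSpeed = 0.5, dutyCycle = 0.4,
    riseFrac = 0.10, fallFrac = 0.02,
    organizerBackground = 20, organizerAmplitude = 100,
    cargoMode = "transient", cargoBaseline = 100,
    kappa = 0.5, cargoDiffusion = 1, barrierCoupling = 3,
    oscPeriod = 40,
    forcingOffFrame = NA_real_,
    illuminationSigma = NA_real_, photonGain = NA_real_,
    readNoiseSigma = 0, bleachTau = NA_real_,
    rngSeed = 1L
  )
  if (mode == "collision") {
    def$width <- 64L; def$height <- 64L
    def$wavelength <- 24; def$nFrames <- 120L
    def$cargoMode <- "anchored"; def$cargoDiffusion <- 2
    def$barrierCoupling <- 6
  } else if (mode == "compartment") {
    def$width <- 220L; def$height <- 24L
    def$nFrames <- 160L
    def$organizerBackground <- 5
    def$kappa <- 0.03
    def$cargoDiffusion <- 1; def$barrierCoupling <- 20
  } else if (mode == "spiral_like") {
    def$cargoMode <- "anchored"; def$nFrames <- 120L
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  def[names(ov)] <- ov
  new("SceneParams", mode = mode,
      width = as.integer(def$width), height = as.integer(def$height),
      nFrames = as.integer(def$nFrames),
      pixelSize = def$pixelSize, frameInterval = def$frameInterval,
      wavelength = def$wavelength, waveSpeed = def$waveSpeed,
      dutyCycle = def$dutyCycle, riseFrac = def$riseFrac,
      fallFrac = def$fallFrac,
      organizerBackground = def$organizerBackground,
      organizerAmplitude = def$organizerAmplitude,
      cargoMode = def$cargoMode, cargoBaseline = def$cargoBaseline,
      kappa = def$kappa, cargoDiffusion = def$cargoDiffusion,
      barrierCoupling = def$barrierCoupling, oscPeriod = def$oscPeriod,
      forcingOffFrame = as.numeric(def$forcingOffFrame),
      illuminationSigma = as.numeric(def$illuminationSigma),
      photonGain = as.numeric(def$photonGain),
      readNoiseSigma = def$readNoiseSigma,
      bleachTau = as.numeric(def$bleachTau),
      rngSeed = as.integer(def$rngSeed))
}

#' Apply the standard imaging-noise stack to scene parameters
#'
#' Sets a gentle Gaussian illumination vignette (sigma = 1.5 x the larger
#' image side), Poisson shot noise at 20 electrons per intensity unit,
#' 2 intensity units of Gaussian read noise and exponential bleaching with a
#' 300-frame time constant.
#'
#' @param params a [SceneParams-class]
#' @return modified [SceneParams-class]
#' @export
withDefaultNoise <- function(params) {
  params@illuminationSigma <- 1.5 * max(params@width, params@height)
  params@photonGain <- 20
  params@readNoiseSigma <- 2
  params@bleachTau <- 300
  validObject(params)
  params
}

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams: mode '", object@mode, "', ", object@width, " x ",
      object@height, " px, ", object@nFrames, " frames\n",
      "  cargo: ", object@cargoMode, " (kappa ", object@kappa,
      ", D_c ", object@cargoDiffusion, ", chi ", object@barrierCoupling,
      " px^2/frame), seed ", object@rngSeed, "\n", sep = "")
})

## organizer fields ---------------------------------------------------------

# compartment geometry constants (px); see methods vignette
.COMP_MARGIN_X <- 20L
.COMP_MARGIN_Y <- 4L
.COMP_WALL_RAMP <- 12
.COMP_EDGE_WIDTH <- 6
.COMP_SWEEP <- c(0.05, 0.45)   # cap edge sweep, fractions of interior length

.organizerField <- function(params, t) {
  W <- params@width; H <- params@height
  bg <- params@organizerBackground; amp <- params@organizerAmplitude
  off <- !is.na(params@forcingOffFrame) && t >= params@forcingOffFrame
  x <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1L), H, W)
  if (params@mode == "planar") {
    if (off) return(matrix(bg, H, W))
    ph <- (x - params@waveSpeed * t) / params@wavelength
    bg + amp * wavePulse(ph, params@dutyCycle, params@riseFrac, params@fallFrac)
  } else if (params@mode == "collision") {
    if (off) return(matrix(bg, H, W))
    mid <- (W - 1) / 2
    phL <- (x - params@waveSpeed * t) / params@wavelength
    phR <- ((W - 1 - x) - params@waveSpeed * t) / params@wavelength
    wL <- wavePulse(phL, params@dutyCycle, params@riseFrac, params@fallFrac)
    wR <- wavePulse(phR, params@dutyCycle, params@riseFrac, params@fallFrac)
    # counter-propagating trains annihilate along the midline: amplitude
    # fades over a narrow dead zone where the colliding fronts extinguish
    dz <- max(4, 0.06 * W)
    envL <- .smoothstep((mid - x) / dz)
    envR <- .smoothstep((x - mid) / dz)
    w <- wL * envL * (x <= mid) + wR * envR * (x > mid)
    bg + amp * w
  } else if (params@mode == "spiral_like") {
    if (off) return(matrix(bg, H, W))
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    th <- atan2(y - cy, x - cx)
    ph <- (r - params@waveSpeed * t) / params@wavelength + th / (2 * pi)
    core <- .smoothstep(r / 8)
    bg + amp * core *
      wavePulse(ph, params@dutyCycle, params@riseFrac, params@fallFrac)
  } else {  # compartment: pole-to-pole sweeping polar cap
    inside <- .compartmentInterior(params)
    u <- x - .COMP_MARGIN_X                      # 0-based long-axis position
    L <- W - 2L * .COMP_MARGIN_X
    win <- .smoothstep(u / .COMP_WALL_RAMP) *
           .smoothstep((L - 1 - u) / .COMP_WALL_RAMP)
    if (off) return(bg * win * inside)
    half <- params@oscPeriod / 2
    phaseIdx <- floor(t / half)
    tau <- (t - phaseIdx * half) / half
    fromLeft <- (phaseIdx %% 2) == 0
    uPole <- if (fromLeft) u else (L - 1 - u)
    edge <- (.COMP_SWEEP[1] + diff(.COMP_SWEEP) * tau) * L
    cap <- 1 / (1 + exp(-(edge - uPole) / .COMP_EDGE_WIDTH))
    (bg + amp * cap) * win * inside
  }
}

.compartmentInterior <- function(params) {
  W <- params@width; H <- params@height
  x <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1L), H, W)
  (x >= .COMP_MARGIN_X & x < W - .COMP_MARGIN_X &
   y >= .COMP_MARGIN_Y & y < H - .COMP_MARGIN_Y) * 1
}

.normalizeField <- function(D) {
  rng <- range(D)
  if (rng[2] <= rng[1]) return(array(0, dim(D)))
  (D - rng[1]) / (rng[2] - rng[1])
}

## conservative transport solver --------------------------------------------

# one explicit finite-volume step of dC/dt = div(D grad C + chi C grad Dn).
# Diffusion is centered; the drift down the organizer gradient is upwinded
# (face velocity v = -chi * dDn; the donor cell supplies the advected mass),
# which keeps concentrations non-negative under the CFL bound.  Face fluxes
# are antisymmetric between neighbours, so total mass is conserved to
# floating-point accuracy (reflecting: zero-flux walls; periodic: wrapped
# faces).
.faceFlux <- function(CL, CR, DnL, DnR, D, chi) {
  v <- -chi * (DnR - DnL)
  -D * (CR - CL) + ifelse(v > 0, v * CL, v * CR)
}

.transportStep <- function(C, Dn, dt, D, chi, periodic) {
  nr <- nrow(C); nc <- ncol(C)
  if (periodic) {
    Fx <- .faceFlux(C, C[, c(2:nc, 1L)], Dn, Dn[, c(2:nc, 1L)], D, chi)
    divx <- Fx - Fx[, c(nc, 1:(nc - 1L))]
    Fy <- .faceFlux(C, C[c(2:nr, 1L), ], Dn, Dn[c(2:nr, 1L), ], D, chi)
    divy <- Fy - Fy[c(nr, 1:(nr - 1L)), ]
    C - dt * (divx + divy)
  } else {
    Fx <- matrix(0, nr, nc + 1L)
    Fx[, 2:nc] <- .faceFlux(C[, 1:(nc - 1L)], C[, 2:nc],
                            Dn[, 1:(nc - 1L)], Dn[, 2:nc], D, chi)
    divx <- Fx[, 2:(nc + 1L)] - Fx[, 1:nc]
    Fy <- matrix(0, nr + 1L, nc)
    Fy[2:nr, ] <- .faceFlux(C[1:(nr - 1L), ], C[2:nr, ],
                            Dn[1:(nr - 1L), ], Dn[2:nr, ], D, chi)
    divy <- Fy[2:(nr + 1L), ] - Fy[1:nr, ]
    C - dt * (divx + divy)
  }
}

# stable explicit time step for given diffusion and maximum drift gradient
.stableStep <- function(D, chi, maxGrad) {
  0.9 / (4 * D + 4 * chi * maxGrad + 1e-12)
}

## noise layers --------------------------------------------------------------

.illuminationField <- function(params) {
  W <- params@width; H <- params@height
  if (is.na(params@illuminationSigma)) return(matrix(1, H, W))
  x <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1L), H, W)
  exp(-(((x - (W - 1) / 2)^2 + (y - (H - 1) / 2)^2)) /
        (2 * params@illuminationSigma^2))
}

.bleachFactors <- function(params) {
  t <- 0:(params@nFrames - 1L)
  if (is.na(params@bleachTau)) rep(1, params@nFrames)
  else exp(-t / params@bleachTau)
}

# apply illumination -> bleach -> shot -> read, in this fixed order, to one
# clean [row, col, frame] array; draws from the current RNG stream
.applyNoise <- function(clean, illum, bleach, params) {
  anyNoise <- !is.na(params@photonGain) || params@readNoiseSigma > 0
  out <- clean
  nf <- dim(clean)[3L]
  for (f in seq_len(nf)) {
    img <- clean[, , f] * illum * bleach[f]
    if (!is.na(params@photonGain))
      img <- matrix(stats::rpois(length(img), params@photonGain * img) /
                      params@photonGain, nrow(img), ncol(img))
    if (params@readNoiseSigma > 0)
      img <- img + stats::rnorm(length(img), 0, params@readNoiseSigma)
    out[, , f] <- if (anyNoise) pmax(img, 0) else img  # camera clips at zero
  }
  out
}

## scene generation ----------------------------------------------------------

.generateScene <- function(params, solverTimeStep = NULL) {
  validObject(params)
  W <- params@width; H <- params@height; nf <- params@nFrames
  periodic <- params@mode == "planar"
  inside <- if (params@mode == "compartment") .compartmentInterior(params)
  org <- array(0, c(H, W, nf))
  carg <- array(0, c(H, W, nf))
  tmask <- array(FALSE, c(H, W, nf))
  halfMax <- params@organizerBackground + params@organizerAmplitude / 2

  DnAt <- function(t) .normalizeField(.organizerField(params, t))

  # anchored transport needs a stable explicit substep; probe the drift
  # gradient on a few frames to derive the bound
  nSub <- 1L
  if (params@cargoMode == "anchored" &&
      (params@cargoDiffusion > 0 || params@barrierCoupling > 0)) {
    probe <- vapply(unique(round(seq(0, nf - 1, length.out = 5))),
                    function(t) {
                      Dn <- DnAt(t)
                      max(abs(diff(Dn)), abs(t(diff(t(Dn)))), 0)
                    }, numeric(1))
    dtStable <- .stableStep(params@cargoDiffusion, params@barrierCoupling,
                            max(probe))
    if (!is.null(solverTimeStep)) {
      if (solverTimeStep > dtStable)
        stop("explicit-scheme stability violated: time step ",
             signif(solverTimeStep, 4), " exceeds the stable bound ",
             signif(dtStable, 4),
             " frames for D_c = ", params@cargoDiffusion,
             ", chi = ", params@barrierCoupling)
      nSub <- max(1L, ceiling(1 / solverTimeStep))
    } else {
      nSub <- max(1L, ceiling(1 / dtStable))
    }
  }

  # cargo state at t = 0
  if (params@cargoMode == "anchored") {
    C <- matrix(params@cargoBaseline, H, W)
    if (!is.null(inside)) C <- C * inside
  }

  for (f in seq_len(nf)) {
    t <- f - 1
    D <- .organizerField(params, t)
    org[, , f] <- D
    tmask[, , f] <- D > halfMax
    if (params@cargoMode == "transient") {
      Ct <- params@cargoBaseline * (1 - params@kappa * .normalizeField(D))
      if (!is.null(inside)) {
        u <- matrix(0:(W - 1L), H, W, byrow = TRUE) - .COMP_MARGIN_X
        L <- W - 2L * .COMP_MARGIN_X
        win <- .smoothstep(u / .COMP_WALL_RAMP) *
               .smoothstep((L - 1 - u) / .COMP_WALL_RAMP)
        Ct <- Ct * win * inside
      }
      carg[, , f] <- Ct
    } else {
      carg[, , f] <- C
      if (f < nf) {  # advance from t to t + 1
        dt <- 1 / nSub
        for (s in seq_len(nSub)) {
          Dn <- DnAt(t + (s - 0.5) * dt)
          if (!is.null(inside)) {
            Cin <- C[(.COMP_MARGIN_Y + 1):(H - .COMP_MARGIN_Y),
                     (.COMP_MARGIN_X + 1):(W - .COMP_MARGIN_X)]
            Dnin <- Dn[(.COMP_MARGIN_Y + 1):(H - .COMP_MARGIN_Y),
                       (.COMP_MARGIN_X + 1):(W - .COMP_MARGIN_X)]
            Cin <- .transportStep(Cin, Dnin, dt, params@cargoDiffusion,
                                  params@barrierCoupling, periodic = FALSE)
            C[(.COMP_MARGIN_Y + 1):(H - .COMP_MARGIN_Y),
              (.COMP_MARGIN_X + 1):(W - .COMP_MARGIN_X)] <- Cin
          } else {
            C <- .transportStep(C, Dn, dt, params@cargoDiffusion,
                                params@barrierCoupling, periodic = periodic)
          }
        }
      }
    }
  }

  illum <- .illuminationField(params)
  bleach <- .bleachFactors(params)
  px <- array(0, c(H, W, 2L, nf))
  .withSeed(params@rngSeed, {
    px[, , 1L, ] <- .applyNoise(org, illum, bleach, params)
    px[, , 2L, ] <- .applyNoise(carg, illum, bleach, params)
  })

  stack <- ImageStack(px, pixelSize = params@pixelSize,
                      frameInterval = params@frameInterval,
                      channelNames = c("organizer", "cargo"))
  truth <- new("GroundTruth", cleanOrganizer = org, cleanCargo = carg,
               trueMask = tmask,
               totalCargoMass = apply(carg, 3, sum),
               illuminationField = illum, bleachFactors = bleach)
  new("SyntheticScene", stack = stack, truth = truth, params = params)
}

#' Generate a planar traveling-wave scene
#'
#' Organizer: background + amplitude x periodic asymmetric pulse translating
#' at \code{waveSpeed} along x (periodic boundaries).  Cargo: transient
#' occupancy depletion or mass-conserved anchored transport (see
#' [sceneParams()]).  Emulates organizer waves with an anticorrelated cargo
#' channel on a planar membrane.
#'
#' @param params a [SceneParams-class] with \code{mode = "planar"}
#' @param solverTimeStep optional explicit-solver time step in frames for
#'   anchored cargo; rejected with the stable bound named when too large.
#'   Default: chosen automatically below the bound.
#' @return a [SyntheticScene-class]
#' @export
generatePlanarScene <- function(params, solverTimeStep = NULL) {
  stopifnot(params@mode == "planar")
  .generateScene(params, solverTimeStep)
}

#' Generate a colliding-wave scene
#'
#' Two counter-propagating organizer wavetrains annihilate along the vertical
#' midline.  Anchored cargo develops a persistent enrichment ridge at the
#' collision line; if \code{forcingOffFrame} is set, the organizer detaches
#' (field drops to background) from that frame on and the cargo relaxes by
#' pure diffusion toward uniformity (reflecting boundaries).
#'
#' @inheritParams generatePlanarScene
#' @param params a [SceneParams-class] with \code{mode = "collision"}
#' @return a [SyntheticScene-class]
#' @export
generateCollisionScene <- function(params, solverTimeStep = NULL) {
  stopifnot(params@mode == "collision")
  .generateScene(params, solverTimeStep)
}

#' Generate a rod-shaped compartment scene with pole-to-pole oscillations
#'
#' The organizer alternately occupies the two compartment halves as a polar
#' cap whose soft edge sweeps from the pole toward mid-compartment each
#' half-period (period \code{oscPeriod} frames).  The time average of the
#' organizer has two polar maxima and a central dip; anchored cargo develops
#' a central maximum; transient cargo stays near-flat.  The compartment
#' interior is inset by a fixed margin inside a dark frame so that
#' edge-detection has background to work with.
#'
#' @inheritParams generatePlanarScene
#' @param params a [SceneParams-class] with \code{mode = "compartment"}
#' @return a [SyntheticScene-class]
#' @export
generateCompartmentScene <- function(params, solverTimeStep = NULL) {
  stopifnot(params@mode == "compartment")
  .generateScene(params, solverTimeStep)
}

#' Generate a spiral-like rotating-wave scene
#'
#' An outward-rotating spiral organizer wave (amplitude suppressed at the
#' core).  With anchored cargo the spiral core becomes depleted and the rim
#' enriched over time.
#'
#' @inheritParams generatePlanarScene
#' @param params a [SceneParams-class] with \code{mode = "spiral_like"}
#' @return a [SyntheticScene-class]
#' @export
generateSpiralScene <- function(params, solverTimeStep = NULL) {
  stopifnot(params@mode == "spiral_like")
  .generateScene(params, solverTimeStep)
}

## accessors -----------------------------------------------------------------

#' @rdname SyntheticScene-class
#' @export
setMethod("imageStack", "SyntheticScene", function(x) x@stack)

#' @rdname SyntheticScene-class
#' @export
setMethod("groundTruth", "SyntheticScene", function(x) x@truth)

#' @rdname SyntheticScene-class
#' @export
setMethod("sceneParameters", "SyntheticScene", function(x) x@params)

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene (", object@params@mode, ", ",
      object@params@cargoMode, " cargo)\n", sep = "")
  show(object@stack)
})

#' @rdname GroundTruth-class
#' @param x a [GroundTruth-class]
#' @export
cleanOrganizer <- function(x) x@cleanOrganizer

#' @rdname GroundTruth-class
#' @export
cleanCargo <- function(x) x@cleanCargo

#' @rdname GroundTruth-class
#' @export
trueMask <- function(x) x@trueMask

#' @rdname GroundTruth-class
#' @export
totalCargoMass <- function(x) x@totalCargoMass

#' @rdname GroundTruth-class
#' @export
illuminationField <- function(x) x@illuminationField

#' @rdname GroundTruth-class
#' @export
bleachFactors <- function(x) x@bleachFactors

## scene serialization -------------------------------------------------------

#' Write or read SceneParams as YAML
#'
#' Serializes every parameter so a scene is reproducible from its config
#' alone.
#'
#' @param params a [SceneParams-class]
#' @param path YAML file path
#' @return \code{readSceneParams} returns a [SceneParams-class];
#'   \code{writeSceneParams} returns \code{path} invisibly.
#' @export
writeSceneParams <- function(params, path) {
  sl <- slotNames(params)
  vals <- lapply(sl, function(s) {
    v <- slot(params, s)
    if (is.numeric(v) && anyNA(v)) NULL else v
  })
  names(vals) <- sl
  yaml::write_yaml(vals[!vapply(vals, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname writeSceneParams
#' @export
readSceneParams <- function(path) {
  vals <- yaml::read_yaml(path)
  mode <- vals$mode
  vals$mode <- NULL
  do.call(sceneParams, c(list(mode = mode), vals))
}

#' Write a synthetic scene to disk
#'
#' Writes the recorded stack as a 16-bit multi-page TIFF (channel-major
#' interleave), the clean fields and true mask as 32-bit float TIFFs, the
#' per-frame ground-truth scalars as CSV and the parameters as YAML, into
#' \code{dir}.
#'
#' @param scene a [SyntheticScene-class]
#' @param dir output directory (created if missing)
#' @return invisibly, the directory
#' @export
writeScene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- writeStack(imageStack(scene), file.path(dir, "stack.tif"))
  tr <- groundTruth(scene)
  nf <- dim(tr@cleanOrganizer)[3L]
  sc2 <- max(tr@cleanOrganizer, tr@cleanCargo, 1)
  pages <- list()
  for (f in seq_len(nf))
    pages <- c(pages, list(tr@cleanOrganizer[, , f] / sc2,
                           tr@cleanCargo[, , f] / sc2))
  tiff::writeTIFF(pages, file.path(dir, "clean.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(lapply(seq_len(nf), function(f) tr@trueMask[, , f] * 1.0),
                  file.path(dir, "true_mask.tif"), bits.per.sample = 8L)
  utils::write.csv(
    data.frame(frame = seq_len(nf) - 1L,
               total_cargo_mass = tr@totalCargoMass,
               bleach_factor = tr@bleachFactors),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  writeSceneParams(sceneParameters(scene), file.path(dir, "scene_params.yaml"))
  utils::write.csv(data.frame(key = c("stack_intensity_scale",
                                      "clean_intensity_scale"),
                              value = c(scale, sc2)),
                   file.path(dir, "scales.csv"), row.names = FALSE)
  invisible(dir)
}
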