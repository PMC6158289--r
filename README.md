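# waveCargo

Quantification of how traveling protein surface waves spatiotemporally
regulate membrane-bound cargo in two-channel fluorescence time-lapse
microscopy.

Self-organizing systems such as *E. coli* MinDE form traveling waves and
pole-to-pole oscillations on membranes.  These waves act on unrelated
membrane-bound molecules in two distinct ways: **transient binders**
(peripheral proteins that exchange quickly with solution) are locally
depleted wherever the wave sits, while **permanently anchored cargo**
(e.g. streptavidin bound to biotinylated lipids) can only diffuse laterally
and is physically carried by the moving wave front — piling up where waves
collide, at mid-compartment in oscillating rods, and away from spiral cores.
waveCargo is for researchers running such in-vitro reconstitution or
confinement experiments who need the image analysis behind those statements.

## What it computes

* **Wave segmentation** (`segmentWave`): per frame, median filter (disc,
  radius 3–6 px) → pseudo-flat-field correction (Gaussian σ = 75 px) →
  automatic Huang or Li threshold → complementary binary masks
  (wave maximum `max(MinD)` / wave minimum `min(MinD)`).
* **Masked intensity statistics** (`computeWaveStats`, `contrast`): means of
  the *original* images over the full frame and both masks, and the wave
  contrast of a cargo channel

  ```
  contrast = (I_min(MinD) - I_max(MinD)) / I_max(MinD)
  ```

  which is positive for cargo anticorrelated with the organizer wave.
  Plus reference normalization (`normalizeToReference`), per-experiment
  pooling (`poolExperiments`), and molecular area coverage
  (`coverageFraction`).
* **Compartment profile analysis** (`analyzeCompartment`): time average →
  long-axis projection → edge clipping on the organizer profile → two-step
  polar-maxima localization (quartic, then 40-px parabola) → projection of
  both channels onto the organizer-defined unit box x ∈ [−0.5, 0.5] →
  quadratic fit `f(x) = a x² + b`.  `a > 0` means polar enrichment (the
  organizer), `a < 0` center enrichment (anchored cargo), `a ≈ 0`
  homogeneous (transient cargo); `2a` is the curvature and `a/4` the profile
  depth.
* **Kymographs** (`extractKymograph`, `normalizeByFrameMean`,
  `bleachCorrectHistogramMatch`, `estimateWavelengthVelocity`).
* **Synthetic scenes** (`sceneParams`, `generatePlanarScene`,
  `generateCollisionScene`, `generateCompartmentScene`,
  `generateSpiralScene`): seeded two-channel stacks with planar, colliding,
  spiral and pole-to-pole oscillating organizer fields, transient or
  mass-conserved anchored cargo (conservative upwind advection–diffusion
  solver), realistic imaging artifacts (vignette, shot noise, read noise,
  bleaching), and full ground truth for every stage.

A config-driven pipeline (`runPipeline`) and a thin CLI
(`inst/scripts/wavecargo.R` with `simulate / segment / wavestats / profile /
kymo / run` subcommands) wrap the same functions.

## Worked example

```r
library(waveCargo)

params <- withDefaultNoise(sceneParams("planar", kappa = 0.5, rngSeed = 42))
scene  <- generatePlanarScene(params)
stack  <- imageStack(scene)

masks <- segmentWave(stack, method = "huang")
masks
#> WaveMaskPair: 100 frame(s), 128 x 128 px, method 'huang'
#>   valid frames: 100/100; mean wave area fraction: 0.418

stats <- computeWaveStats(stack, masks)
stats
#> WaveIntensityStats: 100 frame(s), channels: organizer, cargo (zero-removal means)
#>   organizer  I_full 49.4  I_min 17.44  I_max 93.63  (means over 100 frames)
#>   cargo      I_full 65.62  I_min 81.63  I_max 43.56  (means over 100 frames)

mean(contrast(stats, "cargo"))
#> [1] 0.873
```

The scene was generated with depletion strength κ = 0.5, for which the
ideal contrast is κ/(1−κ) = 1; the measured 0.87 reflects threshold
placement on the wave ramps and the default noise stack (on ground-truth
masks of the noise-free scene the statistic is exactly 1).  The mask area
fraction 0.418 tracks the generator's duty cycle of 0.4.

An oscillating rod-shaped compartment with lipid-anchored cargo:

```r
cp   <- withDefaultNoise(sceneParams("compartment", cargoMode = "anchored",
                                     rngSeed = 42))
comp <- generateCompartmentScene(cp)
analyzeCompartment(imageStack(comp), roi = c(10, 2, 200, 20))
#> UnitBoxProfile: 101 grid points, box [41.211, 177.75] px
#>   organizer  a = +6.849  b = 0.418  curvature = +13.699  depth = +1.712  [polar]
#>   cargo      a = -3.459  b = 1.294  curvature = -6.918  depth = -0.865  [center_enriched]
```

The organizer time average is polar (a > 0), the anchored cargo
center-enriched (a < 0) — the signature of wave-driven transport toward
mid-compartment.  A transient binder in the same geometry classifies as
homogeneous.

Area coverage of lipid-anchored streptavidin at its measured membrane
density:

```r
coverageFraction(6.6e3, 25)   # molecules/um^2, footprint nm^2
#> [1] 16.5                    # percent, i.e. "about 17%"
```

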