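---
title: "Quantifying wave-driven cargo redistribution: models and methods"
author: "waveCargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wave-driven cargo redistribution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveCargo)
```

## The measurement problem

Self-organizing protein systems such as MinDE form traveling surface waves on
membranes, and these waves can redistribute unrelated membrane-bound
molecules ("cargo").  Two cargo classes behave very differently: a
*transient binder* (e.g. an amphipathic-helix construct) exchanges with
solution quickly, so the wave locally suppresses its membrane occupancy but
no material is transported laterally; a *lipid-anchored* cargo (e.g.
streptavidin on biotinylated lipids) cannot detach on the wave timescale and
is instead pushed laterally by the passing wave, building large-scale
gradients — accumulation at wave-collision lines and at mid-compartment in
oscillating rods, depletion at spiral cores.

waveCargo implements the image quantification for such experiments:

1. **Segmentation** of the organizer channel into complementary binary masks
   (wave maximum / wave minimum).
2. **Masked intensity statistics** on the *original* images, with the
   contrast statistic
   \[(I_{\min(\mathrm{MinD})} - I_{\max(\mathrm{MinD})}) /
     I_{\max(\mathrm{MinD})}.\]
3. **Compartment profile analysis**: time-averaged axial profiles projected
   onto an organizer-defined unit box and classified by the curvature of a
   quadratic fit \(f(x) = ax^2 + b\).
4. **Kymograph utilities** including histogram-matching bleach correction
   and a spectral wavelength/velocity estimator.
5. A **synthetic scene generator** that provides ground truth for all of the
   above.

## The synthetic scene generator

No public image data accompany the experiments this pipeline targets, so the
package ships a generator whose scenes have exactly known answers.  Every
scene is fully determined by a `SceneParams` object (including the RNG
seed): identical parameters give bit-identical stacks.

### Organizer fields

* **planar** — a periodic pulse translating at `waveSpeed` (periodic
  boundaries).  The pulse has a slow leading ramp and a steep trailing ramp
  (a propagating front with sharp rear detachment); a point watching the
  wave pass sees a slow rise and a steep fall.  The plateau length is chosen
  so the pulse exceeds half-maximum over exactly `dutyCycle` of the period,
  and the default ramp widths (10% and 2% of the period) keep the intensity
  histogram close to two-phase, which is what makes automatic thresholding
  of the half-maximum mask well-posed.  Setting both ramps to zero gives a
  square pulse for which closed-form oracle values are exact.
* **collision** — two counter-propagating trains whose amplitude fades over
  a narrow (6% of width) dead zone at the vertical midline, emulating
  mutual annihilation of colliding fronts.  The dead zone is the refuge in
  which anchored cargo accumulates.
* **compartment** — a rod-shaped compartment inset in a dark frame.  The
  organizer forms a polar cap whose soft edge (logistic, 6 px) sweeps from
  the pole toward 45% of the compartment length each half-period, then the
  cap switches poles.  The traveling rear edge is what transports anchored
  cargo ("snow-plow"); a static cap would only pump diffusively and far more
  slowly.  A 12-px smoothstep window at the walls emulates the signal
  drop-off at the compartment boundary and gives the time-averaged organizer
  its two well-defined polar maxima.
* **spiral_like** — an outward-rotating Archimedean spiral with a suppressed
  core.

### Cargo models

*Transient* cargo equilibrates with solution much faster than the wave
moves, so its occupancy is an instantaneous function of the organizer:
\(C = C_0\,(1 - \kappa D_n)\), with \(D_n\) the per-frame min–max normalized
organizer field and \(\kappa \in [0, 1)\) the depletion strength.

*Anchored* cargo is mass-conserving and evolves by
\[\partial_t C = \nabla\cdot\left(D_c \nabla C + \chi\, C\, \nabla D_n\right),\]
diffusion plus drift down the organizer gradient.  This is the simplest
conservative realization of a "propagating diffusion barrier" and is a
modeling choice of the generator, not a mechanistic claim about the protein
system.  The equation is integrated with an explicit finite-volume scheme:
centered diffusion, *upwinded* drift (the donor cell supplies the advected
mass), reflecting (zero-flux) walls except in planar mode (periodic).
Antisymmetric face fluxes make total mass exact to floating point; upwinding
keeps concentrations non-negative under the CFL bound.  The sub-step is
chosen automatically as \(0.9 / (4D_c + 4\chi\,\max|\Delta D_n|)\); a
user-supplied step above this bound is rejected with the bound named.

### Default study conditions

Chosen once, as the conditions all tests and the acceptance analysis run
under:

| parameter | planar / collision | compartment | rationale |
|---|---|---|---|
| image size | 128² / 64² px | 220 × 24 px | full waves resp. rod geometry |
| wavelength, speed | 50 px, 0.5 px/frame | — (period 40 frames) | a few wavelengths per field of view; slow waves |
| duty cycle | 0.4 | — | organizer occupies a bit under half the period |
| \(\kappa\) | 0.5 | 0.03 | planar ratio data show strong depletion; in compartments the near-flat transient time average implies the weak-depletion regime (\(\kappa \lesssim 0.04\), since the time-averaged modulation is \(\kappa\,\Delta\langle D_n\rangle \approx 0.5\,\kappa\)) |
| \(D_c\), \(\chi\) | 1–2, 3–6 px²/frame | 1, 20 px²/frame | \(\chi\) sized so the drift speed at the cap edge is comparable to the sweep speed, the regime in which the barrier visibly transports cargo |
| noise (optional) | vignette σ = 1.5 × image side, shot noise at gain 20 e⁻/unit, read noise σ = 2, bleach τ = 300 frames | same | gentle illumination falloff, shot-noise-limited detection |

Noise layers are applied in the fixed physical order illumination → bleach →
shot → read, each independently disableable; with all layers off the
recorded stack equals the clean fields exactly.  When any noise is applied
the result is clipped at zero, as a camera would.

What the generator does *not* emulate: mechanistic reaction–diffusion
kinetics of the organizer itself, 3-D geometry, fluorophore photophysics
beyond exponential bleaching, drift/stage wobble, or structured background.
Passing tests therefore demonstrate correctness of the *quantification*
given data with the assumed statistical structure, not robustness to every
real-microscope artifact.

## Segmentation chain

Per frame of the organizer channel: disc median filter (default radius 4 px,
the middle of the conventional 3–6 px range) → pseudo-flat-field correction
(divide by a Gaussian-blurred copy, σ = 75 px by default, then multiply by
the blurred copy's mean — the mean-preserving convention; the exact
rescaling convention of the original macro is not documented, so this
dialect choice is flagged here) → automatic threshold.  Masks are applied to
the *original* unfiltered images downstream.

Both thresholds operate on a 256-bin histogram over the per-image min–max
range, matching the common 8-bit implementations, and are therefore
invariant under affine intensity maps; results shift slightly with binning,
which is why the binning is fixed and documented.  Huang minimizes the fuzzy
(Shannon) entropy of class membership; because the criterion is exactly flat
across an empty histogram gap, ties are resolved to the middle of the tying
range (deterministic, and symmetric for well-separated modes).  Li–Lee
iterates the minimum-cross-entropy fixed point from the image mean until the
threshold moves less than half a bin.  Comparison is strict (`>` threshold =
wave); ties go to the complement.  Frames constant after filtering (within
1e-9 relative) admit no threshold and are marked invalid, logged, and
excluded from statistics.

## Masked statistics

`maskedMeanZeroRemoved()` reproduces the historical code path exactly: mask
× image, drop *all* zero products, mean.  This also drops genuinely zero
pixels inside the mask and therefore biases means upward whenever true zeros
exist; the corrected mask-membership mean is available via
`zeroRemoval = FALSE`, under which the identity
\(I_{full} = \alpha I_{max} + (1-\alpha) I_{min}\) (α = wave area fraction)
holds exactly.  Pooling follows the per-experiment convention: image means
are averaged per experiment, and the grand mean and SD are taken across
experiment means (unweighted).  Intensity ratios between conditions are
formed on per-condition mean statistics by default (the per-frame
alternative is available), since the figure convention plots one ratio per
experiment.  Reference normalization divides by the reference intensity and
by the fluorescent (labeled) fraction — only the labeled fraction
fluoresces, so measured intensity underestimates protein by that factor.

## Compartment profiles

The axial profile (mean over the short ROI axis) is clipped at the
compartment edges found on the organizer profile: signal above
flank-background + k·σ (k = 3 by default; the criterion is stated in the
field, the numbers are not, so they are configurable) with a positive
smoothed derivative on the left and symmetric on the right.  Compartments
with no such crossings — no oscillating organizer — are rejected, mirroring
the manual exclusion practice.

The two polar maxima are localized in two steps: a quartic fit over the
whole clipped profile supplies rough interior maxima (the derivative cubic
is solved exactly); a parabola over a 40-px window around each refines the
maximum as its vertex, clamped to the window (the 40-px default matches the
original protocol's magnification; it is configurable for other scales).
If a window's parabola opens upward the discrete argmax is used with a
warning.

Both channels are projected with the *same* organizer-defined box onto
x ∈ [−0.5, 0.5] (101-point grid, linear interpolation) — the centered
coordinate is the only convention under which the sign statements
"a > 0 polar, a < 0 center-enriched" hold for \(f(x) = ax^2 + b\).  Each
channel is divided by its own mean over the box before fitting, so *a* is
dimensionless and comparable across compartments.  This normalization is a
package convention: absolute published depth values obtained under an
unknown normalization are not directly comparable to these coefficients,
which is also why the package reports the whole family (a, curvature 2a,
depth a/4 = f(±0.5) − f(0)).  Classification uses a tolerance band
(default 0.15) around zero.

## Kymographs and corrections

Kymographs sample bilinearly at 1-px steps along a line, averaged over a
3-px perpendicular width by default.  The dense-bundle preprocessing blurs
each frame and divides by its mean (every frame then has mean 1, and global
intensity drifts cancel).  Bleach correction matches each frame's empirical
histogram to a reference frame through a monotone quantile map built on
65,536-level CDFs — 16-bit native resolution rather than 8-bit, avoiding
quantization artifacts on float data; integer cumulative counts are used for
the map so that tie groups cannot shift by a level through float rounding.
The map is undefined for a constant frame, which is set to the reference
median with a warning.

Wavelength and velocity are estimated from the peak of the 2-D power
spectrum of the mean-subtracted kymograph, excluding the zero-frequency row
and column and requiring the peak to exceed 3× the median power (otherwise
undetermined).  Estimates snap to the spectral grid (no sub-bin
interpolation), so the data should contain a few periods along both axes;
this estimator is plumbing for convenience, not a reproduction of any
published measurement protocol.

## Numerical choices and edge cases

* Pixel and frame indices are 0-based in all external interfaces (ROIs,
  lines, CSV outputs); R-internal storage is 1-based.
* Median/Gaussian filters use whole-sample reflection at borders; the
  Gaussian blur is built as a dense separable operator so σ may exceed the
  image size (needed for σ = 75 flat-fielding of small test images).
* The flat-field guard floors non-positive blurred values at 1e-12 of the
  blur maximum, with a warning.
* Problem sizes in the test-suite and acceptance analysis (128² planar
  scenes, 64² collisions, 220 × 24 compartments, 20 seeds per
  classification experiment, 200 noise seeds for the quadratic
  Monte-Carlo) were chosen as the smallest sizes at which the studied
  effects are comfortably resolved.

## Known limitations

* The generator's transport model is phenomenological; parameter values for
  \(\chi\) have no measured counterpart, and the timescale separation of
  small- versus large-scale relaxation after organizer detachment is
  realized qualitatively (it is tunable through \(D_c\)) because no
  quantitative value exists to match.
* The zero-removal statistic is intentionally faithful to its source,
  including its bias; use the corrected variant for new analyses.
* Segmentation quality depends on a roughly two-phase intensity histogram;
  very wide wave ramps (rise fraction ≳ 0.2 of the period) push Huang/Li
  thresholds well below half-maximum, and the half-maximum ground-truth
  mask is then not the mask these methods estimate.
* No hypothesis testing between conditions is provided, matching the scope
  of the quantification it implements.
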