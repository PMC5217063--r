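---
title: "Quantifying Min-protein patterns in confined microchambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Min-protein patterns in confined microchambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minwaves)
```

## The problem

The MinD/MinE system of *E. coli* self-organises on lipid membranes into
travelling concentration patterns whose geometry-dependence carries
information about the underlying reaction-diffusion mechanism. When the
proteins are reconstituted inside fully confined, bilayer-coated
microchambers (about 2.4 µm high, 10–60 µm wide, 10–90 µm long), three
pattern genera appear depending on the chamber geometry: pole-to-pole
(and striped) **oscillations**, **spiral rotations** around a pinned
core, and **traveling waves** crossing the chamber. `minwaves`
implements the measurement chain that turns time-lapse fluorescence
movies of such chambers into quantitative pattern descriptors —
per-chamber classification, wavelength, front velocity, protein
concentration — and the aggregation of those descriptors into a
geometric phase diagram. Because no public movies of this kind exist,
the package carries a first-class synthetic-movie generator with exact
ground truth; every estimator is validated by parameter recovery.

## Synthetic movies

The generators are kinematic, not mechanistic: they draw the moving
intensity fields the microscope would record, with controllable
wavelength λ, speed v (or period T), direction, chirality, noise, and
chamber geometry. No reaction–diffusion equations are solved.

* **Traveling wave** — a raised cosine
  `background + amplitude (1 + cos(2π(u − v t)/λ))/2` along the
  propagation coordinate `u`. The symmetric profile makes consecutive
  peak spacing exactly λ, which is the quantity the wavelength
  estimator measures; an optional `asymmetry` parameter skews the
  profile (off by default). Real MinE bands are asymmetric; the
  estimators only use peak positions, so the symmetric default does not
  favour them.
* **Spiral** — `cos(χφ − 2πr/λ + 2πt/T)` in polar coordinates about the
  core, carrying a topological charge of χ = ±1. With several cores,
  each pixel takes the field of its *nearest* core. An earlier design
  combined cores by a per-pixel maximum, but the maximum of two
  equal-amplitude, non-decaying cosines scrambles the phase winding
  around each core — the defining observable of a spiral — whereas
  nearest-core domains keep each charge intact and produce the sharp
  collision seams where real wave fronts annihilate.
* **Oscillation** — each half-period a band of width λ/2 is born on the
  chamber mid-line, translates at constant speed to one pole (reaching
  it after a fraction `travel_frac = 0.6` of the half-period), dwells
  there, and is then replaced by a band heading for the opposite pole.
  The dwell is deliberate: with a purely constant-speed band the
  mid-line would accumulate *more* temporal variance than the poles
  (bands are born there twice per period), inverting the pole-heavy
  temporal-STD signature that distinguishes confined oscillations in
  real chambers. The half-cycle speed profile of real oscillations is
  not quantified; constant travel plus dwell is this package's choice.
  Striped oscillations seed bands at the mid and quarter lines.
* **Noise control** — `noise_only` movies are white Gaussian noise
  about a flat background, used to verify that the classifier declines
  to classify.

Noise is additive Gaussian, clipped at zero — the simplest model that
exercises the estimators; photon (Poisson) statistics are deliberately
out of scope. Defaults: 0.5 µm/px, 10 s frames (a 0.1 Hz frame rate),
amplitude 100, background 20. All randomness is seeded; identical seeds
give bit-identical movies.

What the generators do *not* emulate: photobleaching, uneven
illumination, chamber-wall fluorescence, focus drift, and amplitude
decay near spiral cores. Passing the recovery suites therefore shows
the estimators are correct *given* clean confined kinematics, not that
they are robust to every artefact of real data — the human-override
hooks in the pipeline config (`rotation_deg`, `boxes`) exist for such
cases.

## Preprocessing

**Rotation.** The field is aligned by minimising, over a grid of
angles, the sum over image rows of the per-row SD of the time-averaged,
rotated image: aligned chamber grids leave flat inter-chamber rows.
Search: coarse ±10° in 0.5° steps, refined ±0.5° in 0.05° steps; ties
break toward zero. Rotation uses bilinear interpolation about the image
centre `((H+1)/2, (W+1)/2)`; the same centre convention transforms
ground-truth box corners, so segmentation accuracy can be asserted in
the rotated frame. Round-trip interpolation error on smooth intensity
fields is below 0.1% of the wave amplitude (sharp chamber edges locally
reach a few percent, as any interpolating rotation does).

**Segmentation.** Chambers are the Cartesian product of high intervals
of the smoothed (5 px moving average) row- and column-sum profiles of a
reference image (time average by default, temporal STD selectable).
Intervals are found by *hysteresis*: seeded where the profile crosses
the midpoint between its background and foreground plateaus (10% and
90% quantiles), grown while it stays above background + 0.15 × range. A
plain midpoint cut splits oscillation chambers, whose time average dips
between the dwell zones; the dips stay far above the inter-chamber
background, so the hysteresis keeps them in one piece. Boxes whose
interior mean is below 1.2 × the outside-background level are dropped.
Boxes are 1-based inclusive `(r0, r1, c0, c1)`, the natural R indexing
convention.

**Background.** Per chamber, one scalar — the mean over all pixels and
frames — is subtracted, read as such ("the average intensity in each
chamber") rather than a per-pixel temporal mean so static illumination
gradients remain visible in quadrant views; a per-pixel mode is
available (`subtract_background(mode = "pixel")`). Negative values are
preserved.

## Classification

Every classifier decision is taken on the **phase map**: the per-pixel
argument of the dominant temporal Fourier component (the non-zero
frequency bin with the largest total spectral power over the chamber).
If no bin exceeds twice the median bin power, or the dominant period
exceeds half the movie (fewer than two full cycles — too little data
for a stable phase), the chamber is `unclassified`. The cascade is:

1. **Rotation** — one or more interior phase singularities: 2×2
   plaquettes whose wrapped phase differences wind by ±2π. Three
   guards matter in practice: (i) pixels whose dominant-frequency
   amplitude is below a quarter of the 90th percentile carry noise
   phase and are masked out; (ii) plaquettes with any single edge jump
   above 0.9π sit on antiphase discontinuity lines (standing patterns),
   where noise flips wraps at random, and are discarded — a genuine
   core winds smoothly at about π/2 per edge; (iii) detections are
   merged by single-linkage clustering within λ/4 and clusters with
   zero net charge (noise dipoles) are dropped. Several cores still
   count as one rotation chamber.
2. **Drifting core** — a core found in both movie halves but displaced
   by more than half the chamber length is a front sweeping through,
   not a pinned spiral; it is re-tagged `traveling_wave`. The L/2
   displacement threshold is this package's operationalisation.
3. **Oscillation** — the mirror-coherence score. For each chamber axis
   the circular mean of `exp(i(φ − φ_mirrored))` is computed,
   amplitude-weighted. Pole-to-pole modes are mirror-*antiphase*
   (difference π); striped modes, whose dominant frequency is a
   harmonic of the shuttling period because three bands pass each
   point per half-cycle, are mirror-*in-phase*. Both are standing
   patterns, so the score uses the coherence magnitude, with one guard:
   an axis along which the phase barely varies (the cross axis of a
   plane wave is trivially mirror-symmetric) is rejected by requiring
   the circular spread of the per-line phase angles along the axis to
   exceed 0.3. Threshold 0.6. A wave whose visible span along the
   propagation axis is much shorter than λ/4 genuinely approaches a
   synchronous blink and would be scored as standing; chambers that
   short cannot carry a measurable wave in any case.
4. **Traveling wave** — the phase fits a spatial plane: wrapped phase
   gradients are averaged (amplitude-weighted circular mean), and the
   weighted RMS residual about the implied plane must be below
   0.25 × 2π.
5. Otherwise `unclassified`.

All thresholds are config-exposed defaults tuned on the synthetic
suite; they are implementation choices, not measured constants. The
features (dominant frequency, planarity, coherence, winding count) are
returned with every label for auditability. Classification is invariant
to intensity scaling and offsets by construction, and mirror reflection
preserves labels while flipping spiral chirality.

## Wavelength and velocity

**Direction** is the angle of the negated mean spatial phase gradient
(the phase of `cos(ωt − ku)` is `−ku`); for rotations, the local
gradient half a wavelength from the core gives the tangential
direction.

**Wavelength**: intensities are sampled along a centre line in the
propagation direction (averaged over 5 parallel lines to suppress
pixel noise), one kymograph row per frame. Per row, local maxima with
prominence ≥ 0.5 × the row SD are detected after a 5 px moving-average
smooth (noise spikes are single-pixel; real crests span tens of
pixels). Consecutive peak spacings are pooled over all rows — pooled
after detection — histogrammed in 2 px bins, and a Gaussian is fitted
by least squares; its mean × pixel size is λ. Spacings beyond the
chamber diagonal are discarded as artefacts. If every row holds fewer
than two peaks the wavelength is *undefined* — the legal outcome for a
chamber shorter than λ. If the fit degenerates (noise-free movies give
a single-bin histogram), the sample mean ± SD is reported with a flag.
For unconfined flat-bilayer movies the line is supplied manually,
mirroring the hand-drawn line of that procedure.

**Velocity, shear estimator**: on the binary peak kymograph, row *t*
is displaced by −s·t for candidate slopes s; at the true slope the
peak trajectories stack vertically and the mean per-column SD of the
sheared image is minimal. v = |s*| × pixel size / frame interval. A
shear is used instead of a rigid rotation deliberately: the kymograph
axes carry different units, and a shear preserves the per-line
(constant-time) reading while giving the same argmin at small angles.
Two numerical points: (i) peak marks are widened by a 5 px smooth
before shearing — per-row detection jitters by a few pixels and
point-like marks never overlap; (ii) the slope is seeded by the
aggregate cross-correlation between consecutive rows and the shear
objective is only scanned within ±1.2 px/frame of the seed at
0.02 px/frame. The narrow window is essential: on a canvas that grows
with the shear, sparse columns at extreme slopes fake low SDs, so a
global scan can run away to the grid edge. The seed is unambiguous
while fronts advance less than half a peak spacing per frame. The
slope uncertainty comes from the curvature of a parabola fitted
through the objective around its minimum, against the parabola's
residual scatter; a flat objective (stationary pattern) reports v = 0
with an SD spanning the grid.

**Velocity, tracking estimator** (independent cross-check): per frame,
the intensity-weighted centroid of the *brightest connected*
suprathreshold (Otsu) region — one band — is tracked; v is the mean
step magnitude over frames. Steps above λ/2 (the tracked band handing
over to the next at the chamber edge) and steps in which the band
touches the frame edge perpendicular to its motion (truncated bands
have edge-biased centroids) are discarded. Tracking the whole
suprathreshold region would not work: for a periodic wave train in a
fixed window the global centroid merely oscillates.

The two estimators agree within 10% on generated waves across the
speed range of the study conditions, and λ/v reproduces the generative
temporal period. Wavelength estimates are invariant to intensity
scaling, offset, and time reversal. Within-chamber spread (the
Gaussian σ) and chamber-to-chamber spread are reported separately.

## Concentration inference

Chamber concentrations of the Min proteins cannot be read off the
injection syringe: membrane binding accumulates protein while solution
keeps flowing in. The inference compares each labeled species'
microscope signal with that of co-injected GFP — which does not bind
the membrane, so its chamber concentration is known — referenced
against fluorometer calibration curves. A detector signal is
`S = C·B·Q_eff·I·τ`; writing `F = Q_eff·I·τ`, all brightnesses and
instrument factors collapse into the dimensionless factor

```
F(C) = (S_GFP_flu / S_Min_flu(C)) · (F_flu / F_mic) · (S_Min_mic / S_GFP_mic)
```

whose unit value pins the chamber concentration: `C_chamber` is the
`C` at which `F(C) = 1`. The package exposes both solution strategies:
direct substitution (closed form, valid for linear-through-origin
calibration curves) and the bracketed root solve of `F(C) − 1` over
the calibration range (uniroot, tolerance 10⁻³ µM), which also handles
the nonlinear MinD-Cy3 response. That nonlinearity — plausibly a
dequenching effect with no known functional form — is handled by a
shape-preserving monotone cubic interpolant (Fritsch–Carlson) rather
than a parametric quench model; extrapolation beyond the calibrated
range is linear and flagged. Monotonicity is validated at fit time
(the offending point pair is named), which guarantees a unique root.
Instrument factor ratios default to 1 with config override — they are
machine constants that cancel whenever both species are measured on
the same pair of instruments. A degree-of-labeling factor (0.88 for
Cy3 per MinD, 0.45 for Cy5 per MinE) optionally converts
labeled-species to total-protein concentration; it is off by default
because the factor equation operates on the labeled species' signal
throughout.

## Phase diagram

Per-chamber labels aggregate into tiles keyed by the *designed*
`(W, L)` values (the pipeline snaps measured sizes to the 10 µm design
grid), not measured pixel sizes. A tile's majority label requires at
least 4 classified chambers (`min_n = 4`); exact plurality ties are
reported as `"tie"` rather than silently resolved, and unclassified
chambers are tallied in their own column without voting. Selection
histograms slice the same rows by width, length, aspect ratio L/W
(rounded to 0.1) or area. Multi-core rotations are merged with single
spirals in the counts, as the tagging rule dictates.

## Problem sizes and determinism

The validation suite runs entirely on generated data: recovery
experiments use 60–90 frame movies of 100×120 px chambers or
200×200 px unconfined fields, and the classifier benchmark uses 200
movies of 40 frames at SNR 5 plus a clean cohort that must classify
perfectly. These sizes put every estimator at least an order of
magnitude above its resolution limits while keeping the whole suite
runnable in minutes on one CPU. All stochastic stages derive their
RNG streams from explicit seeds; pipeline reruns on identical inputs
are byte-identical.

## Known limitations

* The generators are kinematic; agreement of an estimator with
  generative truth does not test robustness to bleaching, drift, or
  uneven illumination.
* The classifier assumes one dominant temporal frequency per chamber;
  superposed patterns (e.g. a wave crossing a weak spiral) resolve to
  whichever component carries more spectral power.
* Velocity from the shear estimator is resolution-limited for
  displacements well under a pixel per frame; at the viscous-condition
  speed (0.4 px/frame at 10 s sampling) it still recovers truth, but
  slower patterns would need longer movies.
* `count_phase_singularities` reports merged, net-charged clusters;
  tightly bound spiral pairs of opposite chirality (separation < λ/4)
  cancel and are not counted.
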