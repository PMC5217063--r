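# minwaves

Quantitative analysis of MinD/MinE reaction–diffusion patterns in
time-lapse fluorescence movies of fully confined, bilayer-coated
microchambers — for experimentalists reconstituting the *E. coli* Min
system in vitro and for modellers who need geometry-resolved pattern
statistics to constrain reaction–diffusion models.

Inside 2.4 µm-high chambers (widths 10–60 µm, lengths 10–90 µm) the Min
proteins form three pattern genera depending on geometry: pole-to-pole
(and striped) **oscillations**, **spiral rotations** around a pinned
core, and **traveling waves**. `minwaves` implements the full
measurement chain:

* **Synthetic movies** with exact ground truth (traveling plane waves,
  single/multi-core spirals, pole-to-pole and striped oscillations,
  multi-chamber fields with rigid rotation) — every estimator in the
  package is validated by parameter recovery against them.
* **Preprocessing** — field rotation correction (minimising the per-row
  SD of the time-averaged image over an angle grid), chamber
  segmentation from marginal intensity profiles, Otsu thresholding,
  per-chamber scalar background subtraction.
* **Quadrant summaries** — representative frame, temporal-STD image,
  and the Xt/Yt mid-line kymographs in the standard four-pane layout.
* **Classification** — a deterministic cascade on the per-pixel phase
  of the dominant temporal Fourier component: phase singularities
  (winding number ±1) ⇒ rotation; mirror-coherent standing phase ⇒
  oscillation; spatially planar phase ⇒ traveling wave; drifting cores
  re-tagged as waves; no dominant frequency ⇒ unclassified.
* **Wave metrics** — wavelength λ from a Gaussian fit to the histogram
  of consecutive kymograph peak spacings; front velocity v from shear
  minimisation of the peak kymograph (the slope aligning peak
  trajectories), cross-checked by tracking the brightest wave band.
* **Concentration inference** — chamber concentrations of the labeled
  Min proteins from their fluorescence relative to co-injected GFP
  (whose chamber concentration is always the injected one), via the
  dimensionless factor
  `F(C) = (S_GFP^flu / S_Min^flu(C)) · (F^flu/F^mic) · (S_Min^mic / S_GFP^mic)`
  solved at `F(C) = 1`; linear and monotone-nonlinear calibration
  curves supported.
* **Phase diagrams** — per-(W, L) tile majorities (≥ 4 chambers per
  tile, ties reported) and geometry-selection histograms by width,
  length, aspect ratio and area.

## Worked example

Generate a confined traveling wave with known ground truth
(λ = 43 µm, v = 0.3 µm/s in a 60 × 50 µm chamber at 0.5 µm/px and
10 s frames, noise at 10% of the wave amplitude), then classify and
measure it:

```r
library(minwaves)

geom <- chamber_geometry(width_um = 50, length_um = 60, pixel_size_um = 0.5)
spec <- pattern_spec("traveling_wave", wavelength_um = 43, speed_um_s = 0.3,
                     amplitude = 100, background = 20, noise_sd = 10, seed = 7)
movie <- generate_traveling_wave(geom, spec, n_frames = 60, frame_interval_s = 10)
movie
#> <min_movie> 100 x 120 px, 60 frames | 0.5 um/px, 10 s/frame (60 x 50 um, 590 s)

chamber <- subtract_background(movie)
classify_pattern(chamber)$label
#> [1] "traveling_wave"

w <- measure_wave(chamber)
```

which prints

```
wavelength: 43.2 +/- 2.7 um (8 peak pairs)
velocity (shear): 0.307 um/s | (tracking): 0.300 um/s
```

The wavelength (43.2 µm) is the mean of the Gaussian fitted to the
pooled consecutive-peak spacings of the kymograph, ±σ of that fit; the
two velocities come from the independent shear-minimisation and
band-tracking estimators and agree with the generative 0.3 µm/s to
about 2%. The temporal period implied by λ/v (≈ 143 s) matches the
movie's dominant Fourier period (150 s at the 10 s frame resolution).

## Analysis workflow

The `analysis/` scripts run the package end to end on synthetic data
and write tables and figures under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | 2 × 3 chamber field (waves, spirals, oscillations), rotated 2°, written as TIFF + YAML |
| `02_segment_classify.R` | full pipeline: rotation, segmentation, quadrants, classification vs ground truth |
| `03_wave_metrics.R` | λ and v recovery under each study condition (confined/flat, room T/viscous/37 °C) |
| `04_concentration.R` | GFP-referenced concentration inference, MinE:MinD ratio, enrichment |
| `05_phase_diagram.R` | 240-chamber cohort → selection histograms and the (W, L) phase diagram |

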