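#' Parameter-recovery benchmark: confined chamber wave
#'
#' Generates a traveling wave in a confined chamber (length 60 µm along
#' the propagation axis, width 50 µm, 0.5 µm/px, 10 s frames) with the
#' requested ground-truth wavelength and speed plus Gaussian noise, and
#' runs the full measurement chain (direction estimate, propagation
#' kymograph, peak-spacing wavelength, shear-minimisation and tracking
#' velocities). Used to check that the estimators recover the reported
#' in-chamber pattern statistics when those are used as generative
#' truth.
#'
#' @param wavelength_um,speed_um_s generative ground truth.
#' @param n_frames number of frames (10 s apart).
#' @param noise_frac noise SD as a fraction of the wave amplitude.
#' @param seed reproducibility seed for the noise.
#' @param width_um,length_um chamber size.
#' @return The [measure_wave()] tibble plus `true_wavelength_um` and
#'   `true_velocity_um_s` columns.
#' @export
benchmark_confined_wave <- function(wavelength_um, speed_um_s,
                                    n_frames = 60L, noise_frac = 0.1,
                                    seed = 1L, width_um = 50,
                                    length_um = 60) {
  geom <- chamber_geometry(width_um, length_um, pixel_size_um = 0.5)
  spec <- pattern_spec("traveling_wave", wavelength_um = wavelength_um,
                       speed_um_s = speed_um_s, amplitude = 100,
                       background = 20, noise_sd = 100 * noise_frac,
                       seed = seed)
  m <- generate_traveling_wave(geom, spec, n_frames, 10)
  out <- measure_wave(subtract_background(m))
  out$true_wavelength_um <- wavelength_um
  out$true_velocity_um_s <- speed_um_s
  out
}

#' Parameter-recovery benchmark: flat supported-bilayer wave
#'
#' As [benchmark_confined_wave()] but on an unconfined 200 x 200 µm
#' field at 1 µm/px, with the propagation line supplied manually along
#' the wave direction (the flat-bilayer procedure: no chamber walls, so
#' the line is drawn by hand).
#'
#' @inheritParams benchmark_confined_wave
#' @return The [measure_wave()] tibble plus ground-truth columns.
#' @export
benchmark_flat_slb_wave <- function(wavelength_um, speed_um_s,
                                    n_frames = 60L, noise_frac = 0.1,
                                    seed = 1L) {
  geom <- chamber_geometry(200, 200, pixel_size_um = 1)
  spec <- pattern_spec("traveling_wave", wavelength_um = wavelength_um,
                       speed_um_s = speed_um_s, amplitude = 100,
                       background = 20, noise_sd = 100 * noise_frac,
                       seed = seed)
  m <- generate_traveling_wave(geom, spec, n_frames, 10)
  mb <- subtract_background(m)
  H <- nrow(mb$data)
  line <- list(start = c((H + 1) / 2, 3), end = c((H + 1) / 2, ncol(mb$data) - 2))
  out <- measure_wave(mb, line = line)
  out$true_wavelength_um <- wavelength_um
  out$true_velocity_um_s <- speed_um_s
  out
}

#' Classifier agreement benchmark
#'
#' Generates a cohort with [generate_cohort()], classifies every movie
#' and returns the agreement with the generative labels.
#'
#' @inheritParams generate_cohort
#' @return A list: `accuracy`, `confusion` (table), `n`.
#' @export
benchmark_classifier <- function(n = 200L, noise_frac = 0.2, seed = 1L) {
  coh <- generate_cohort(n, noise_frac = noise_frac, seed = seed)
  preds <- vapply(coh, function(r)
    classify_pattern(subtract_background(r$movie))$label, character(1))
  truth <- vapply(coh, function(r) r$true_label, character(1))
  list(accuracy = mean(preds == truth),
       confusion = table(truth = truth, predicted = preds), n = n)
}

#' Concentration-inference benchmark against the reported chamber means
#'
#' Reconstructs the GFP-referenced inference for both Min species in a
#' synthetic measurement scenario whose ground truth is set to the
#' reported chamber concentrations: linear fluorometer response for
#' MinE-Cy5, a saturating (monotone, nonlinear) response for MinD-Cy3,
#' and microscope signals constructed from the ground-truth enrichment.
#' The `F = 1` solve must recover the chamber concentrations, from
#' which the MinE:MinD ratio and the mean enrichment over the injected
#' stocks follow.
#'
#' @return A tibble with one row per species: injected and recovered
#'   chamber concentrations and the enrichment factor; attributes
#'   `ratio_E_over_D` and `mean_enrichment`.
#' @export
benchmark_concentration <- function() {
  ref <- min_reference_concentrations()
  conc <- seq(0.25, 30, by = 0.25)
  curves <- list(
    MinD = fit_calibration(
      data.frame(concentration_uM = conc, signal = 40 * conc / (1 + conc / 12)),
      "monotone_interpolation", species = "MinD_Cy3"),
    MinE = fit_calibration(
      data.frame(concentration_uM = conc, signal = 25 * conc),
      "linear_through_origin", species = "MinE_Cy5"))
  S_gfp_flu <- 120; S_gfp_mic <- 900
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    sp <- ref$species[i]
    truth <- ref$chamber_uM[i]
    # microscope Min signal implied by the ground-truth chamber
    # concentration (identical instrument factor ratios)
    sig <- list(S_min_mic = S_gfp_mic * curves[[sp]](truth) / S_gfp_flu,
                S_gfp_mic = S_gfp_mic, S_gfp_flu = S_gfp_flu)
    est <- infer_concentration(sig, curves[[sp]])
    tibble::tibble(species = sp, injected_uM = ref$injected_uM[i],
                   true_chamber_uM = truth, recovered_uM = est$C_uM,
                   enrichment = est$C_uM / ref$injected_uM[i])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ratio_E_over_D") <-
    out$recovered_uM[out$species == "MinE"] /
    out$recovered_uM[out$species == "MinD"]
  attr(out, "mean_enrichment") <- mean(out$enrichment)
  out
}
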