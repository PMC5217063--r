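#' Reported Min pattern statistics used as generative ground truth
#'
#' Mean and SD of the measured wavelength and front-propagation velocity
#' of in-vitro Min patterns under the study conditions this package's
#' synthetic benchmarks emulate: traveling waves in fully confined
#' microchambers and on flat supported lipid bilayers (SLB), at room
#' temperature and at 37 °C, and in chambers with a ~10 cP crowded
#' medium. These values parameterise the parameter-recovery experiments
#' (the generators are run with these means as ground truth and the
#' estimators must recover them) and the derived temporal-period
#' arithmetic.
#'
#' @return A tibble with columns `condition`, `confinement`,
#'   `wavelength_um`, `wavelength_sd_um`, `velocity_um_s`,
#'   `velocity_sd_um_s`, `n_wavelength`, `n_velocity`.
#' @export
min_reference_conditions <- function() {
  tibble::tribble(
    ~condition,            ~confinement, ~wavelength_um, ~wavelength_sd_um,
    ~velocity_um_s, ~velocity_sd_um_s, ~n_wavelength, ~n_velocity,
    "room_temp",           "chamber",    43,  6,  0.3,  0.1,  35, 333,
    "room_temp",           "flat_slb",   78, 12,  0.6,  0.2,  30,  30,
    "viscous_10cP",        "chamber",    23,  4,  0.02, 0.014, 17,  17,
    "37C",                 "chamber",    37,  9,  0.5,  0.3,  34, 162,
    "37C",                 "flat_slb",   48,  6,  1.4,  NA,   27,  27
  )
}

#' Reported Min protein concentrations in the chambers
#'
#' Injected stock concentrations and the GFP-calibrated chamber
#' concentrations (mean ± SD over 52 chambers) of MinD and MinE. The
#' chamber values exceed the injected ones because membrane binding
#' accumulates protein while fresh solution keeps flowing in during
#' loading.
#'
#' @return A tibble with columns `species`, `injected_uM`,
#'   `chamber_uM`, `chamber_sd_uM`, `n_chambers`.
#' @export
min_reference_concentrations <- function() {
  tibble::tribble(
    ~species, ~injected_uM, ~chamber_uM, ~chamber_sd_uM, ~n_chambers,
    "MinD",   1.08,         4.5,         0.5,            52,
    "MinE",   1.00,         6.0,         3.0,            52
  )
}
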