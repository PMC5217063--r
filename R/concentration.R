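#' Fit a fluorometer calibration curve
#'
#' Relates a fluorescent species' bulk concentration to its
#' background-subtracted fluorometer signal. Two models are supported:
#' a least-squares line through the origin (adequate for MinE-Cy5 and
#' GFP, whose response is linear) and a shape-preserving monotone cubic
#' interpolant (Fritsch-Carlson) for nonlinear responses such as
#' MinD-Cy3, with linear extrapolation beyond the calibrated range.
#'
#' @param points data frame with columns `concentration_uM` (strictly
#'   increasing) and `signal` (non-negative, non-decreasing); at least 3
#'   points.
#' @param model `"linear_through_origin"` or `"monotone_interpolation"`.
#' @param species optional label stored on the curve.
#' @return An object of class `calibration_curve`; call it like a
#'   function, `curve(conc_uM)`, to evaluate the signal. Attributes
#'   `range_uM` and `slope` (linear model only) are set.
#' @export
fit_calibration <- function(points,
                            model = c("linear_through_origin",
                                      "monotone_interpolation"),
                            species = NULL) {
  model <- match.arg(model)
  stopifnot(nrow(points) >= 3,
            all(c("concentration_uM", "signal") %in% names(points)))
  cc <- points$concentration_uM
  ss <- points$signal
  if (any(diff(cc) <= 0)) stop("concentrations must be strictly increasing")
  if (any(ss < 0)) stop("signals must be non-negative")
  bad <- which(diff(ss) < 0)
  if (model == "monotone_interpolation" && length(bad) > 0)
    stop(sprintf(
      "signal decreases between %.4g and %.4g uM: not monotone",
      cc[bad[1]], cc[bad[1] + 1]))
  if (model == "linear_through_origin") {
    slope <- sum(cc * ss) / sum(cc^2)
    f <- function(conc_uM) slope * conc_uM
  } else {
    interp <- stats::splinefun(cc, ss, method = "monoH.FC")
    # linear extrapolation with the end-point derivatives
    d_lo <- interp(cc[1], deriv = 1); d_hi <- interp(cc[length(cc)], deriv = 1)
    f <- function(conc_uM) {
      out <- interp(conc_uM)
      lo <- conc_uM < cc[1]; hi <- conc_uM > cc[length(cc)]
      out[lo] <- ss[1] + d_lo * (conc_uM[lo] - cc[1])
      out[hi] <- ss[length(ss)] + d_hi * (conc_uM[hi] - cc[length(cc)])
      out
    }
    slope <- NULL
  }
  structure(f, class = c("calibration_curve", "function"),
            model = model, species = species,
            range_uM = range(cc), slope = slope, points = points)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s, %s, range %.3g-%.3g uM\n",
              attr(x, "species") %||% "?", attr(x, "model"),
              attr(x, "range_uM")[1], attr(x, "range_uM")[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instrument factor ratios
#'
#' The detector quantum efficiency, source intensity and exposure time
#' enter the signal equation `S = C * B * Qeff * I * tau` only through
#' the product `F = Qeff * I * tau`; what matters for concentration
#' inference are the Min-to-GFP ratios of `F` on the microscope and on
#' the fluorometer. Both default to 1 (identical optical factors), with
#' overrides for instruments whose specs are known.
#'
#' @param F_mic_ratio `F_Min / F_GFP` on the microscope.
#' @param F_flu_ratio `F_Min / F_GFP` on the fluorometer.
#' @return A list of class `instrument_factors`.
#' @export
instrument_factors <- function(F_mic_ratio = 1, F_flu_ratio = 1) {
  stopifnot(F_mic_ratio > 0, F_flu_ratio > 0)
  structure(list(F_mic_ratio = F_mic_ratio, F_flu_ratio = F_flu_ratio),
            class = "instrument_factors")
}

#' The dimensionless concentration factor
#'
#' For a candidate bulk concentration `C`, evaluates
#' `F(C) = (S_GFP_flu / S_Min_flu(C)) * (F_flu_ratio / F_mic_ratio) *
#' (S_Min_mic / S_GFP_mic)`,
#' the factor by which the chamber concentration exceeds the candidate
#' bulk value. The species brightness cancels in this combination, so it
#' never needs to be known. The chamber concentration is the value of
#' `C` at which `F(C) = 1`.
#'
#' @param C_candidate candidate concentration(s) in micromolar.
#' @param signals named list with `S_min_mic`, `S_gfp_mic` (microscope)
#'   and `S_gfp_flu` (fluorometer), all background-subtracted and
#'   positive.
#' @param curve the Min species' [fit_calibration()] curve giving
#'   `S_Min_flu(C)`.
#' @param factors an [instrument_factors()] object.
#' @return Numeric vector of factor values; the attribute
#'   `extrapolated` flags candidates outside the calibration range.
#' @export
script_F <- function(C_candidate, signals, curve,
                     factors = instrument_factors()) {
  stopifnot(signals$S_min_mic > 0, signals$S_gfp_mic > 0,
            signals$S_gfp_flu > 0)
  s_flu <- curve(C_candidate)
  if (any(s_flu <= 0))
    stop("calibration signal non-positive at the candidate concentration")
  out <- (signals$S_gfp_flu / s_flu) *
    (factors$F_flu_ratio / factors$F_mic_ratio) *
    (signals$S_min_mic / signals$S_gfp_mic)
  rng <- attr(curve, "range_uM")
  attr(out, "extrapolated") <- C_candidate < rng[1] | C_candidate > rng[2]
  out
}

#' Infer the chamber concentration of a Min species
#'
#' Two mathematically equivalent strategies are exposed. The default
#' (`"root"`) solves `F(C) - 1 = 0` by bracketed bisection over the
#' calibration range (tolerance `1e-3` uM), which accommodates
#' nonlinear calibration curves. `"direct"` substitutes the signals into
#' the closed-form solution valid for a linear-through-origin curve; for
#' linear curves the two agree to the solver tolerance.
#'
#' @inheritParams script_F
#' @param strategy `"root"` or `"direct"`.
#' @param tol_uM bisection tolerance in micromolar.
#' @param labeling_factor degree of labeling of the imaged species
#'   (e.g. 0.88 for Cy3 per MinD, 0.45 for Cy5 per MinE). The solve
#'   operates on the labeled-species signal; dividing its result by this
#'   factor converts it to total-protein concentration. The default 1
#'   leaves the labeled-species scale untouched.
#' @return A list: `C_uM`, `F_at_solution` (1 up to tolerance for the
#'   root strategy), `strategy`, `extrapolated`.
#' @export
infer_concentration <- function(signals, curve,
                                factors = instrument_factors(),
                                strategy = c("root", "direct"),
                                tol_uM = 1e-3, labeling_factor = 1) {
  stopifnot(labeling_factor > 0, labeling_factor <= 1)
  strategy <- match.arg(strategy)
  rng <- attr(curve, "range_uM")
  if (strategy == "direct") {
    slope <- attr(curve, "slope")
    if (is.null(slope))
      stop("direct substitution requires a linear-through-origin curve")
    C <- (signals$S_gfp_flu / slope) *
      (factors$F_flu_ratio / factors$F_mic_ratio) *
      (signals$S_min_mic / signals$S_gfp_mic)
  } else {
    g <- function(C) script_F(C, signals, curve, factors) - 1
    lo <- max(rng[1], tol_uM); hi <- rng[2]
    if (g(lo) * g(hi) > 0)
      stop("F - 1 does not change sign over the calibration range: ",
           "out of calibration range")
    C <- stats::uniroot(g, c(lo, hi), tol = tol_uM)$root
  }
  list(C_uM = C / labeling_factor,
       F_at_solution = as.numeric(script_F(C, signals, curve, factors)),
       strategy = strategy,
       extrapolated = C < rng[1] || C > rng[2])
}
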