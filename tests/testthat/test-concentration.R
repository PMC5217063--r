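test_that("calibration fits are exact on their defining cases", {
  pts <- data.frame(concentration_uM = c(1, 2, 4, 8), signal = c(2, 4, 8, 16))
  lin <- fit_calibration(pts, "linear_through_origin")
  expect_equal(attr(lin, "slope"), 2)
  expect_equal(lin(c(3, 5)), c(6, 10))
  mono <- fit_calibration(pts, "monotone_interpolation")
  # interpolation property: calibration points reproduced exactly
  expect_equal(mono(pts$concentration_uM), pts$signal)
  # saturating curve: interpolant within 2% at midpoints
  conc <- seq(0.5, 30, 0.5)
  sat <- function(C) C / (1 + C / 10)
  curve <- fit_calibration(data.frame(concentration_uM = conc,
                                      signal = sat(conc)),
                           "monotone_interpolation")
  mids <- conc[-length(conc)] + 0.25
  expect_lt(max(abs(curve(mids) - sat(mids)) / sat(mids)), 0.02)
})

test_that("non-monotone points are rejected with the offending pair named", {
  pts <- data.frame(concentration_uM = c(1, 2, 3, 4), signal = c(2, 5, 4, 6))
  expect_error(fit_calibration(pts, "monotone_interpolation"), "2 and 3")
  expect_error(fit_calibration(pts[1:2, ], "linear_through_origin"), "3")
})

test_that("the concentration factor obeys its algebraic identities", {
  curve <- linear_curve(slope = 2)
  sig <- list(S_min_mic = 400, S_gfp_mic = 500, S_gfp_flu = 50)
  # linear curve: F(C) = k / C, so F(2) / F(4) = 2
  expect_equal(as.numeric(script_F(2, sig, curve) / script_F(4, sig, curve)), 2)
  # doubling S_min_mic doubles F at every C
  sig2 <- sig; sig2$S_min_mic <- 800
  for (C in c(1, 3, 7))
    expect_equal(as.numeric(script_F(C, sig2, curve)),
                 2 * as.numeric(script_F(C, sig, curve)))
  # identity configuration: F(C_injected) = 1
  inj <- 1.5
  sigI <- list(S_min_mic = 500 * curve(inj) / 50, S_gfp_mic = 500,
               S_gfp_flu = 50)
  expect_equal(as.numeric(script_F(inj, sigI, curve)), 1)
})

test_that("the F = 1 solve returns injected and enriched concentrations", {
  curve <- linear_curve(slope = 2)
  inj <- 1.0
  S_gfp_flu <- 50; S_gfp_mic <- 500
  base_mic <- S_gfp_mic * curve(inj) / S_gfp_flu
  # identity configuration
  r <- infer_concentration(list(S_min_mic = base_mic, S_gfp_mic = S_gfp_mic,
                                S_gfp_flu = S_gfp_flu), curve)
  expect_equal(r$C_uM, inj, tolerance = 1e-3)
  expect_equal(r$F_at_solution, 1, tolerance = 1e-3)
  # 5-fold membrane enrichment
  r5 <- infer_concentration(list(S_min_mic = 5 * base_mic,
                                 S_gfp_mic = S_gfp_mic,
                                 S_gfp_flu = S_gfp_flu), curve)
  expect_equal(r5$C_uM, 5 * inj, tolerance = 1e-3)
  # root solve and direct substitution agree for linear curves
  rd <- infer_concentration(list(S_min_mic = 5 * base_mic,
                                 S_gfp_mic = S_gfp_mic,
                                 S_gfp_flu = S_gfp_flu), curve,
                            strategy = "direct")
  expect_equal(r5$C_uM, rd$C_uM, tolerance = 1e-3)
  # optional degree-of-labeling correction scales the result to total
  # protein (labeled fraction 0.5 -> twice the labeled concentration)
  rl <- infer_concentration(list(S_min_mic = 5 * base_mic,
                                 S_gfp_mic = S_gfp_mic,
                                 S_gfp_flu = S_gfp_flu), curve,
                            labeling_factor = 0.5)
  expect_equal(rl$C_uM, 2 * r5$C_uM, tolerance = 1e-3)
})

test_that("inference is invariant to rescaling one instrument's signals", {
  curve <- linear_curve(slope = 3)
  sig <- list(S_min_mic = 500, S_gfp_mic = 400, S_gfp_flu = 60)
  base <- infer_concentration(sig, curve)$C_uM
  # common factor on both microscope channels cancels (brightness and
  # machine factors drop out of the ratio)
  sig_mic <- list(S_min_mic = 500 * 3.3, S_gfp_mic = 400 * 3.3,
                  S_gfp_flu = 60)
  expect_equal(infer_concentration(sig_mic, curve)$C_uM, base,
               tolerance = 1e-6)
})

test_that("instrument factor ratios shift the root as the model says", {
  curve <- linear_curve(slope = 2)
  sig <- list(S_min_mic = 400, S_gfp_mic = 500, S_gfp_flu = 50)
  r1 <- infer_concentration(sig, curve)$C_uM
  r2 <- infer_concentration(sig, curve,
                            factors = instrument_factors(F_mic_ratio = 2))$C_uM
  expect_equal(r2, r1 / 2, tolerance = 1e-3)
})

test_that("a root outside the calibration range is refused", {
  conc <- seq(1, 5, 1)
  curve <- fit_calibration(data.frame(concentration_uM = conc,
                                      signal = 2 * conc),
                           "linear_through_origin")
  sig <- list(S_min_mic = 5000, S_gfp_mic = 10, S_gfp_flu = 50)
  expect_error(infer_concentration(sig, curve), "calibration range")
})
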