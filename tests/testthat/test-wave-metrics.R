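test_that("direction estimation recovers the generative angle", {
  for (th in c(0, 30)) {
    m <- subtract_background(wave_movie(W = 50, L = 60, direction_deg = th,
                                        noise_sd = 5, seed = th + 1))
    expect_equal(estimate_direction(m), th, tolerance = 2)
  }
  # reversing propagation flips the estimate by 180 degrees
  fwd <- subtract_background(wave_movie(direction_deg = 0, seed = 3))
  rev_ <- fwd; rev_$data <- fwd$data[, , rev(seq_len(dim(fwd$data)[3]))]
  d1 <- estimate_direction(fwd); d2 <- estimate_direction(rev_)
  expect_equal(abs(wrap_phase((d1 - d2) * pi / 180)), pi, tolerance = 0.08)
})

test_that("propagation kymographs sample the movie faithfully", {
  m <- subtract_background(wave_movie(W = 30, L = 60, n_frames = 12))
  k <- propagation_kymograph(m, start = c(30, 5), end = c(30, 110),
                             band_px = 1)
  expect_equal(nrow(k), 12)
  # row t equals the frame values along the integer-pixel line
  expect_equal(k[4, ], m$data[30, 5:110, 4], tolerance = 1e-9)
  expect_error(propagation_kymograph(m, c(10, 10), c(10, 12)), "4 px")
  # static movie: zero column variance
  pat <- matrix(sin(seq_len(900)), 30, 30)
  st <- min_movie(array(rep(pat, 5), c(30, 30, 5)), 0.5, 10)
  ks <- propagation_kymograph(st, c(15, 2), c(15, 28), band_px = 1)
  expect_lt(max(apply(ks, 2, sd)), 1e-9)
})

test_that("wavelength estimation is exact on noiseless kymographs", {
  m <- subtract_background(wave_movie(wavelength_um = 40, speed_um_s = 0.5,
                                      W = 30, L = 90))
  k <- propagation_kymograph(m, c(30, 2), c(30, 178))
  wl <- estimate_wavelength(k, 0.5)
  expect_equal(wl$wavelength_um, 40, tolerance = 0.5)
  expect_gte(wl$n_pairs, 1)
})

test_that("wavelength is undefined for chambers shorter than the wavelength", {
  m <- subtract_background(wave_movie(wavelength_um = 43, W = 20, L = 30,
                                      n_frames = 30))
  k <- propagation_kymograph(m, c(20, 2), c(20, 58))
  wl <- estimate_wavelength(k, 0.5)
  expect_equal(wl$method, "undefined")
  expect_true(is.na(wl$wavelength_um))
})

test_that("wavelength estimate is invariant to scaling, offset, time reversal", {
  m <- subtract_background(wave_movie(noise_sd = 10, seed = 8))
  k <- propagation_kymograph(m, c(50, 2), c(50, 118))
  base <- estimate_wavelength(k, 0.5)
  expect_equal(estimate_wavelength(5 * k + 30, 0.5)$wavelength_um,
               base$wavelength_um)
  expect_equal(estimate_wavelength(k[rev(seq_len(nrow(k))), ], 0.5)$wavelength_um,
               base$wavelength_um)
})

test_that("shear-minimisation velocity matches exact constructions", {
  # peaks advancing exactly 1 px/frame at 0.5 um/px and 10 s frames
  pk <- matrix(FALSE, 20, 60)
  for (t in 1:20) pk[t, c(10, 40) + (t - 1)] <- TRUE
  v <- estimate_velocity_kymo_rotation(pk, 0.5, 10)
  expect_lt(abs(v$velocity_um_s - 0.05), 0.002)
  # stationary peaks
  pk0 <- matrix(FALSE, 20, 60); pk0[, c(15, 45)] <- TRUE
  v0 <- estimate_velocity_kymo_rotation(pk0, 0.5, 10)
  expect_equal(v0$velocity_um_s, 0, tolerance = 1e-6)
  expect_error(estimate_velocity_kymo_rotation(matrix(FALSE, 5, 20), 0.5, 10),
               "3 frames")
})

test_that("the two velocity estimators agree on generated waves", {
  for (v_true in c(0.1, 0.3)) {
    m <- subtract_background(wave_movie(wavelength_um = 43, speed_um_s = v_true,
                                        W = 50, L = 60, n_frames = 60,
                                        noise_sd = 10, seed = round(100 * v_true)))
    w <- measure_wave(m)
    expect_equal(w$velocity_um_s, v_true, tolerance = 0.1 * v_true + 0.01)
    expect_equal(w$velocity_tracking_um_s, w$velocity_um_s,
                 tolerance = 0.1 * w$velocity_um_s)
  }
})

test_that("wavelength over velocity reproduces the generative period", {
  m <- subtract_background(wave_movie(wavelength_um = 40, speed_um_s = 0.4,
                                      W = 50, L = 90, n_frames = 60,
                                      noise_sd = 10, seed = 12))
  w <- measure_wave(m)
  period_est <- w$wavelength_um / w$velocity_um_s
  expect_equal(period_est, 40 / 0.4, tolerance = 10)
})

test_that("a static movie tracks to zero velocity", {
  frame <- matrix(0, 40, 40)
  frame[, 15:25] <- 50
  arr <- array(0, c(40, 40, 12))
  # modulate uniformly in time so a dominant frequency exists
  for (t in 1:12) arr[, , t] <- frame * (1 + 0.5 * sin(2 * pi * t / 6))
  m <- subtract_background(min_movie(arr, 0.5, 10))
  v <- estimate_velocity_tracking(m, wavelength_um = 20)
  expect_equal(v$velocity_um_s, 0, tolerance = 1e-9)
})
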