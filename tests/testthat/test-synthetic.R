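test_that("traveling wave field matches the closed form and its symmetries", {
  m <- wave_movie(wavelength_um = 40, speed_um_s = 0.5, W = 30, L = 60)
  # cosine maximum: at a zero-phase point intensity = background + amplitude
  # (the grid samples within a fraction of a pixel of the crest)
  expect_equal(max(m$data[, , 1]), 120, tolerance = 1e-3)
  expect_gte(min(m$data), 20 - 1e-9)
  # temporal period lambda / v = 80 s = 8 frames: frames 1 and 9 identical
  expect_equal(m$data[, , 1], m$data[, , 9], tolerance = 1e-9)
  # dominant spatial frequency of one frame along the propagation axis
  row <- m$data[10, , 1] - mean(m$data[10, , 1])
  spec_pow <- Mod(stats::fft(row))^2
  k <- which.max(spec_pow[2:(length(row) %/% 2 + 1)])
  # lambda = 40 um = 80 px on a 120 px row: frequency 120/80 = 1.5 -> bin 1 or 2
  freq_px <- k / length(row)
  expect_lt(abs(freq_px - 1 / 80), 0.5 / length(row) + 1e-9)
  # noise-free spatial mean is constant over time when the chamber spans
  # whole wavelengths (the cosine average over full periods is fixed)
  m2p <- wave_movie(wavelength_um = 40, speed_um_s = 0.5, W = 30, L = 80)
  means <- apply(m2p$data, 3, mean)
  expect_lt(diff(range(means)), 1e-6 * mean(means))
})

test_that("wave generator rejects aliased wavelengths and short movies", {
  geom <- chamber_geometry(20, 20, pixel_size_um = 0.5)
  spec <- pattern_spec("traveling_wave", wavelength_um = 0.6, speed_um_s = 0.1)
  expect_error(generate_traveling_wave(geom, spec, 10), "alias")
  spec2 <- pattern_spec("traveling_wave", wavelength_um = 20, speed_um_s = 0.1)
  expect_error(generate_traveling_wave(geom, spec2, 1), "at least 2")
})

test_that("same seed reproduces a movie bit for bit, different seeds do not", {
  a <- wave_movie(noise_sd = 10, seed = 5)
  b <- wave_movie(noise_sd = 10, seed = 5)
  c <- wave_movie(noise_sd = 10, seed = 6)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  # additivity: the noise-free component is unchanged under noise
  clean <- wave_movie(noise_sd = 0)
  resid <- a$data - clean$data
  expect_lt(abs(mean(resid)), 0.5)
  expect_equal(sd(resid), 10, tolerance = 0.05)
})

test_that("spiral phase winds by chirality * 2pi and keeps radial spacing", {
  m <- spiral_movie(wavelength_um = 20, W = 40, L = 40)
  pm <- phase_map(subtract_background(m))
  # winding on a loop around the centre core
  cx <- (ncol(pm$phase) + 1) / 2; cy <- (nrow(pm$phase) + 1) / 2
  th <- seq(0, 2 * pi, length.out = 200)
  r_px <- 15
  ph <- pm$phase[cbind(round(cy + r_px * sin(th)), round(cx + r_px * cos(th)))]
  winding <- sum(wrap_phase(diff(ph))) / (2 * pi)
  expect_equal(abs(winding), 1, tolerance = 0.05)
  # spacing of consecutive intensity maxima along a radial line = lambda
  # (sampled away from the core, where the azimuthal term is negligible)
  m2 <- spiral_movie(wavelength_um = 10, W = 40, L = 40)
  # frame 3 puts two crests at radii ~4 and ~14 um, both well inside
  # the radial window (the temporal period is 5 frames)
  prof <- m2$data[40, 46:80, 3]
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  expect_equal(mean(diff(pk)) * m2$pixel_size_um, 10, tolerance = 0.06)
})

test_that("multi-core spirals stay bounded and are rejected outside the chamber", {
  m <- spiral_movie(W = 20, L = 50, n_cores = 2, noise_sd = 0)
  expect_gte(min(m$data), 20 - 1e-9)
  expect_lte(max(m$data), 120 + 1e-9)
  expect_error(
    spiral_movie(W = 20, L = 50, cores_um = matrix(c(60, 10), 1)),
    "outside")
})

test_that("oscillation movies carry the period and pole-dwell signatures", {
  m <- osc_movie(period_s = 120, W = 10, L = 30, n_frames = 72)
  # pole trace autocorrelation peaks at the generator period (12 frames)
  pole <- apply(m$data[, 55:60, ], 3, mean)
  ac <- stats::acf(pole, lag.max = 20, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 12, tolerance = 1)
  # two largest temporal-STD values sit in the pole-end fifths
  s <- compute_std_image(m)
  colstd <- colMeans(s)
  n <- length(colstd)
  top2 <- order(colstd, decreasing = TRUE)[1:2]
  fifth <- ceiling(n / 5)
  expect_true(all(top2 <= fifth | top2 > n - fifth))
  mid <- colstd[(2 * fifth + 1):(3 * fifth)]
  expect_lt(max(mid), max(colstd))
})

test_that("oscillation generator rejects periods under twice the frame interval", {
  expect_error(osc_movie(period_s = 15), "twice the frame interval")
})

test_that("noise_only movies are white noise about the background", {
  geom <- chamber_geometry(30, 30, pixel_size_um = 0.5)
  spec <- pattern_spec("noise_only", background = 50, noise_sd = 8, seed = 2)
  m <- generate_oscillation(geom, spec, 50, 10)
  expect_equal(mean(m$data), 50, tolerance = 0.5)
  expect_equal(sd(m$data), 8, tolerance = 0.3)
  tr <- m$data[10, 10, ]
  ac <- stats::acf(tr, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 0.35))
})

test_that("field generation returns truthful boxes and rejects overlaps", {
  fld <- demo_field(rotation = 0, n_frames = 10)
  expect_equal(nrow(fld$boxes), 6)
  expect_equal(fld$boxes$r0, c(16, 16, 16, 76, 76, 76))
  g <- chamber_geometry(20, 30, origin_px = c(10, 10), pixel_size_um = 0.5)
  g2 <- chamber_geometry(20, 30, origin_px = c(20, 20), pixel_size_um = 0.5)
  s <- pattern_spec("traveling_wave", wavelength_um = 25, speed_um_s = 0.3)
  expect_error(generate_field(list(list(geom = g, spec = s),
                                   list(geom = g2, spec = s)), n_frames = 5),
               "overlap")
})

test_that("field rotation round-trips within interpolation error on smooth regions", {
  m <- wave_movie(wavelength_um = 30, W = 60, L = 60, n_frames = 3)
  f <- m$data[, , 1]
  bg <- mean(f)
  r <- rotate_image(rotate_image(f, 4, fill = bg), -4, fill = bg)
  inner <- 10:110
  rms <- sqrt(mean((r[inner, inner] - f[inner, inner])^2))
  expect_lt(rms / 100, 0.02)
})
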