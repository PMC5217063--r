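test_that("phase map recovers frequency and a planar phase for plane waves", {
  m <- subtract_background(wave_movie(wavelength_um = 40, speed_um_s = 0.5,
                                      W = 40, L = 60, n_frames = 48))
  pm <- phase_map(m)
  expect_true(pm$ok)
  # temporal frequency v / lambda within one bin
  expect_equal(pm$freq_hz, 0.5 / 40, tolerance = 1 / (48 * 10))
  # phase is linear in space with gradient magnitude 2 pi / lambda:
  # least-squares plane fit residual under 5% of 2 pi
  H <- nrow(pm$phase); W <- ncol(pm$phase)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  z <- exp(1i * pm$phase)
  # unwrap along x by cumulative wrapped differences on the mid row
  mid <- pm$phase[H %/% 2, ]
  un <- cumsum(c(mid[1], wrap_phase(diff(mid))))
  fit <- lm(un ~ seq_along(un))
  slope <- abs(unname(coef(fit)[2]))
  expect_equal(slope, 2 * pi / 80, tolerance = 0.02)
  expect_lt(sd(residuals(fit)), 0.05 * 2 * pi)
})

test_that("white-noise movies report no dominant frequency", {
  spec <- pattern_spec("noise_only", background = 30, noise_sd = 10, seed = 21)
  m <- generate_oscillation(chamber_geometry(30, 30, pixel_size_um = 0.5),
                            spec, 40, 10)
  pm <- phase_map(subtract_background(m))
  expect_false(pm$ok)
  expect_equal(classify_pattern(subtract_background(m))$label, "unclassified")
})

test_that("phase singularity counting finds spiral cores", {
  m1 <- subtract_background(spiral_movie(W = 40, L = 40, noise_sd = 5, seed = 2))
  pm <- phase_map(m1)
  s <- count_phase_singularities(pm$phase, merge_radius_px = 10)
  expect_equal(s$count, 1)
  # core within 3 px of the chamber centre
  expect_lt(sqrt(sum((s$cores[1, c("row", "col")] - c(40.5, 40.5))^2)), 3)
  # plane wave: no singularities
  mw <- subtract_background(wave_movie(n_frames = 40))
  pw <- phase_map(mw)
  expect_equal(count_phase_singularities(pw$phase, merge_radius_px = 10)$count, 0)
  # two cores 20 um apart
  m2 <- subtract_background(spiral_movie(W = 20, L = 40, n_cores = 2,
                                         cores_um = cbind(c(10, 30), c(10, 10)),
                                         noise_sd = 5, seed = 3))
  pm2 <- phase_map(m2)
  s2 <- count_phase_singularities(pm2$phase,
                                  mask = pm2$amplitude >
                                    0.25 * quantile(pm2$amplitude, 0.9),
                                  merge_radius_px = 10)
  expect_equal(s2$count, 2)
})

test_that("the cascade labels each genus correctly at SNR 10", {
  cases <- list(
    list(m = wave_movie(noise_sd = 10, seed = 31), want = "traveling_wave"),
    list(m = spiral_movie(noise_sd = 10, seed = 32), want = "rotation"),
    list(m = osc_movie(noise_sd = 10, seed = 33), want = "oscillation"),
    list(m = osc_movie(kind = "striped_oscillation", wavelength_um = 20,
                       W = 10, L = 60, noise_sd = 10, seed = 34),
         want = "oscillation"))
  for (cs in cases) {
    got <- classify_pattern(subtract_background(cs$m))
    expect_equal(got$label, cs$want)
  }
  got2 <- classify_pattern(subtract_background(
    spiral_movie(W = 20, L = 50, n_cores = 2, noise_sd = 10, seed = 35)))
  expect_equal(got2$label, "rotation")
  expect_equal(got2$n_rotation_centers, 2)
})

test_that("classification is invariant to intensity scaling and offsets", {
  m <- subtract_background(spiral_movie(noise_sd = 8, seed = 41))
  base <- classify_pattern(m)
  scaled <- m; scaled$data <- 3.7 * m$data + 55
  expect_equal(classify_pattern(scaled)$label, base$label)
  mirrored <- m; mirrored$data <- m$data[, rev(seq_len(ncol(m$data))), ]
  mcls <- classify_pattern(mirrored)
  expect_equal(mcls$label, base$label)
  # mirroring flips the spiral chirality (topological charge sign)
  expect_equal(unname(mcls$cores[1, "charge"]), -unname(base$cores[1, "charge"]))
})

test_that("a rotation centre drifting across the chamber is tagged traveling wave", {
  # splice two spiral half-movies whose cores sit at opposite chamber ends
  a <- spiral_movie(W = 20, L = 50, cores_um = matrix(c(8, 6), 1),
                    noise_sd = 5, seed = 51, n_frames = 24)
  b <- spiral_movie(W = 20, L = 50, cores_um = matrix(c(42, 14), 1),
                    noise_sd = 5, seed = 52, n_frames = 24)
  m <- min_movie(array(c(a$data, b$data), c(dim(a$data)[1:2], 48)), 0.5, 10)
  cls <- classify_pattern(subtract_background(m))
  expect_equal(cls$label, "traveling_wave")
})

test_that("clean generator output is classified perfectly", {
  coh <- generate_cohort(12, noise_frac = 0, seed = 5)
  preds <- vapply(coh, function(r)
    classify_pattern(subtract_background(r$movie))$label, character(1))
  truth <- vapply(coh, function(r) r$true_label, character(1))
  expect_identical(preds, truth)
})

test_that("a slow pattern without two full cycles stays unclassified", {
  # period 400 s in a 400 s movie: one cycle only
  m <- osc_movie(period_s = 400, W = 10, L = 30, n_frames = 40)
  cls <- classify_pattern(subtract_background(m))
  expect_equal(cls$label, "unclassified")
})
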