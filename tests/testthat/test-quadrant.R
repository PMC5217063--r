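test_that("temporal STD image follows the population definition", {
  cst <- min_movie(array(5, c(8, 8, 6)), 0.5, 10)
  expect_true(all(compute_std_image(cst) == 0))
  two <- min_movie(array(c(rep(0, 64), rep(2, 64)), c(8, 8, 2)), 0.5, 10)
  expect_true(all(abs(compute_std_image(two) - 1) < 1e-12))
  # sinusoidal trace of amplitude A has SD A / sqrt(2)
  A <- 7
  tt <- seq_len(200)
  arr <- array(0, c(4, 4, 200))
  for (t in tt) arr[, , t] <- 10 + A * sin(2 * pi * t / 20)
  s <- compute_std_image(min_movie(arr, 0.5, 10))
  expect_equal(s[1, 1], A / sqrt(2), tolerance = 0.02)
})

test_that("STD image is frame-permutation invariant, kymographs are not", {
  m <- wave_movie(n_frames = 16, noise_sd = 3, seed = 4, W = 20, L = 30)
  perm <- m
  perm$data <- m$data[, , c(9:16, 1:8)]
  expect_equal(compute_std_image(m), compute_std_image(perm))
  k1 <- midline_kymographs(m)$kymo_xt
  k2 <- midline_kymographs(perm)$kymo_xt
  expect_false(isTRUE(all.equal(k1, k2)))
})

test_that("midline kymographs reproduce the strict midline and wave slope", {
  m <- wave_movie(wavelength_um = 30, speed_um_s = 0.4, W = 20, L = 60,
                  n_frames = 20)
  k <- midline_kymographs(m, band_px = 1)
  mid <- (dim(m$data)[1] + 1) %/% 2
  expect_equal(k$kymo_xt[3, ], m$data[mid, , 3], tolerance = 1e-12)
  # cross-correlation lag between consecutive rows = v * dt / px
  k3 <- midline_kymographs(m, band_px = 3)$kymo_xt
  lags <- -12:12
  cc <- vapply(lags, function(l) {
    a <- k3[1, ]; b <- k3[2, ]
    n <- length(a)
    if (l >= 0) stats::cor(a[1:(n - l)], b[(1 + l):n])
    else stats::cor(a[(1 - l):n], b[1:(n + l)])
  }, numeric(1))
  best <- lags[which.max(cc)]
  expect_equal(best, 0.4 * 10 / 0.5, tolerance = 1)
})

test_that("oscillation kymograph band centroid alternates about the mid-column", {
  m <- osc_movie(period_s = 120, W = 10, L = 40, n_frames = 48)
  k <- midline_kymographs(m)$kymo_xt
  n <- ncol(k)
  centroid <- apply(k, 1, function(row) {
    w <- row - min(row)
    sum(w * seq_len(n)) / sum(w) - (n + 1) / 2
  })
  # sign flips at the generator's half-period cadence: strong + and -
  # excursions both occur, roughly balanced
  expect_gt(max(centroid), n / 8)
  expect_lt(min(centroid), -n / 8)
  flips <- sum(diff(sign(centroid[abs(centroid) > n / 10])) != 0)
  expect_gte(flips, 5)
})

test_that("the quadrant bundle is a faithful composition", {
  m <- wave_movie(W = 20, L = 30, n_frames = 9)
  q <- compose_quadrant(m)
  expect_equal(q$frame_index, 4)  # floor(9 / 2)
  expect_identical(q$frame, m$data[, , 5])
  expect_equal(q$std_image, compute_std_image(m))
  k <- midline_kymographs(m, band_px = 3)
  expect_equal(q$kymo_xt, k$kymo_xt)
  expect_equal(q$kymo_yt, k$kymo_yt)
  expect_error(midline_kymographs(m, band_px = 4), "odd")
  expect_error(midline_kymographs(m, band_px = 99), "wider")
})

test_that("quadrant rendering arranges the four panes and writes a PNG", {
  m <- wave_movie(W = 20, L = 30, n_frames = 9)
  q <- compose_quadrant(m)
  path <- tempfile(fileext = ".png")
  arr <- render_quadrant(q, path)
  expect_true(file.exists(path))
  d <- dim(m$data)
  # canvas holds the four padded panes plus the 2 px gaps
  expect_equal(dim(arr)[3], 3)
  expect_gte(dim(arr)[1], d[1] + d[3] + 2)
  expect_gte(dim(arr)[2], d[2] + d[3] + 2)
  # STD of a noise-only movie is spatially flat
  spec <- pattern_spec("noise_only", background = 30, noise_sd = 5, seed = 9)
  nm <- generate_oscillation(chamber_geometry(20, 20, pixel_size_um = 0.5),
                             spec, 80, 10)
  s <- compute_std_image(nm)
  se <- 5 / sqrt(2 * (80 - 1))
  expect_lt(max(abs(s - mean(s))), 5 * se + 0.5)
})
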