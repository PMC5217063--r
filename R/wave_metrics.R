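#' Estimate the wave propagation direction
#'
#' For traveling patterns the direction is the angle of the negated
#' mask-averaged spatial gradient of the dominant-frequency phase map
#' (the phase of `cos(w t - k u)` is `-k u`, so fronts advance along
#' `-grad(phase)`). For rotations (a phase singularity is present) the
#' local propagation direction half a wavelength from the core is
#' returned, which is tangential to the rotation.
#'
#' @param movie a background-subtracted chamber [min_movie].
#' @return Angle in degrees, counter-clockwise from the +x (column) axis,
#'   in `(-180, 180]`.
#' @export
estimate_direction <- function(movie) {
  pm <- phase_map(movie)
  if (!pm$ok) stop("no dominant frequency: direction undefined")
  g <- phase_gradient(pm$phase, pm$amplitude)
  kmag <- sqrt(sum(g^2))
  lambda_px <- if (kmag > 0) 2 * pi / kmag else Inf
  sing <- count_phase_singularities(pm$phase,
                                    merge_radius_px = max(3, lambda_px / 4))
  if (sing$count >= 1) {
    # local gradient half a wavelength to the +x side of the first core
    core <- sing$cores[1, ]
    r <- round(core["row"]); c <- round(min(core["col"] + lambda_px / 2,
                                            ncol(pm$phase) - 2))
    r <- min(max(r, 2), nrow(pm$phase) - 2)
    win_r <- (r - 1):(r + 1); win_c <- (max(c - 1, 2)):(min(c + 1, ncol(pm$phase) - 1))
    g <- phase_gradient(pm$phase[win_r, win_c, drop = FALSE],
                        pm$amplitude[win_r, win_c, drop = FALSE])
  }
  unname(atan2(-g["gy"], -g["gx"]) * 180 / pi)
}

#' Space-time kymograph along a line
#'
#' Row `t` holds bilinear samples of frame `t` at unit-pixel spacing
#' along the segment from `start` to `end` (fractional pixel positions
#' allowed), averaged over `band_px` parallel lines offset
#' perpendicular to the segment to suppress pixel noise.
#'
#' @param movie a background-subtracted [min_movie].
#' @param start,end numeric `(row, col)` endpoints in pixels.
#' @param band_px odd number of parallel lines averaged.
#' @return A `T x S` matrix with attribute `positions_px` (distance from
#'   `start` of each sample).
#' @export
propagation_kymograph <- function(movie, start, end, band_px = 5L) {
  stopifnot(band_px >= 1, band_px %% 2 == 1)
  len <- sqrt(sum((end - start)^2))
  if (len < 4) stop("propagation line shorter than 4 px")
  S <- floor(len) + 1L
  f <- (seq_len(S) - 1) / len
  rows <- start[1] + f * (end[1] - start[1])
  cols <- start[2] + f * (end[2] - start[2])
  # unit normal to the line
  nr <- -(end[2] - start[2]) / len
  nc <- (end[1] - start[1]) / len
  offsets <- seq(-(band_px - 1L) / 2, (band_px - 1L) / 2)
  T_ <- n_frames(movie)
  H <- nrow(movie$data); W <- ncol(movie$data)
  kymo <- matrix(0, T_, S)
  for (t in seq_len(T_)) {
    acc <- rep(0, S); nacc <- rep(0, S)
    frame <- movie$data[, , t]
    for (o in offsets) {
      rr <- rows + o * nr; cc <- cols + o * nc
      inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      v <- bilinear_sample(frame, rr, cc)
      acc[inside] <- acc[inside] + v[inside]
      nacc[inside] <- nacc[inside] + 1
    }
    kymo[t, ] <- acc / pmax(nacc, 1)
  }
  attr(kymo, "positions_px") <- (seq_len(S) - 1)
  kymo
}

# Moving-average smoothing of a vector (edges keep raw values).
smooth_vec <- function(x, width) {
  if (width <= 1) return(x)
  s <- stats::filter(x, rep(1 / width, width), sides = 2)
  s[is.na(s)] <- x[is.na(s)]
  as.numeric(s)
}

# Per-row peak detection: returns a binary matrix of the kymograph's
# local maxima with prominence >= prominence_factor * row SD, after a
# short moving-average smooth that suppresses single-pixel noise peaks
# (wavelengths of interest span tens of pixels, so the smooth does not
# displace real maxima).
peak_kymograph <- function(kymo, prominence_factor = 0.5, smooth_px = 5L) {
  out <- matrix(FALSE, nrow(kymo), ncol(kymo))
  for (t in seq_len(nrow(kymo))) {
    row <- smooth_vec(kymo[t, ], smooth_px)
    pk <- find_peaks(row, min_prominence = prominence_factor * stats::sd(row))
    out[t, pk] <- TRUE
  }
  out
}

#' Wavelength from kymograph peak spacings
#'
#' Detects local intensity maxima on every kymograph row (prominence at
#' least `prominence_factor` times the row SD), pools the
#' consecutive-peak distances over all rows, histograms them in
#' `bin_px`-wide bins and fits a Gaussian by least squares; the fitted
#' mean and SD, scaled by the pixel size, give the wavelength and its
#' spread. If the fit does not converge (e.g. all spacings identical in
#' a noise-free movie) the sample mean and SD are reported with
#' `method = "moments"`.
#'
#' @param kymo kymograph from [propagation_kymograph()].
#' @param pixel_size_um pixel size along the line, micrometres.
#' @param prominence_factor peak prominence threshold in row-SD units.
#' @param smooth_px moving-average width applied to each row before peak
#'   detection (suppresses single-pixel noise maxima).
#' @param bin_px histogram bin width in pixels.
#' @param max_distance_px spacings above this (e.g. the chamber diagonal)
#'   are discarded as artefacts.
#' @return A list: `wavelength_um`, `wavelength_sd_um`, `n_pairs`,
#'   `method` (`"gaussian"`, `"moments"`, or `"undefined"` when fewer
#'   than two peaks exist on every row — a chamber shorter than the
#'   wavelength is a legal outcome).
#' @export
estimate_wavelength <- function(kymo, pixel_size_um, prominence_factor = 0.5,
                                bin_px = 2, max_distance_px = Inf,
                                smooth_px = 5L) {
  pk_mat <- peak_kymograph(kymo, prominence_factor, smooth_px)
  dists <- numeric(0)
  for (t in seq_len(nrow(kymo))) {
    pk <- which(pk_mat[t, ])
    if (length(pk) >= 2) dists <- c(dists, diff(pk))
  }
  dists <- dists[dists <= max_distance_px]
  if (length(dists) == 0)
    return(list(wavelength_um = NA_real_, wavelength_sd_um = NA_real_,
                n_pairs = 0L, method = "undefined"))
  breaks <- seq(0, max(dists) + bin_px, by = bin_px)
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
  fit <- tryCatch({
    df <- data.frame(x = h$mids, y = h$counts)
    m <- minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
      start = list(a = max(df$y), mu = mean(dists),
                   s = max(stats::sd(dists), bin_px / 2)),
      lower = c(a = 0, mu = min(dists), s = bin_px / 4),
      upper = c(a = Inf, mu = max(dists), s = diff(range(dists)) + bin_px),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    if (!is.finite(cf["mu"]) || cf["mu"] <= 0) stop("bad fit")
    list(mu = unname(cf["mu"]), s = abs(unname(cf["s"])), method = "gaussian")
  }, error = function(e) {
    list(mu = mean(dists), s = stats::sd(dists), method = "moments")
  })
  list(wavelength_um = fit$mu * pixel_size_um,
       wavelength_sd_um = fit$s * pixel_size_um,
       n_pairs = length(dists), method = fit$method)
}

#' Front velocity by kymograph shear minimisation
#'
#' Shears the binary peak kymograph by candidate slopes (pixels per
#' frame): row `t` is displaced by `-slope * t`, wrapping circularly at
#' the line ends so every column keeps full temporal support. At the
#' true slope, peak trajectories stack vertically and the mean
#' per-column standard deviation of the sheared image is minimal. The
#' optimum is refined by a parabola through the objective around the
#' grid minimum; the parabola's curvature, against the residual scatter
#' of the objective, gives the slope uncertainty. A shear is used
#' rather than a rigid rotation because the kymograph axes carry
#' different units; for small angles both give the same argmin.
#'
#' @param peak_kymo logical/0-1 `T x S` matrix of peak positions (see
#'   [peak_kymograph()]).
#' @param pixel_size_um pixel size along the line.
#' @param frame_interval_s frame interval in seconds.
#' @param slope_grid candidate slopes in px/frame; by default the slope
#'   is seeded by the aggregate cross-correlation between consecutive
#'   peak rows and the shear objective is scanned at 0.02 px/frame
#'   within 1.2 px/frame of that seed.
#' @return A list: `velocity_um_s` (magnitude), `velocity_sd_um_s`,
#'   `slope_px_frame` (signed), `objective` (tibble of slope, value). A
#'   flat objective (stationary pattern) returns zero velocity with an
#'   SD spanning the grid.
#' @export
estimate_velocity_kymo_rotation <- function(peak_kymo, pixel_size_um,
                                            frame_interval_s,
                                            slope_grid = NULL) {
  pk <- (peak_kymo > 0) * 1
  T_ <- nrow(pk); S <- ncol(pk)
  if (sum(rowSums(pk) > 0) < 3)
    stop("need detected peaks in at least 3 frames")
  # widen the peak marks into short bumps: per-row detection jitters by
  # a few pixels, and both the correlation seed and the shear objective
  # need overlapping support to see alignment through that jitter
  pk <- t(apply(pk, 1, smooth_vec, width = 5L))
  xs <- seq_len(S)
  shear_objective <- function(s) {
    shift <- -s * (seq_len(T_) - 1)
    off <- 1L - floor(min(shift))
    width <- S + ceiling(max(shift)) + off + 1L
    acc <- matrix(0, T_, width)
    for (t in seq_len(T_)) {
      o <- shift[t] + off
      i0 <- floor(o); fr <- o - i0
      lo <- xs + i0
      acc[t, lo] <- (1 - fr) * pk[t, ]
      acc[t, lo + 1L] <- acc[t, lo + 1L] + fr * pk[t, ]
    }
    mu <- colMeans(acc)
    sds <- sqrt(pmax(colMeans(acc^2) - mu^2, 0))
    mean(sds)
  }
  # seed the slope with the aggregate cross-correlation between
  # consecutive rows: unambiguous while fronts advance less than half a
  # peak spacing per frame, and it keeps the shear refinement inside a
  # narrow window where canvas geometry is comparable across candidates
  max_lag <- max(2L, S %/% 3L)
  xcorr <- vapply(-max_lag:max_lag, function(l) {
    tot <- 0
    for (t in seq_len(T_ - 1L)) {
      a <- pk[t, ]; b <- pk[t + 1L, ]
      if (l >= 0) tot <- tot + sum(a[seq_len(S - l)] * b[seq_len(S - l) + l])
      else tot <- tot + sum(a[seq_len(S + l) - l] * b[seq_len(S + l)])
    }
    tot
  }, numeric(1))
  s0 <- (-max_lag:max_lag)[which.max(xcorr)]
  search <- function(grid) {
    vals <- vapply(grid, shear_objective, numeric(1))
    keep <- is.finite(vals)
    list(grid = grid[keep], vals = vals[keep])
  }
  if (is.null(slope_grid)) {
    fine <- search(seq(s0 - 1.2, s0 + 1.2, by = 0.02))
    grid <- fine$grid; vals <- fine$vals
    full_range <- 2.4
  } else {
    res <- search(slope_grid)
    grid <- res$grid; vals <- res$vals
    full_range <- diff(range(slope_grid))
  }
  obj <- tibble::tibble(slope = grid, value = vals)
  rng <- diff(range(vals))
  scale <- pixel_size_um / frame_interval_s
  if (length(vals) < 3 || rng < 1e-9 * max(abs(vals), 1)) {
    return(list(velocity_um_s = 0,
                velocity_sd_um_s = full_range / 2 * scale,
                slope_px_frame = 0, objective = obj))
  }
  i <- which.min(vals)
  win <- max(1, i - 4):min(length(grid), i + 4)
  qf <- stats::lm(vals[win] ~ stats::poly(grid[win], 2, raw = TRUE))
  a <- unname(stats::coef(qf)[3]); b <- unname(stats::coef(qf)[2])
  if (is.finite(a) && a > 0) {
    s_hat <- -b / (2 * a)
    if (s_hat < min(grid[win]) || s_hat > max(grid[win])) s_hat <- grid[i]
    resid_sd <- stats::sd(stats::residuals(qf))
    s_sd <- sqrt(max(resid_sd, 1e-12) / a)
  } else {
    s_hat <- grid[i]
    s_sd <- diff(range(grid[win])) / 2
  }
  list(velocity_um_s = abs(s_hat) * scale,
       velocity_sd_um_s = s_sd * scale,
       slope_px_frame = unname(s_hat), objective = obj)
}

#' Front velocity by band tracking
#'
#' Tracks, per frame, the intensity-weighted centroid of the brightest
#' connected suprathreshold (Otsu) region — one wave band — and averages
#' the frame-to-frame displacement magnitudes. Steps larger than half a
#' wavelength are discarded as wrap-around events (the tracked band
#' leaving the chamber while the next takes over as the brightest), and
#' steps in which the tracked band touches the frame boundary are
#' dropped because a truncated band's centroid is biased toward the
#' edge.
#'
#' @param movie a background-subtracted chamber [min_movie].
#' @param wavelength_um wavelength used for the wrap-around cut; `NULL`
#'   disables the cut.
#' @return A list: `velocity_um_s`, `velocity_sd_um_s`, `n_steps`. A
#'   movie whose tracked band never moves returns zero velocity.
#' @export
estimate_velocity_tracking <- function(movie, wavelength_um = NULL) {
  pm <- phase_map(movie)
  if (!pm$ok) stop("no dominant frequency: tracking undefined")
  T_ <- n_frames(movie)
  d <- dim(movie$data)
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  cent <- matrix(NA_real_, T_, 2)
  touch <- matrix(FALSE, T_, 4)  # top, bottom, left, right
  for (t in seq_len(T_)) {
    f <- movie$data[, , t]
    th <- otsu_threshold(f)
    if (is.na(th)) { cent[t, ] <- c(mean(rows), mean(cols)); next }
    mask <- f > th
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- matrix(as.integer(lab), d[1], d[2])
    if (max(lab) == 0) { cent[t, ] <- c(mean(rows), mean(cols)); next }
    bright <- which.max(vapply(seq_len(max(lab)),
                               function(k) sum(f[lab == k]), numeric(1)))
    sel <- lab == bright
    w <- (f - th) * sel
    cent[t, ] <- c(sum(rows * w), sum(cols * w)) / sum(w)
    touch[t, ] <- c(any(sel[1, ]), any(sel[d[1], ]),
                    any(sel[, 1]), any(sel[, d[2]]))
  }
  # a band being cut off at an edge perpendicular to its motion has a
  # biased centroid; decide the motion axis from the total displacement
  disp <- colSums(abs(diff(cent)), na.rm = TRUE)
  interior <- if (disp[2] >= disp[1]) !(touch[, 3] | touch[, 4])
              else !(touch[, 1] | touch[, 2])
  steps <- sqrt(rowSums(diff(cent)^2)) * movie$pixel_size_um
  ok <- interior[-T_] & interior[-1]
  if (!is.null(wavelength_um)) ok <- ok & steps < wavelength_um / 2
  kept <- steps[ok]
  if (length(kept) == 0) {
    if (all(steps < 1e-9))
      return(list(velocity_um_s = 0, velocity_sd_um_s = 0, n_steps = 0L))
    stop("no usable displacement steps: undersampled movie")
  }
  list(velocity_um_s = mean(kept) / movie$frame_interval_s,
       velocity_sd_um_s = stats::sd(kept) / movie$frame_interval_s,
       n_steps = length(kept))
}

# Longest line segment through the image centre along direction theta
# (degrees) staying `margin` px inside the frame; returns start/end.
centre_line <- function(dim_hw, direction_deg, margin = 1) {
  th <- direction_deg * pi / 180
  cr <- (dim_hw[1] + 1) / 2; cc <- (dim_hw[2] + 1) / 2
  dr <- sin(th); dc <- cos(th)
  lim <- function(d, c, n) {
    if (abs(d) < 1e-12) return(Inf)
    max((c(1 + margin, n - margin) - c) / d)
  }
  tmax <- min(lim(dr, cr, dim_hw[1]), lim(dc, cc, dim_hw[2]))
  tmin <- -min(lim(-dr, cr, dim_hw[1]), lim(-dc, cc, dim_hw[2]))
  list(start = c(cr + tmin * dr, cc + tmin * dc),
       end = c(cr + tmax * dr, cc + tmax * dc))
}

#' Full wave measurement of one chamber movie
#'
#' Convenience wrapper: estimates the propagation direction, samples the
#' kymograph along a centre line in that direction (or along a
#' user-supplied line, mirroring the manual line of unconfined
#' flat-bilayer movies), and derives the wavelength and both velocity
#' estimates.
#'
#' @param movie a background-subtracted chamber [min_movie].
#' @param line optional `list(start = , end = )` pixel coordinates
#'   overriding the automatic direction line.
#' @param prominence_factor peak prominence threshold (row-SD units).
#' @return A one-row tibble with direction, wavelength (mean, SD, number
#'   of peak pairs, fit method) and the two velocity estimates.
#' @export
measure_wave <- function(movie, line = NULL, prominence_factor = 0.5) {
  dir_deg <- tryCatch(estimate_direction(movie), error = function(e) NA_real_)
  if (is.null(line)) {
    if (!is.finite(dir_deg)) stop("no dominant frequency: cannot place line")
    line <- centre_line(dim(movie$data)[1:2], dir_deg)
  }
  kymo <- propagation_kymograph(movie, line$start, line$end)
  diag_px <- sqrt(sum((dim(movie$data)[1:2])^2))
  wl <- estimate_wavelength(kymo, movie$pixel_size_um,
                            prominence_factor = prominence_factor,
                            max_distance_px = diag_px)
  pk <- peak_kymograph(kymo, prominence_factor)
  vshear <- tryCatch(
    estimate_velocity_kymo_rotation(pk, movie$pixel_size_um,
                                    movie$frame_interval_s),
    error = function(e) list(velocity_um_s = NA_real_,
                             velocity_sd_um_s = NA_real_))
  vtrack <- tryCatch(
    estimate_velocity_tracking(movie, wl$wavelength_um),
    error = function(e) list(velocity_um_s = NA_real_,
                             velocity_sd_um_s = NA_real_))
  tibble::tibble(direction_deg = dir_deg,
                 wavelength_um = wl$wavelength_um,
                 wavelength_sd_um = wl$wavelength_sd_um,
                 n_peak_pairs = wl$n_pairs, wavelength_method = wl$method,
                 velocity_um_s = vshear$velocity_um_s,
                 velocity_sd_um_s = vshear$velocity_sd_um_s,
                 velocity_tracking_um_s = vtrack$velocity_um_s,
                 velocity_tracking_sd_um_s = vtrack$velocity_sd_um_s)
}
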