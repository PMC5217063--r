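#' Per-pixel temporal phase map
#'
#' Computes the discrete Fourier transform of every pixel trace and keeps
#' the non-zero frequency bin with the largest total spectral power over
#' the mask. The returned phase map is the argument of that component per
#' pixel (so a wave `cos(w t - k u)` has phase `-k u`), the amplitude map
#' its modulus. If no bin exceeds twice the median bin power the movie
#' has no dominant frequency and `ok` is `FALSE`.
#'
#' @param movie a background-subtracted [min_movie] with at least 8
#'   frames.
#' @param mask optional logical matrix selecting chamber pixels (default
#'   all).
#' @return A list: `ok`, `amplitude`, `phase`, `freq_hz`, `cycles` (the
#'   number of full periods in the movie), `power` (per-bin total power).
#' @export
phase_map <- function(movie, mask = NULL) {
  d <- dim(movie$data)
  T_ <- d[3]
  if (T_ < 8L) stop("phase_map needs at least 8 frames")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  traces <- matrix(aperm(movie$data, c(3, 1, 2)), T_, d[1] * d[2])
  ft <- stats::mvfft(traces)
  bins <- 2:(T_ %/% 2L + 1L)
  pw <- Mod(ft[bins, as.vector(mask), drop = FALSE])^2
  total <- rowSums(pw)
  k <- bins[which.max(total)]
  ok <- max(total) > 2 * stats::median(total)
  amp <- matrix(Mod(ft[k, ]), d[1], d[2]) * 2 / T_
  ph <- matrix(Arg(ft[k, ]), d[1], d[2])
  list(ok = ok, amplitude = amp, phase = ph,
       freq_hz = (k - 1) / (T_ * movie$frame_interval_s),
       cycles = k - 1, power = stats::setNames(total, bins))
}

#' Count phase singularities (spiral cores)
#'
#' Sums wrapped phase differences around every 2x2 plaquette; plaquettes
#' with winding number ±1 mark phase singularities. Nearby detections are
#' merged by single-linkage clustering within `merge_radius_px`, summing
#' their charges; clusters with zero net charge (wrap dipoles from noise)
#' are discarded.
#'
#' @param phase 2-D phase matrix (radians).
#' @param mask optional logical matrix; a plaquette counts only when all
#'   four corners are in the mask.
#' @param merge_radius_px merge radius in pixels (a quarter wavelength is
#'   the classifier default).
#' @param border_px detections closer than this to the mask edge are
#'   dropped (singularities pinned to walls are boundary artefacts).
#' @return A list with `count` and `cores` (matrix with columns `row`,
#'   `col`, `charge`).
#' @export
count_phase_singularities <- function(phase, mask = NULL, merge_radius_px = 5,
                                      border_px = 2L) {
  H <- nrow(phase); W <- ncol(phase)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  p00 <- phase[-H, -W]; p01 <- phase[-H, -1]
  p11 <- phase[-1, -1]; p10 <- phase[-1, -W]
  d1 <- wrap_phase(p01 - p00); d2 <- wrap_phase(p11 - p01)
  d3 <- wrap_phase(p10 - p11); d4 <- wrap_phase(p00 - p10)
  wind <- (d1 + d2 + d3 + d4) / (2 * pi)
  # a genuine core winds smoothly (edge steps ~ pi/2); an edge step close
  # to pi marks an antiphase discontinuity line, whose noisy wraps mimic
  # singularities and must not count
  smooth_edges <- pmax(abs(d1), abs(d2), abs(d3), abs(d4)) < 0.9 * pi
  valid <- mask[-H, -W] & mask[-H, -1] & mask[-1, -1] & mask[-1, -W] &
    smooth_edges
  # stay clear of the mask/image border
  if (border_px > 0) {
    inner <- matrix(FALSE, H - 1, W - 1)
    rs <- (1 + border_px):(H - 1 - border_px)
    cs <- (1 + border_px):(W - 1 - border_px)
    if (length(rs) > 0 && length(cs) > 0) inner[rs, cs] <- TRUE
    valid <- valid & inner
  }
  hit <- which(valid & abs(wind) > 0.5, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(list(count = 0L, cores = cbind(row = numeric(0), col = numeric(0),
                                          charge = numeric(0))))
  pos <- cbind(hit[, 1] + 0.5, hit[, 2] + 0.5)
  charge <- round(wind[hit])
  cl <- if (nrow(pos) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(pos), method = "single"),
                  h = merge_radius_px)
  cores <- do.call(rbind, lapply(unique(cl), function(g) {
    i <- cl == g
    c(row = mean(pos[i, 1]), col = mean(pos[i, 2]), charge = sum(charge[i]))
  }))
  cores <- cores[cores[, "charge"] != 0, , drop = FALSE]
  list(count = nrow(cores), cores = cores)
}

# Pixels with a meaningful dominant-frequency amplitude.
amplitude_mask <- function(amplitude, frac = 0.25) {
  amplitude > frac * stats::quantile(amplitude, 0.9)
}

# Amplitude-weighted circular mean of wrapped spatial phase gradients;
# returns c(gx, gy) in radians per pixel.
phase_gradient <- function(phase, amplitude) {
  H <- nrow(phase); W <- ncol(phase)
  gx <- wrap_phase(phase[, -1] - phase[, -W])
  wx <- amplitude[, -1] * amplitude[, -W]
  gy <- wrap_phase(phase[-1, ] - phase[-H, ])
  wy <- amplitude[-1, ] * amplitude[-H, ]
  # circular weighted mean guards against residual wraps
  mean_ang <- function(g, w) Arg(sum(w * exp(1i * g)) / sum(w))
  c(gx = mean_ang(gx, wx), gy = mean_ang(gy, wy))
}

# Weighted RMS residual (radians) of the best-fitting spatial phase plane.
planarity_residual <- function(phase, amplitude) {
  g <- phase_gradient(phase, amplitude)
  H <- nrow(phase); W <- ncol(phase)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  yy <- matrix(seq_len(H), H, W)
  plane <- g["gx"] * xx + g["gy"] * yy
  w <- amplitude / max(amplitude)
  off <- Arg(sum(w * exp(1i * (phase - plane))))
  res <- wrap_phase(phase - plane - off)
  sqrt(sum(w * res^2) / sum(w))
}

# Standing-oscillation score. For each chamber axis the mirror
# coherence |<e^{i(phase - mirrored phase)}>| is 1 when opposite halves
# hold a fixed phase relation (pi apart for pole-to-pole modes, 0 for
# striped modes whose dominant frequency is a harmonic of the shuttling
# period) and ~0 for traveling waves and spirals. A trivially coherent
# axis along which the phase barely varies (e.g. the cross axis of a
# plane wave) is rejected by requiring circular phase spread along the
# axis. Returns the best axis score and the signed antiphase component.
standing_scores <- function(phase, amplitude) {
  H <- nrow(phase); W <- ncol(phase)
  axis_score <- function(flip, along) {
    pf <- flip(phase); wf <- flip(amplitude)
    w <- amplitude * wf
    z <- sum(w * exp(1i * (phase - pf))) / sum(w)
    # circular spread of phase along the candidate oscillation axis
    prof <- if (along == "x") {
      colSums(amplitude * exp(1i * phase)) / pmax(colSums(amplitude), 1e-12)
    } else {
      rowSums(amplitude * exp(1i * phase)) / pmax(rowSums(amplitude), 1e-12)
    }
    wl <- if (along == "x") colSums(amplitude) else rowSums(amplitude)
    # only the angle of each line's mean counts: cross-axis variation
    # must not masquerade as along-axis spread
    keep <- Mod(prof) > 1e-9
    unit <- prof[keep] / Mod(prof[keep])
    spread <- 1 - Mod(sum(wl[keep] * unit) / sum(wl[keep]))
    c(coherence = Mod(z), anti = -Re(z), spread = spread)
  }
  sx <- axis_score(function(m) m[, rev(seq_len(ncol(m)))], "x")
  sy <- axis_score(function(m) m[rev(seq_len(nrow(m))), ], "y")
  eff <- c(if (sx["spread"] > 0.3) sx["coherence"] else 0,
           if (sy["spread"] > 0.3) sy["coherence"] else 0)
  list(score = max(eff), antiphase = max(sx["anti"], sy["anti"]))
}

#' Classify a chamber movie
#'
#' Deterministic decision cascade over the per-pixel phase map of the
#' dominant temporal frequency:
#' 1. no dominant frequency, or fewer than two full cycles in the movie,
#'    gives `unclassified`;
#' 2. one or more interior phase singularities give `rotation` (several
#'    cores are still one rotation), unless the core travels more than
#'    half the chamber length between the two movie halves, which is
#'    reassigned to `traveling_wave`;
#' 3. a mirror-antiphase phase field (score above
#'    `antiphase_threshold`) gives `oscillation` (this covers striped and
#'    side-to-side modes, whose bands alternate in antiphase);
#' 4. a phase field well fit by a spatial plane (weighted RMS residual
#'    below `planarity_threshold`) gives `traveling_wave`;
#' 5. anything else is `unclassified`.
#'
#' The classification is invariant to intensity scaling and offsets by
#' construction (only the non-DC Fourier component is used).
#'
#' @param movie a background-subtracted chamber [min_movie].
#' @param antiphase_threshold cascade threshold, default 0.6.
#' @param planarity_threshold residual threshold in radians, default
#'   `0.25 * 2 * pi`.
#' @param border_px singularity exclusion border (pixels).
#' @return An object of class `pattern_class`: list with `label`,
#'   `n_rotation_centers`, `cores`, and `features` (dominant frequency in
#'   Hz, planarity residual, antiphase score, winding count, wavelength
#'   estimate in pixels).
#' @export
classify_pattern <- function(movie, antiphase_threshold = 0.6,
                             planarity_threshold = 0.25 * 2 * pi,
                             border_px = 2L) {
  unclassified <- function(freq = NA_real_) {
    structure(list(label = "unclassified", n_rotation_centers = 0L,
                   cores = NULL,
                   features = list(freq_hz = freq, planarity = NA_real_,
                                   antiphase = NA_real_, standing = NA_real_,
                                   winding = 0L, lambda_px = NA_real_)),
              class = "pattern_class")
  }
  pm <- tryCatch(phase_map(movie), error = function(e) NULL)
  if (is.null(pm) || !pm$ok) return(unclassified())
  if (pm$cycles < 2) return(unclassified(pm$freq_hz))
  g <- phase_gradient(pm$phase, pm$amplitude)
  kmag <- sqrt(sum(g^2))
  lambda_px <- if (kmag > 0) 2 * pi / kmag else Inf
  merge_radius <- max(3, min(lambda_px, max(dim(movie$data)[1:2])) / 4)
  # pixels whose dominant-frequency amplitude is weak carry noise phase
  # and must not vote for singularities
  strong <- amplitude_mask(pm$amplitude)
  sing <- count_phase_singularities(pm$phase, mask = strong,
                                    merge_radius_px = merge_radius,
                                    border_px = border_px)
  standing <- standing_scores(pm$phase, pm$amplitude)
  planar <- planarity_residual(pm$phase, pm$amplitude)
  feats <- list(freq_hz = pm$freq_hz, planarity = planar,
                antiphase = standing$antiphase, standing = standing$score,
                winding = sing$count, lambda_px = lambda_px)
  halves <- half_cores(movie, border_px)
  drift_px <- if (!is.null(halves$a) && !is.null(halves$b))
    sqrt(sum((halves$a - halves$b)^2)) else NA_real_
  drifting <- is.finite(drift_px) && drift_px > max(dim(movie$data)[1:2]) / 2
  label <- if (sing$count >= 1L) {
    if (drifting) "traveling_wave" else "rotation"
  } else if (drifting) {
    # a core present in both halves but displaced across the chamber is
    # a front sweeping through, not a pinned spiral
    "traveling_wave"
  } else if (standing$score > antiphase_threshold) {
    "oscillation"
  } else if (planar < planarity_threshold) {
    "traveling_wave"
  } else "unclassified"
  structure(list(label = label,
                 n_rotation_centers = if (label == "rotation")
                   sing$count else 0L,
                 cores = sing$cores, features = feats),
            class = "pattern_class")
}

# Locate the dominant rotation centre in each half of the movie (NULL
# when a half has no dominant frequency, fewer than two full cycles, or
# no core). Used to spot cores that drift across the chamber.
half_cores <- function(movie, border_px = 2L) {
  T_ <- n_frames(movie)
  if (T_ < 16L) return(list(a = NULL, b = NULL))
  half <- T_ %/% 2L
  locate <- function(idx) {
    m <- min_movie(movie$data[, , idx, drop = FALSE],
                   movie$pixel_size_um, movie$frame_interval_s)
    pm <- tryCatch(phase_map(m), error = function(e) NULL)
    if (is.null(pm) || !pm$ok || pm$cycles < 2) return(NULL)
    s <- count_phase_singularities(pm$phase, mask = amplitude_mask(pm$amplitude),
                                   border_px = border_px)
    if (s$count < 1) return(NULL)
    s$cores[1, c("row", "col")]
  }
  list(a = locate(seq_len(half)), b = locate((half + 1L):T_))
}
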