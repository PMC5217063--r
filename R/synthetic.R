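#' Chamber geometry
#'
#' Describes one rectangular microchamber. The chamber length (its long
#' axis, along which oscillations and default waves run) maps to image
#' columns; the width maps to rows. `origin_px` is the (row, col) of the
#' chamber's top-left pixel when the chamber is placed in a larger field.
#'
#' @param width_um chamber width in micrometres (rows).
#' @param length_um chamber length in micrometres (columns).
#' @param height_um chamber height in micrometres (default 2.4, the
#'   fabricated chamber height; not used by the kinematic generators).
#' @param origin_px integer (row, col) origin, 1-based.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(width_um, length_um, height_um = 2.4,
                             origin_px = c(1L, 1L), pixel_size_um = 0.5) {
  stopifnot(width_um > 0, length_um > 0, height_um > 0, pixel_size_um > 0)
  structure(
    list(width_um = width_um, length_um = length_um, height_um = height_um,
         origin_px = as.integer(origin_px), pixel_size_um = pixel_size_um,
         width_px = max(2L, round(width_um / pixel_size_um)),
         length_px = max(2L, round(length_um / pixel_size_um))),
    class = "chamber_geometry"
  )
}

#' Ground-truth pattern parameters for the synthetic generators
#'
#' @param pattern_kind one of `"traveling_wave"`, `"spiral"`,
#'   `"oscillation"`, `"striped_oscillation"`, `"noise_only"`.
#' @param wavelength_um spatial period in micrometres.
#' @param speed_um_s front speed in micrometres per second (waves and
#'   spirals; the spiral temporal period is `wavelength_um / speed_um_s`).
#' @param period_s temporal period in seconds (oscillations; for spirals
#'   it may be given instead of `speed_um_s`).
#' @param direction_deg propagation direction, degrees counter-clockwise
#'   from the +x (column) axis.
#' @param chirality spiral handedness, `+1` or `-1`.
#' @param n_cores number of spiral cores.
#' @param cores_um optional `n_cores x 2` matrix of core (x, y) positions
#'   in micrometres from the chamber's top-left corner; defaults to the
#'   chamber centre for one core and evenly spaced centres along the
#'   length for several.
#' @param amplitude peak-to-trough intensity of the noise-free pattern
#'   (arbitrary units).
#' @param background baseline intensity inside the chamber.
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (intensities are clipped at zero after adding noise).
#' @param asymmetry wave-profile skew in `[0, 1)`; 0 gives the symmetric
#'   raised cosine whose peak spacing equals the wavelength exactly.
#' @param seed integer seed making the generated noise reproducible.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern_kind = c("traveling_wave", "spiral",
                                          "oscillation", "striped_oscillation",
                                          "noise_only"),
                         wavelength_um = 40, speed_um_s = NULL, period_s = NULL,
                         direction_deg = 0, chirality = 1L, n_cores = 1L,
                         cores_um = NULL, amplitude = 100, background = 20,
                         noise_sd = 0, asymmetry = 0, seed = 1L) {
  pattern_kind <- match.arg(pattern_kind)
  stopifnot(wavelength_um > 0, noise_sd >= 0, amplitude >= 0, background >= 0,
            asymmetry >= 0, asymmetry < 1)
  if (!is.null(speed_um_s)) stopifnot(speed_um_s >= 0)
  if (!is.null(period_s)) stopifnot(period_s > 0)
  if (pattern_kind == "spiral") {
    stopifnot(n_cores >= 1L, chirality %in% c(-1L, 1L))
    if (is.null(speed_um_s) && is.null(period_s))
      stop("a spiral needs `speed_um_s` or `period_s`")
  }
  if (pattern_kind == "traveling_wave" && is.null(speed_um_s))
    stop("a traveling wave needs `speed_um_s`")
  if (pattern_kind %in% c("oscillation", "striped_oscillation") &&
      is.null(period_s))
    stop("an oscillation needs `period_s`")
  structure(
    list(pattern_kind = pattern_kind, wavelength_um = wavelength_um,
         speed_um_s = speed_um_s, period_s = period_s,
         direction_deg = direction_deg, chirality = as.integer(chirality),
         n_cores = as.integer(n_cores), cores_um = cores_um,
         amplitude = amplitude, background = background, noise_sd = noise_sd,
         asymmetry = asymmetry, seed = as.integer(seed)),
    class = "pattern_spec"
  )
}

# Evaluate code with a temporary RNG state so generators are reproducible
# without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# (x, y) coordinate grids of a chamber in micrometres (pixel centres).
chamber_grid_um <- function(geom) {
  H <- geom$width_px; W <- geom$length_px; px <- geom$pixel_size_um
  list(x = matrix((seq_len(W) - 0.5) * px, H, W, byrow = TRUE),
       y = matrix((seq_len(H) - 0.5) * px, H, W))
}

# Raised-cosine waveform of unit amplitude with optional sawtooth-like
# skew; phase in radians, period 2*pi, maximum 1 at phase 0.
wave_profile <- function(phase, asymmetry = 0) {
  if (asymmetry > 0) phase <- phase + asymmetry * sin(phase)
  (1 + cos(phase)) / 2
}

add_noise_clip <- function(arr, noise_sd, seed) {
  if (noise_sd > 0) {
    arr <- with_seed(seed, arr + stats::rnorm(length(arr), sd = noise_sd))
    arr[arr < 0] <- 0
  }
  arr
}

#' Generate a confined traveling plane wave
#'
#' Noise-free intensity inside the chamber is
#' `background + amplitude * (1 + cos(2*pi*(x*cos(th) + y*sin(th) - v*t) / lambda)) / 2`,
#' with additive Gaussian noise (SD `noise_sd`) clipped at zero.
#'
#' @param geom a [chamber_geometry].
#' @param spec a [pattern_spec] with `pattern_kind = "traveling_wave"`.
#' @param n_frames number of frames (at least 2).
#' @param frame_interval_s frame interval in seconds.
#' @return A [min_movie] the size of the chamber.
#' @export
generate_traveling_wave <- function(geom, spec, n_frames = 60L,
                                    frame_interval_s = 10) {
  stopifnot(inherits(geom, "chamber_geometry"), inherits(spec, "pattern_spec"))
  if (spec$pattern_kind != "traveling_wave")
    stop("spec$pattern_kind must be 'traveling_wave'")
  if (n_frames < 2L) stop("n_frames must be at least 2")
  if (spec$wavelength_um < 2 * geom$pixel_size_um)
    stop("wavelength below 2 px would alias; refuse to generate")
  g <- chamber_grid_um(geom)
  th <- spec$direction_deg * pi / 180
  u <- g$x * cos(th) + g$y * sin(th)
  arr <- array(0, c(geom$width_px, geom$length_px, n_frames))
  for (t in seq_len(n_frames)) {
    tt <- (t - 1) * frame_interval_s
    ph <- 2 * pi * (u - spec$speed_um_s * tt) / spec$wavelength_um
    arr[, , t] <- spec$background +
      spec$amplitude * wave_profile(ph, spec$asymmetry)
  }
  arr <- add_noise_clip(arr, spec$noise_sd, spec$seed)
  min_movie(arr, geom$pixel_size_um, frame_interval_s)
}

#' Generate rotating spiral waves
#'
#' Each core contributes
#' `background + amplitude * (1 + cos(chi*phi - 2*pi*r/lambda + 2*pi*t/T)) / 2`
#' in polar coordinates `(r, phi)` about the core, with `T =
#' lambda / speed` (or `period_s`). With several cores, each pixel shows
#' the field of its nearest core: fronts from neighbouring spirals
#' annihilate where they meet, so each spiral owns the domain up to the
#' mid-line to its neighbour, as collision boundaries between real
#' spirals do. Intensities stay within `[background, background +
#' amplitude]`.
#'
#' @inheritParams generate_traveling_wave
#' @param spec a [pattern_spec] with `pattern_kind = "spiral"`.
#' @return A [min_movie].
#' @export
generate_spiral <- function(geom, spec, n_frames = 60L, frame_interval_s = 10) {
  stopifnot(inherits(geom, "chamber_geometry"), inherits(spec, "pattern_spec"))
  if (spec$pattern_kind != "spiral")
    stop("spec$pattern_kind must be 'spiral'")
  if (n_frames < 2L) stop("n_frames must be at least 2")
  period <- if (!is.null(spec$period_s)) spec$period_s
            else spec$wavelength_um / spec$speed_um_s
  cores <- spec$cores_um
  if (is.null(cores)) {
    cores <- if (spec$n_cores == 1L) {
      matrix(c(geom$length_um / 2, geom$width_um / 2), 1)
    } else {
      cbind(geom$length_um * (seq_len(spec$n_cores) - 0.5) / spec$n_cores,
            geom$width_um / 2)
    }
  }
  cores <- matrix(cores, ncol = 2)
  if (any(cores[, 1] < 0 | cores[, 1] > geom$length_um |
          cores[, 2] < 0 | cores[, 2] > geom$width_um))
    stop("spiral core outside the chamber")
  g <- chamber_grid_um(geom)
  # per-core polar fields and nearest-core domain assignment
  rr <- list(); pp <- list()
  dist2 <- array(Inf, c(geom$width_px, geom$length_px, nrow(cores)))
  for (k in seq_len(nrow(cores))) {
    dx <- g$x - cores[k, 1]; dy <- g$y - cores[k, 2]
    rr[[k]] <- sqrt(dx^2 + dy^2); pp[[k]] <- atan2(dy, dx)
    dist2[, , k] <- rr[[k]]
  }
  owner <- apply(dist2, c(1, 2), which.min)
  arr <- array(0, c(geom$width_px, geom$length_px, n_frames))
  for (t in seq_len(n_frames)) {
    tt <- (t - 1) * frame_interval_s
    frame <- matrix(0, geom$width_px, geom$length_px)
    for (k in seq_len(nrow(cores))) {
      ph <- spec$chirality * pp[[k]] - 2 * pi * rr[[k]] / spec$wavelength_um +
        2 * pi * tt / period
      f <- spec$background + spec$amplitude * wave_profile(ph, spec$asymmetry)
      sel <- owner == k
      frame[sel] <- f[sel]
    }
    arr[, , t] <- frame
  }
  arr <- add_noise_clip(arr, spec$noise_sd, spec$seed)
  min_movie(arr, geom$pixel_size_um, frame_interval_s)
}

#' Generate pole-to-pole or striped oscillations
#'
#' Every half-period a band of full width `wavelength_um / 2` (a raised
#' cosine bump) is born on the chamber mid-line and translates along the
#' chamber length toward one pole at constant speed, reaching it after a
#' fraction `travel_frac` of the half-period; it then dwells at the pole
#' until it is replaced by the next band, born again at the mid-line and
#' heading for the opposite pole. The dwell reproduces the pole-dominant
#' temporal-STD signature that distinguishes confined oscillations from
#' plain traveling waves. Striped oscillations additionally seed bands on
#' both quarter lines, which translate in the same direction. A
#' `"noise_only"` spec yields white noise about the background, as a
#' degenerate control.
#'
#' @inheritParams generate_traveling_wave
#' @param spec a [pattern_spec] with `pattern_kind` one of
#'   `"oscillation"`, `"striped_oscillation"`, `"noise_only"`.
#' @param travel_frac fraction of each half-period spent traveling (the
#'   rest is spent dwelling at the pole); in `(0, 1]`.
#' @return A [min_movie].
#' @export
generate_oscillation <- function(geom, spec, n_frames = 60L,
                                 frame_interval_s = 10, travel_frac = 0.6) {
  stopifnot(travel_frac > 0, travel_frac <= 1)
  stopifnot(inherits(geom, "chamber_geometry"), inherits(spec, "pattern_spec"))
  if (n_frames < 2L) stop("n_frames must be at least 2")
  arr <- array(0, c(geom$width_px, geom$length_px, n_frames))
  if (spec$pattern_kind == "noise_only") {
    arr[] <- spec$background
    arr <- add_noise_clip(arr, spec$noise_sd, spec$seed)
    return(min_movie(arr, geom$pixel_size_um, frame_interval_s))
  }
  if (!spec$pattern_kind %in% c("oscillation", "striped_oscillation"))
    stop("spec$pattern_kind must be an oscillation kind or 'noise_only'")
  if (spec$period_s <= 2 * frame_interval_s)
    stop("period_s must exceed twice the frame interval")
  g <- chamber_grid_um(geom)
  s <- g$x[1, ]                      # positions along the length, um
  L <- geom$length_um
  half <- spec$period_s / 2
  w <- spec$wavelength_um / 2        # full band width
  starts <- if (spec$pattern_kind == "striped_oscillation")
    c(L / 4, L / 2, 3 * L / 4) else L / 2
  bump <- function(d) ifelse(abs(d) <= w / 2, (1 + cos(2 * pi * d / w)) / 2, 0)
  for (t in seq_len(n_frames)) {
    tt <- (t - 1) * frame_interval_s
    k <- floor(tt / half)
    f <- (tt - k * half) / half      # progress within the half-period
    dir <- if (k %% 2 == 0) 1 else -1
    travelled <- min(f / travel_frac, 1) * (L / 2)
    prof <- rep(0, length(s))
    for (s0 in starts) {
      centre <- s0 + dir * travelled
      prof <- pmax(prof, bump(s - centre))
    }
    arr[, , t] <- spec$background +
      spec$amplitude * matrix(prof, geom$width_px, geom$length_px, byrow = TRUE)
  }
  arr <- add_noise_clip(arr, spec$noise_sd, spec$seed)
  min_movie(arr, geom$pixel_size_um, frame_interval_s)
}

#' Generate a movie for any pattern kind
#'
#' Dispatches on `spec$pattern_kind` to the dedicated generator.
#'
#' @inheritParams generate_traveling_wave
#' @return A [min_movie].
#' @export
generate_pattern <- function(geom, spec, n_frames = 60L, frame_interval_s = 10) {
  switch(spec$pattern_kind,
         traveling_wave = generate_traveling_wave(geom, spec, n_frames,
                                                  frame_interval_s),
         spiral = generate_spiral(geom, spec, n_frames, frame_interval_s),
         generate_oscillation(geom, spec, n_frames, frame_interval_s))
}

#' Draw a randomised cohort of ground-truth chamber movies
#'
#' Samples `n` chamber movies balanced over the three pattern genera
#' (pole-to-pole/striped oscillations, traveling waves, spiral
#' rotations) with geometry and kinematic parameters drawn from the
#' ranges where each pattern is found in confined chambers: oscillations
#' in narrow chambers (width ~10-20 µm), rotations in compact low
#' aspect-ratio chambers, traveling waves in long chambers. Noise is
#' scaled to the pattern amplitude via `noise_frac` (an SNR of 5 means
#' `noise_frac = 0.2`).
#'
#' @param n number of movies.
#' @param noise_frac noise SD as a fraction of the pattern amplitude.
#' @param seed integer seed; the i-th movie of a cohort is reproducible.
#' @param n_frames,frame_interval_s movie length and frame interval.
#' @param pixel_size_um pixel size.
#' @return A list of records: `movie` (background-subtracted not applied),
#'   `geom`, `spec`, `true_label` (the generative genus with striped
#'   modes tagged `"oscillation"`).
#' @export
generate_cohort <- function(n, noise_frac = 0.2, seed = 1L, n_frames = 40L,
                            frame_interval_s = 10, pixel_size_um = 0.5) {
  kinds <- rep(c("oscillation", "striped_oscillation", "traveling_wave",
                 "spiral"), length.out = n)
  lapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, i), {
      kind <- kinds[i]
      amp <- 100
      par <- switch(kind,
        oscillation = {
          W <- sample(c(10, 15, 20), 1); L <- sample(seq(20, 50, 10), 1)
          list(geom = chamber_geometry(W, L, pixel_size_um = pixel_size_um),
               spec = pattern_spec("oscillation",
                                   wavelength_um = stats::runif(1, 25, 45),
                                   period_s = stats::runif(1, 80, 200),
                                   amplitude = amp, background = 20,
                                   noise_sd = noise_frac * amp,
                                   seed = derive_seed(seed, i + 10000L)))
        },
        striped_oscillation = {
          W <- 10; L <- sample(c(50, 60), 1)
          list(geom = chamber_geometry(W, L, pixel_size_um = pixel_size_um),
               spec = pattern_spec("striped_oscillation",
                                   wavelength_um = stats::runif(1, 15, 25),
                                   period_s = stats::runif(1, 100, 200),
                                   amplitude = amp, background = 20,
                                   noise_sd = noise_frac * amp,
                                   seed = derive_seed(seed, i + 10000L)))
        },
        traveling_wave = {
          W <- sample(seq(30, 60, 10), 1); L <- sample(seq(50, 90, 10), 1)
          list(geom = chamber_geometry(W, L, pixel_size_um = pixel_size_um),
               spec = pattern_spec("traveling_wave",
                                   wavelength_um = stats::runif(1, 35, 50),
                                   speed_um_s = stats::runif(1, 0.2, 0.5),
                                   direction_deg = stats::runif(1, -20, 20),
                                   amplitude = amp, background = 20,
                                   noise_sd = noise_frac * amp,
                                   seed = derive_seed(seed, i + 10000L)))
        },
        spiral = {
          W <- sample(seq(20, 50, 10), 1); L <- sample(seq(20, 50, 10), 1)
          list(geom = chamber_geometry(W, L, pixel_size_um = pixel_size_um),
               spec = pattern_spec("spiral",
                                   wavelength_um = stats::runif(1, 15, 30),
                                   speed_um_s = stats::runif(1, 0.1, 0.3),
                                   chirality = sample(c(-1L, 1L), 1),
                                   amplitude = amp, background = 20,
                                   noise_sd = noise_frac * amp,
                                   seed = derive_seed(seed, i + 10000L)))
        })
      movie <- generate_pattern(par$geom, par$spec, n_frames, frame_interval_s)
      list(movie = movie, geom = par$geom, spec = par$spec,
           true_label = if (kind %in% c("oscillation", "striped_oscillation"))
             "oscillation" else if (kind == "spiral") "rotation" else kind)
    })
  })
}

#' Generate a multi-chamber field movie with known chamber positions
#'
#' Places each chamber's pattern into a common field of view at its
#' `origin_px`, with a distinct lower inter-chamber background, then
#' rigidly rotates the whole field (bilinear interpolation). Ground-truth
#' bounding boxes are returned in the rotated frame as the axis-aligned
#' hull of the rotated chamber corners.
#'
#' @param layout list of `list(geom = , spec = )` pairs; the `origin_px`
#'   of each geometry places it in the field.
#' @param field_rotation_deg rigid rotation applied to the whole field.
#' @param n_frames number of frames.
#' @param frame_interval_s frame interval in seconds.
#' @param field_background intensity of the inter-chamber area; must be
#'   below the chamber backgrounds to create segmentable steps.
#' @param margin_px blank border around the outermost chambers.
#' @return A list with `movie` (a [min_movie]) and `boxes`, a tibble with
#'   1-based inclusive pixel bounds `r0, r1, c0, c1` per chamber.
#' @export
generate_field <- function(layout, field_rotation_deg = 0, n_frames = 30L,
                           frame_interval_s = 10, field_background = 4,
                           margin_px = 10L) {
  stopifnot(length(layout) >= 1)
  px <- layout[[1]]$geom$pixel_size_um
  boxes <- do.call(rbind, lapply(layout, function(ch) {
    g <- ch$geom
    c(r0 = g$origin_px[1], r1 = g$origin_px[1] + g$width_px - 1L,
      c0 = g$origin_px[2], c1 = g$origin_px[2] + g$length_px - 1L)
  }))
  # pairwise overlap check
  if (nrow(boxes) > 1) {
    for (i in seq_len(nrow(boxes) - 1)) for (j in (i + 1):nrow(boxes)) {
      a <- boxes[i, ]; b <- boxes[j, ]
      if (a["r0"] <= b["r1"] && b["r0"] <= a["r1"] &&
          a["c0"] <= b["c1"] && b["c0"] <= a["c1"])
        stop("chambers ", i, " and ", j, " overlap")
    }
  }
  H <- max(boxes[, "r1"]) + margin_px
  W <- max(boxes[, "c1"]) + margin_px
  arr <- array(field_background, c(H, W, n_frames))
  for (i in seq_along(layout)) {
    ch <- layout[[i]]
    stopifnot(abs(ch$geom$pixel_size_um - px) < 1e-12)
    m <- generate_pattern(ch$geom, ch$spec, n_frames, frame_interval_s)
    arr[boxes[i, "r0"]:boxes[i, "r1"], boxes[i, "c0"]:boxes[i, "c1"], ] <-
      m$data
  }
  if (field_rotation_deg != 0) {
    for (t in seq_len(n_frames))
      arr[, , t] <- rotate_image(arr[, , t], field_rotation_deg,
                                 fill = field_background)
    rot_boxes <- t(apply(boxes, 1, function(b) {
      corners <- cbind(c(b["r0"], b["r0"], b["r1"], b["r1"]),
                       c(b["c0"], b["c1"], b["c0"], b["c1"]))
      rc <- rotate_point(corners, field_rotation_deg, c(H, W))
      c(r0 = min(rc[, 1]), r1 = max(rc[, 1]),
        c0 = min(rc[, 2]), c1 = max(rc[, 2]))
    }))
    boxes <- rot_boxes
  }
  list(movie = min_movie(arr, px, frame_interval_s),
       boxes = tibble::as_tibble(as.data.frame(boxes)))
}
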