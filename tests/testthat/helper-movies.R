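# Shared synthetic fixtures, built in code at test time.

wave_movie <- function(wavelength_um = 43, speed_um_s = 0.3, W = 50, L = 60,
                       px = 0.5, n_frames = 60, noise_sd = 0, seed = 1,
                       direction_deg = 0, dt = 10) {
  geom <- chamber_geometry(W, L, pixel_size_um = px)
  spec <- pattern_spec("traveling_wave", wavelength_um = wavelength_um,
                       speed_um_s = speed_um_s, direction_deg = direction_deg,
                       amplitude = 100, background = 20,
                       noise_sd = noise_sd, seed = seed)
  generate_traveling_wave(geom, spec, n_frames, dt)
}

spiral_movie <- function(wavelength_um = 20, speed_um_s = 0.2, W = 40, L = 40,
                         px = 0.5, n_frames = 60, noise_sd = 0, seed = 1,
                         n_cores = 1, cores_um = NULL, chirality = 1) {
  geom <- chamber_geometry(W, L, pixel_size_um = px)
  spec <- pattern_spec("spiral", wavelength_um = wavelength_um,
                       speed_um_s = speed_um_s, n_cores = n_cores,
                       cores_um = cores_um, chirality = chirality,
                       amplitude = 100, background = 20,
                       noise_sd = noise_sd, seed = seed)
  generate_spiral(geom, spec, n_frames, 10)
}

osc_movie <- function(wavelength_um = 30, period_s = 120, W = 10, L = 30,
                      px = 0.5, n_frames = 60, noise_sd = 0, seed = 1,
                      kind = "oscillation") {
  geom <- chamber_geometry(W, L, pixel_size_um = px)
  spec <- pattern_spec(kind, wavelength_um = wavelength_um,
                       period_s = period_s, amplitude = 100, background = 20,
                       noise_sd = noise_sd, seed = seed)
  generate_oscillation(geom, spec, n_frames, 10)
}

# 2 x 3 chamber field with one pattern kind per chamber.
demo_field <- function(rotation = 0, n_frames = 40, noise_sd = 5, seed = 1) {
  kinds <- c("traveling_wave", "spiral", "oscillation")
  layout <- list()
  idx <- 1
  for (i in 0:1) for (j in 0:2) {
    g <- chamber_geometry(20, 30, origin_px = c(16 + i * 60, 16 + j * 80),
                          pixel_size_um = 0.5)
    k <- kinds[j + 1]
    s <- switch(k,
      traveling_wave = pattern_spec("traveling_wave", wavelength_um = 25,
                                    speed_um_s = 0.3, amplitude = 100,
                                    background = 20, noise_sd = noise_sd,
                                    seed = seed + idx),
      spiral = pattern_spec("spiral", wavelength_um = 20, speed_um_s = 0.2,
                            amplitude = 100, background = 20,
                            noise_sd = noise_sd, seed = seed + idx),
      oscillation = pattern_spec("oscillation", wavelength_um = 25,
                                 period_s = 120, amplitude = 100,
                                 background = 20, noise_sd = noise_sd,
                                 seed = seed + idx))
    layout[[idx]] <- list(geom = g, spec = s)
    idx <- idx + 1
  }
  generate_field(layout, field_rotation_deg = rotation, n_frames = n_frames)
}

linear_curve <- function(slope = 2, cmax = 30, species = "MinE_Cy5") {
  conc <- seq(0.5, cmax, by = 0.5)
  fit_calibration(data.frame(concentration_uM = conc, signal = slope * conc),
                  "linear_through_origin", species = species)
}
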