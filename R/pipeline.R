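#' Pipeline configuration
#'
#' Central knob collection for [run_pipeline()]. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param rotation_deg explicit rotation override (degrees); `NULL`
#'   estimates it from the movie.
#' @param boxes explicit chamber boxes (tibble `r0, r1, c0, c1`),
#'   overriding automatic segmentation — the human-correction hook.
#' @param reference `"mean"` or `"std"`: reference image for
#'   segmentation.
#' @param band_px kymograph band width (odd).
#' @param smooth_px,min_contrast segmentation parameters, see
#'   [segment_chambers()].
#' @param antiphase_threshold,planarity_threshold classifier thresholds,
#'   see [classify_pattern()].
#' @param prominence_factor peak-detection prominence (row-SD units).
#' @param design_step_um chamber sizes are snapped to this design grid
#'   when reporting `W_um` / `L_um` (the fabricated layouts come in
#'   10 um steps).
#' @param seed integer seed for any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(rotation_deg = NULL, boxes = NULL,
                            reference = c("mean", "std"), band_px = 3L,
                            smooth_px = 5L, min_contrast = 1.2,
                            antiphase_threshold = 0.6,
                            planarity_threshold = 0.25 * 2 * pi,
                            prominence_factor = 0.5,
                            design_step_um = 10, seed = 1L) {
  reference <- match.arg(reference)
  stopifnot(band_px >= 1, band_px %% 2 == 1, smooth_px >= 1,
            min_contrast > 0, design_step_um > 0)
  structure(list(rotation_deg = rotation_deg, boxes = boxes,
                 reference = reference, band_px = as.integer(band_px),
                 smooth_px = as.integer(smooth_px),
                 min_contrast = min_contrast,
                 antiphase_threshold = antiphase_threshold,
                 planarity_threshold = planarity_threshold,
                 prominence_factor = prominence_factor,
                 design_step_um = design_step_um, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; unknown keys raise an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full chamber-analysis pipeline on one field movie
#'
#' Fixed stage order: rotation correction (estimated, or overridden by
#' the config's human-correction hook), chamber segmentation on the
#' time-average (or temporal-STD) reference image, per-chamber cropping
#' and scalar background subtraction, quadrant summaries,
#' classification, and wave measurement. A failing stage is logged with
#' its chamber id; remaining chambers are still processed.
#'
#' @param movie a [min_movie] of the whole field, or a TIFF path
#'   readable by [read_movie()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the segmentation,
#'   class and wave tables are written as CSV and the quadrants as PNG.
#' @return A list: `rotation_deg`, `segmentation`, `chambers` (tibble
#'   with geometry, label, scores and wave metrics per chamber),
#'   `quadrants` (list), `log` (character vector of stage messages).
#' @export
run_pipeline <- function(movie, config = pipeline_config(), out_dir = NULL) {
  if (is.character(movie)) movie <- read_movie(movie)
  stopifnot(inherits(movie, "min_movie"), inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  rot <- config$rotation_deg
  if (is.null(rot)) {
    rot <- tryCatch(estimate_rotation(movie), error = function(e) {
      note("rotation estimate failed: %s", conditionMessage(e)); 0
    })
  }
  note("rotation correction: %.2f deg", rot)
  work <- if (rot != 0) rotate_movie(movie, rot,
                                     fill = stats::median(movie$data)) else movie

  seg <- NULL
  if (!is.null(config$boxes)) {
    seg <- structure(list(boxes = tibble::as_tibble(config$boxes),
                          row_profile = NULL, col_profile = NULL,
                          rotation_deg = rot),
                     class = "segmentation_result")
    note("segmentation: %d boxes supplied by config", nrow(seg$boxes))
  } else {
    ref <- if (config$reference == "mean") mean_image(work)
           else compute_std_image(work)
    seg <- segment_chambers(ref, smooth_px = config$smooth_px,
                            min_contrast = config$min_contrast)
    seg$rotation_deg <- rot
    note("segmentation: %d boxes detected", nrow(seg$boxes))
  }

  px <- movie$pixel_size_um
  snap <- function(um) config$design_step_um *
    round(um / config$design_step_um)
  chambers <- list(); quadrants <- list()
  for (i in seq_len(nrow(seg$boxes))) {
    box <- seg$boxes[i, ]
    res <- tryCatch({
      ch <- crop_movie(work, box)
      ch <- subtract_background(ch)
      quad <- compose_quadrant(ch, band_px = min(config$band_px,
                                                 2L * (min(dim(ch$data)[1:2]) %/% 2L) - 1L))
      cls <- classify_pattern(ch,
                              antiphase_threshold = config$antiphase_threshold,
                              planarity_threshold = config$planarity_threshold)
      wave <- if (cls$label %in% c("traveling_wave", "rotation")) {
        tryCatch(measure_wave(ch, prominence_factor = config$prominence_factor),
                 error = function(e) NULL)
      } else NULL
      quadrants[[i]] <- quad
      tibble::tibble(
        chamber_id = i,
        W_um = snap(nrow(ch$data) * px), L_um = snap(ncol(ch$data) * px),
        r0 = box$r0, r1 = box$r1, c0 = box$c0, c1 = box$c1,
        label = cls$label, n_centers = cls$n_rotation_centers,
        dominant_period_s = 1 / cls$features$freq_hz,
        antiphase = cls$features$antiphase,
        planarity = cls$features$planarity,
        wavelength_um = if (is.null(wave)) NA_real_ else wave$wavelength_um,
        velocity_um_s = if (is.null(wave)) NA_real_ else wave$velocity_um_s)
    }, error = function(e) {
      note("chamber %d failed: %s", i, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) chambers[[i]] <- res
  }
  chambers <- dplyr::bind_rows(chambers)
  note("classified %d/%d chambers", nrow(chambers), nrow(seg$boxes))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(seg$boxes, file.path(out_dir, "segmentation.csv"),
                     row.names = FALSE)
    utils::write.csv(chambers, file.path(out_dir, "chambers.csv"),
                     row.names = FALSE)
    for (i in seq_along(quadrants)) {
      if (!is.null(quadrants[[i]]))
        render_quadrant(quadrants[[i]],
                        file.path(out_dir, sprintf("quadrant_%02d.png", i)))
    }
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  list(rotation_deg = rot, segmentation = seg, chambers = chambers,
       quadrants = quadrants, log = log)
}
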