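#' Estimate the field rotation angle
#'
#' The correction angle is found by minimising, over a grid of candidate
#' angles, the sum over image rows of the per-row standard deviation of
#' the rotated time-averaged image. When the chamber grid is aligned with
#' the pixel axes, rows between chambers are flat and the objective is
#' minimal; ties are broken toward the smallest `|angle|`. The default is
#' a coarse search over ±10° in 0.5° steps refined by ±0.5° in 0.05°
#' steps around the coarse optimum.
#'
#' @param movie a [min_movie] of the whole field.
#' @param angle_grid optional numeric vector of candidate angles
#'   (degrees). When supplied, only this grid is searched (no
#'   refinement).
#' @param coarse_step,fine_step,range_deg parameters of the default
#'   two-stage search.
#' @return The correction angle in degrees: rotating the movie by this
#'   angle aligns the chambers with the pixel axes.
#' @export
estimate_rotation <- function(movie, angle_grid = NULL, range_deg = 10,
                              coarse_step = 0.5, fine_step = 0.05) {
  ref <- mean_image(movie)
  if (stats::sd(ref) < .Machine$double.eps^0.5 * max(1, mean(ref)))
    stop("spatially uniform average image: rotation objective is degenerate")
  fill <- stats::median(ref)
  objective <- function(a) {
    rot <- rotate_image(ref, a, fill = fill)
    sum(apply(rot, 1, stats::sd))
  }
  pick <- function(grid) {
    vals <- vapply(grid, objective, numeric(1))
    best <- which(vals == min(vals))
    grid[best][which.min(abs(grid[best]))]   # tie-break toward 0
  }
  if (!is.null(angle_grid)) {
    stopifnot(length(angle_grid) >= 1)
    return(pick(sort(angle_grid)))
  }
  coarse <- pick(seq(-range_deg, range_deg, by = coarse_step))
  pick(seq(coarse - coarse_step, coarse + coarse_step, by = fine_step))
}

# Detect plateau-crossing steps in a smoothed 1-D marginal profile.
# Hysteresis thresholding: segments are seeded where the profile crosses
# the midpoint between the background and foreground plateaus and grown
# outward while it stays above a low threshold just over the background
# plateau. Chamber interiors whose time-average dips (e.g. oscillation
# chambers, dim between the dwell zones) stay in one piece because the
# dip remains well above the inter-chamber background.
# Returns inclusive (start, end) index pairs of high plateaus.
profile_steps <- function(profile, smooth_px = 5L, grow_frac = 0.15,
                          min_width = 4L) {
  k <- rep(1 / smooth_px, smooth_px)
  sm <- stats::filter(profile, k, sides = 2)
  sm[is.na(sm)] <- profile[is.na(sm)]
  sm <- as.numeric(sm)
  lo <- stats::quantile(sm, 0.1); hi <- stats::quantile(sm, 0.9)
  if (hi - lo <= .Machine$double.eps^0.5 * max(1, abs(hi)))
    return(matrix(numeric(0), 0, 2))
  seed_th <- (lo + hi) / 2
  grow_th <- lo + grow_frac * (hi - lo)
  above <- sm > grow_th
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  keep <- vapply(seq_along(starts), function(i) {
    any(sm[starts[i]:ends[i]] > seed_th) &&
      (ends[i] - starts[i] + 1L) >= min_width
  }, logical(1))
  cbind(starts[keep], ends[keep])
}

#' Segment a field into chamber bounding boxes
#'
#' Implements step detection on the row-sum and column-sum marginal
#' profiles of a reference image (typically the time-average or
#' temporal-STD frame of a rotation-corrected movie): each profile is
#' smoothed with a short moving average and thresholded at the midpoint
#' between its background and foreground plateaus; the Cartesian product
#' of high intervals yields candidate boxes, which are kept when their
#' interior mean exceeds the inter-box background level by
#' `min_contrast`.
#'
#' @param reference_image 2-D matrix.
#' @param smooth_px moving-average width for the marginal profiles.
#' @param min_contrast required ratio of box interior mean to the
#'   background level outside all candidate boxes.
#' @return A list of class `segmentation_result` with `boxes` (tibble of
#'   1-based inclusive `r0, r1, c0, c1`), the marginal `row_profile` and
#'   `col_profile`, and `rotation_deg` (filled in by [run_pipeline()]).
#' @export
segment_chambers <- function(reference_image, smooth_px = 5L,
                             min_contrast = 1.2) {
  row_profile <- rowMeans(reference_image)
  col_profile <- colMeans(reference_image)
  rsteps <- profile_steps(row_profile, smooth_px)
  csteps <- profile_steps(col_profile, smooth_px)
  boxes <- NULL
  if (nrow(rsteps) > 0 && nrow(csteps) > 0) {
    cand <- expand.grid(ri = seq_len(nrow(rsteps)), ci = seq_len(nrow(csteps)))
    boxes <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      r <- rsteps[cand$ri[i], ]; c <- csteps[cand$ci[i], ]
      data.frame(r0 = r[1], r1 = r[2], c0 = c[1], c1 = c[2])
    }))
    # background = intensity outside the union of candidate boxes
    mask <- matrix(FALSE, nrow(reference_image), ncol(reference_image))
    for (i in seq_len(nrow(boxes)))
      mask[boxes$r0[i]:boxes$r1[i], boxes$c0[i]:boxes$c1[i]] <- TRUE
    bg <- if (any(!mask)) mean(reference_image[!mask]) else 0
    keep <- vapply(seq_len(nrow(boxes)), function(i) {
      interior <- reference_image[boxes$r0[i]:boxes$r1[i],
                                  boxes$c0[i]:boxes$c1[i]]
      bg <= 0 || mean(interior) > min_contrast * bg
    }, logical(1))
    boxes <- boxes[keep, , drop = FALSE]
  }
  if (is.null(boxes) || nrow(boxes) == 0) {
    warning("no intensity steps found; returning an empty segmentation")
    boxes <- data.frame(r0 = numeric(0), r1 = numeric(0),
                        c0 = numeric(0), c1 = numeric(0))
  }
  structure(list(boxes = tibble::as_tibble(boxes),
                 row_profile = row_profile, col_profile = col_profile,
                 rotation_deg = 0),
            class = "segmentation_result")
}

#' Threshold mask of a single frame
#'
#' Otsu's method on the frame histogram by default; the frame mean and a
#' quantile cut are available as alternatives.
#'
#' @param frame 2-D matrix of finite intensities.
#' @param method `"otsu"`, `"mean"` or `"percentile"`.
#' @param percentile cut level for `method = "percentile"`.
#' @return A logical matrix, `TRUE` where the intensity exceeds the
#'   threshold. A constant frame yields an all-`FALSE` mask with a
#'   warning.
#' @export
threshold_frame <- function(frame, method = c("otsu", "mean", "percentile"),
                            percentile = 0.7) {
  method <- match.arg(method)
  stopifnot(all(is.finite(frame)))
  if (diff(range(frame)) == 0) {
    warning("constant frame: no threshold exists, returning all-FALSE mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  th <- switch(method,
               otsu = otsu_threshold(frame),
               mean = mean(frame),
               percentile = stats::quantile(frame, percentile))
  frame > th
}

#' Subtract the chamber-mean intensity
#'
#' Subtracts the scalar mean over all pixels and frames of a cropped
#' chamber movie (`mode = "scalar"`, the default), or the per-pixel
#' temporal mean (`mode = "pixel"`). Negative values are preserved.
#'
#' @param chamber_movie a [min_movie] already cropped to one chamber.
#' @param mode `"scalar"` or `"pixel"`.
#' @return A background-subtracted [min_movie].
#' @export
subtract_background <- function(chamber_movie, mode = c("scalar", "pixel")) {
  mode <- match.arg(mode)
  d <- chamber_movie$data
  d <- if (mode == "scalar") d - mean(d) else {
    sweep(d, c(1, 2), mean_image(chamber_movie))
  }
  out <- chamber_movie
  out$data <- d
  out
}

#' Crop a movie to a bounding box
#'
#' @param movie a [min_movie].
#' @param box a row of a segmentation `boxes` table (`r0, r1, c0, c1`,
#'   1-based inclusive; fractional bounds are rounded inward).
#' @return The cropped [min_movie].
#' @export
crop_movie <- function(movie, box) {
  r0 <- max(1L, ceiling(box$r0)); r1 <- min(nrow(movie$data), floor(box$r1))
  c0 <- max(1L, ceiling(box$c0)); c1 <- min(ncol(movie$data), floor(box$c1))
  stopifnot(r1 > r0, c1 > c0)
  min_movie(movie$data[r0:r1, c0:c1, , drop = FALSE],
            movie$pixel_size_um, movie$frame_interval_s)
}
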