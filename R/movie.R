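#' Time-lapse movie container
#'
#' A `min_movie` bundles a single-channel fluorescence stack with its
#' physical calibration. The intensity data are stored as a 3-D array with
#' dimensions `(rows, columns, frames)`; row index increases downward,
#' column index to the right, and angles throughout the package are
#' measured counter-clockwise from the +x (column) axis in that pixel
#' coordinate frame.
#'
#' @param data numeric 3-D array `(H, W, T)` of intensities; all values
#'   must be finite and at least two frames are required.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @return An object of class `min_movie`: a list with elements `data`,
#'   `pixel_size_um` and `frame_interval_s`.
#' @export
min_movie <- function(data, pixel_size_um, frame_interval_s) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows, cols, frames)")
  if (dim(data)[3] < 2L)
    stop("a movie needs at least 2 frames")
  if (!all(is.finite(data)))
    stop("movie intensities must be finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "min_movie"
  )
}

#' @export
print.min_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<min_movie> %d x %d px, %d frames | %.3g um/px, %.3g s/frame (%.3g x %.3g um, %.0f s)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s,
    d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
    (d[3] - 1) * x$frame_interval_s))
  invisible(x)
}

#' @export
dim.min_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

#' Extract one frame of a movie
#'
#' @param movie a [min_movie].
#' @param t frame index (1-based).
#' @return A 2-D numeric matrix.
#' @export
movie_frame <- function(movie, t) {
  stopifnot(t >= 1, t <= n_frames(movie))
  movie$data[, , t]
}

#' Temporal mean image of a movie
#'
#' @param movie a [min_movie].
#' @return A 2-D matrix, the per-pixel mean over frames.
#' @export
mean_image <- function(movie) {
  rowMeans(movie$data, dims = 2L)
}

#' Read a movie from a multi-frame TIFF with a YAML sidecar
#'
#' The sidecar (by default `<stem>.yaml` next to the TIFF) must provide
#' `pixel_size_um` and `frame_interval_s`.
#'
#' @param path path to a multi-frame TIFF.
#' @param meta optional path to the YAML metadata file.
#' @return A [min_movie].
#' @export
read_movie <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- paste0(sub("\\.tiff?$", "", path), ".yaml")
  if (!file.exists(meta))
    stop("metadata file not found: ", meta)
  m <- yaml::read_yaml(meta)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3L) f <- f[, , 1]  # first channel of RGB TIFFs
    arr[, , t] <- f
  }
  scale <- if (is.null(m$intensity_scale)) 1 else m$intensity_scale
  min_movie(arr * scale, m$pixel_size_um, m$frame_interval_s)
}

#' Write a movie as a multi-frame TIFF plus YAML sidecar
#'
#' Intensities are rescaled to `[0, 1]` for 16-bit TIFF storage; the scale
#' factor is recorded in the sidecar (`intensity_scale`) so [read_movie()]
#' restores the original values.
#'
#' @param movie a [min_movie].
#' @param path output TIFF path; the sidecar is written as `<stem>.yaml`.
#' @param extra named list merged into the sidecar (e.g. ground-truth
#'   pattern parameters).
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(movie, path, extra = list()) {
  hi <- max(movie$data)
  scale <- if (hi > 0) hi else 1
  frames <- lapply(seq_len(n_frames(movie)),
                   function(t) movie$data[, , t] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- c(list(pixel_size_um = movie$pixel_size_um,
                 frame_interval_s = movie$frame_interval_s,
                 intensity_scale = scale), extra)
  sidecar <- paste0(sub("\\.tiff?$", "", path), ".yaml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}
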