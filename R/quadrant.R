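#' Temporal standard-deviation image
#'
#' Per-pixel population standard deviation over frames (divisor `T`, not
#' `T - 1`, so a two-frame movie with values \{0, 2\} gives exactly 1).
#'
#' @param movie a [min_movie].
#' @return A 2-D matrix of per-pixel temporal SDs.
#' @export
compute_std_image <- function(movie) {
  mu <- mean_image(movie)
  sq <- rowMeans(movie$data^2, dims = 2L)
  sqrt(pmax(sq - mu^2, 0))
}

#' Midline kymographs
#'
#' `kymo_xt` stacks, per frame, the mean over `band_px` rows centred on
#' the horizontal mid-line (one kymograph row per frame, columns =
#' space). `kymo_yt` is the analogue for the vertical mid-line, arranged
#' with space along rows and time along columns.
#'
#' @param movie a [min_movie].
#' @param band_px odd number of lines averaged across the mid-line.
#' @return A list with `kymo_xt` (`T x W`) and `kymo_yt` (`H x T`).
#' @export
midline_kymographs <- function(movie, band_px = 3L) {
  if (band_px < 1L || band_px %% 2L != 1L)
    stop("band_px must be a positive odd count")
  d <- dim(movie$data)
  if (band_px > d[1] || band_px > d[2])
    stop("band_px is wider than the chamber")
  half <- (band_px - 1L) %/% 2L
  mid_r <- (d[1] + 1L) %/% 2L
  mid_c <- (d[2] + 1L) %/% 2L
  rows <- (mid_r - half):(mid_r + half)
  cols <- (mid_c - half):(mid_c + half)
  kymo_xt <- matrix(0, d[3], d[2])
  kymo_yt <- matrix(0, d[1], d[3])
  for (t in seq_len(d[3])) {
    kymo_xt[t, ] <- colMeans(matrix(movie$data[rows, , t], length(rows), d[2]))
    kymo_yt[, t] <- rowMeans(matrix(movie$data[, cols, t], d[1], length(cols)))
  }
  list(kymo_xt = kymo_xt, kymo_yt = kymo_yt)
}

#' Quadrant summary of one chamber movie
#'
#' Bundles the four standard per-chamber views: a representative frame
#' (the middle frame by default), the temporal-STD image, and the two
#' midline kymographs.
#'
#' @param movie a [min_movie].
#' @param band_px kymograph band width (odd).
#' @param frame_index representative frame; defaults to `floor(T / 2)`
#'   (0-based convention), i.e. frame `floor(T / 2) + 1` in R indexing
#'   reported back as the 0-based value.
#' @return An object of class `quadrant_summary` with elements `frame`,
#'   `std_image`, `kymo_xt`, `kymo_yt`, `frame_index`.
#' @export
compose_quadrant <- function(movie, band_px = 3L, frame_index = NULL) {
  T_ <- n_frames(movie)
  if (is.null(frame_index)) frame_index <- T_ %/% 2L
  stopifnot(frame_index >= 0L, frame_index < T_)
  k <- midline_kymographs(movie, band_px)
  structure(
    list(frame = movie$data[, , frame_index + 1L],
         std_image = compute_std_image(movie),
         kymo_xt = k$kymo_xt, kymo_yt = k$kymo_yt,
         frame_index = frame_index),
    class = "quadrant_summary"
  )
}

# 16-level colour lookup table used for quadrant rendering.
quadrant_lut <- function() {
  grDevices::hcl.colors(16L, "Spectral", rev = TRUE)
}

# Map a matrix to an RGB array through the 16-colour LUT.
lut_rgb <- function(img, lut = quadrant_lut()) {
  rng <- range(img)
  idx <- if (diff(rng) > 0)
    pmin(16L, 1L + floor((img - rng[1]) / diff(rng) * 16)) else
    matrix(1L, nrow(img), ncol(img))
  cols <- grDevices::col2rgb(lut) / 255
  arr <- array(0, c(nrow(img), ncol(img), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(cols[ch, idx], nrow(img))
  arr
}

#' Render a quadrant summary to a PNG file
#'
#' The four panes follow the standard arrangement: representative frame
#' upper-left, Yt kymograph upper-right, Xt kymograph lower-left,
#' temporal-STD image lower-right, all colour-coded with a 16-level
#' lookup table.
#'
#' @param quad a `quadrant_summary`.
#' @param path output PNG path.
#' @param gap_px separator width between panes.
#' @return Invisibly, the assembled RGB array (also written to `path`).
#' @export
render_quadrant <- function(quad, path = NULL, gap_px = 2L) {
  # Xt sits under the frame (shared space axis, time running down); Yt
  # sits beside it (shared space axis, time running right)
  panes <- list(ul = lut_rgb(quad$frame), ur = lut_rgb(quad$kymo_yt),
                ll = lut_rgb(quad$kymo_xt), lr = lut_rgb(quad$std_image))
  hs <- vapply(panes, function(p) dim(p)[1], numeric(1))
  ws <- vapply(panes, function(p) dim(p)[2], numeric(1))
  top_h <- max(hs["ul"], hs["ur"]); bot_h <- max(hs["ll"], hs["lr"])
  left_w <- max(ws["ul"], ws["ll"]); right_w <- max(ws["ur"], ws["lr"])
  H <- top_h + bot_h + gap_px; W <- left_w + right_w + gap_px
  out <- array(1, c(H, W, 3))
  put <- function(p, r, c) {
    d <- dim(p)
    out[r:(r + d[1] - 1), c:(c + d[2] - 1), ] <<- p
  }
  put(panes$ul, 1, 1)
  put(panes$ur, 1, left_w + gap_px + 1)
  put(panes$ll, top_h + gap_px + 1, 1)
  put(panes$lr, top_h + gap_px + 1, left_w + gap_px + 1)
  if (!is.null(path)) png::writePNG(out, path)
  invisible(out)
}
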