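# Shared numeric helpers: phase wrapping, bilinear rotation/sampling,
# Otsu thresholding, 1-D peak detection with prominence.

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# Bilinear sample of matrix `img` at fractional (row, col) positions.
# Points outside the grid return `fill`.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  inside <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  r0 <- pmin(pmax(floor(rows), 1L), H - 1L)
  c0 <- pmin(pmax(floor(cols), 1L), W - 1L)
  fr <- rows - r0
  fc <- cols - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  val <- (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
  val[!inside] <- fill
  val
}

#' Rotate an image about its centre
#'
#' Rigid rotation by `angle_deg` (counter-clockwise in the package's pixel
#' frame, i.e. positive x along columns, positive y along rows) with
#' bilinear interpolation. Output has the same dimensions; pixels sampled
#' from outside the source are set to `fill`. The centre of rotation is
#' `((H + 1) / 2, (W + 1) / 2)`, which [rotate_point()] uses as well so
#' that coordinates and images transform consistently.
#'
#' @param img 2-D numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param fill value for pixels mapped from outside the source image.
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(img, angle_deg, fill = 0) {
  if (angle_deg == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  # inverse map: for each output pixel find its source location
  rr <- matrix(seq_len(H), H, W) - cr
  cc_ <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  # rotation by +th maps source (x, y) -> (x cos - y sin, x sin + y cos)
  # with x = col offset, y = row offset; invert with -th
  src_c <- cc_ * cos(th) + rr * sin(th) + cc
  src_r <- -cc_ * sin(th) + rr * cos(th) + cr
  out <- bilinear_sample(img, as.vector(src_r), as.vector(src_c), fill = fill)
  matrix(out, H, W)
}

#' Rotate points about the image centre
#'
#' Forward transform matching [rotate_image()]: a feature at `(row, col)`
#' in the unrotated image appears at the returned position after the image
#' is rotated by `angle_deg`.
#'
#' @param rc two-column matrix (row, col) of positions.
#' @param angle_deg rotation angle in degrees.
#' @param dim image dimensions `c(H, W)`.
#' @return Two-column matrix of rotated (row, col) positions.
#' @export
rotate_point <- function(rc, angle_deg, dim) {
  th <- angle_deg * pi / 180
  cr <- (dim[1] + 1) / 2; cc <- (dim[2] + 1) / 2
  y <- rc[, 1] - cr; x <- rc[, 2] - cc
  cbind(row = x * sin(th) + y * cos(th) + cr,
        col = x * cos(th) - y * sin(th) + cc)
}

#' Rotate every frame of a movie
#'
#' @param movie a [min_movie].
#' @param angle_deg rotation in degrees (counter-clockwise, see
#'   [rotate_image()]).
#' @param fill fill value outside the source frame.
#' @return A rotated [min_movie].
#' @export
rotate_movie <- function(movie, angle_deg, fill = 0) {
  out <- movie$data
  for (t in seq_len(n_frames(movie)))
    out[, , t] <- rotate_image(movie$data[, , t], angle_deg, fill = fill)
  min_movie(out, movie$pixel_size_um, movie$frame_interval_s)
}

# Otsu threshold of a numeric matrix (EBImage backend). Returns the
# threshold on the intensity scale of `x`, or NA for a constant input.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  th <- EBImage::otsu(EBImage::Image(x), range = rng, levels = 256L)
  as.numeric(th)
}

# Local maxima of a 1-D signal with prominence filtering.
# A peak's prominence is its height above the higher of the two minima
# separating it from neighbouring higher terrain (standard definition).
# Returns integer positions, sorted.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  core <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(core) == 0) return(integer(0))
  keep <- vapply(core, function(p) {
    # walk left until higher point or edge; track the minimum
    lmin <- y[p]; i <- p
    while (i > 1 && y[i - 1] <= y[p]) { i <- i - 1; lmin <- min(lmin, y[i]) }
    lbase <- if (i == 1 && y[i] <= y[p]) min(lmin, y[1]) else lmin
    rmin <- y[p]; i <- p
    while (i < n && y[i + 1] <= y[p]) { i <- i + 1; rmin <- min(rmin, y[i]) }
    rbase <- if (i == n && y[i] <= y[p]) min(rmin, y[n]) else rmin
    (y[p] - max(lbase, rbase)) >= min_prominence
  }, logical(1))
  core[keep]
}

# Deterministic sub-seed derivation so one user seed drives several
# independent random stages without reuse.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
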