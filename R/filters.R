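#' Gaussian kernel
#'
#' Kernel weights on an integer grid centered at the kernel's geometric
#' center, normalized to sum 1. For an even size the center falls between
#' samples (half-integer positions), matching the common fixed-size
#' convention.
#'
#' @param size side length in pixels.
#' @param sigma standard deviation in pixels.
#' @return size x size numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(size = 10L, sigma = 4) {
  if (size < 1 || sigma <= 0)
    stop_typed("bad_input", "gaussian_kernel: need size >= 1, sigma > 0")
  x <- seq_len(size) - 1 - (size - 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' 2-D correlation with reflective or replicate borders
#'
#' @param mat numeric matrix.
#' @param kernel numeric matrix; its origin is `floor(dim/2)` (0-based).
#' @param border "reflect" (half-sample) or "replicate".
#' @return numeric matrix of the same shape.
#' @export
correlate2 <- function(mat, kernel, border = c("reflect", "replicate")) {
  border <- match.arg(border)
  cpp_correlate2(as_pixels(mat), kernel,
                 as.integer(nrow(kernel) %/% 2), as.integer(ncol(kernel) %/% 2),
                 border)
}

#' Pre-smoothing filters for OCT B-scans
#'
#' `gaussian_smooth()` convolves with a 10 x 10 Gaussian of standard
#' deviation 4 (reflective borders); `median_filter()` applies a 3 x 3 median,
#' effective against residual speckle. Both preserve the container class and
#' axial pitch.
#'
#' @param img an `oct_image`, `gray_image` or plain matrix.
#' @param size,sigma Gaussian kernel size and SD.
#' @param radius median window radius (1 = 3 x 3).
#' @return same container type as the input.
#' @export
gaussian_smooth <- function(img, size = 10L, sigma = 4) {
  px <- clamp01(gaussian_blur(as_pixels(img), sigma, size))
  rewrap(img, px)
}

# separable Gaussian: two 1-D passes, identical to the full 2-D correlation
# because the kernel is an outer product and reflect indexing is per-axis
gaussian_blur <- function(mat, sigma, size = 2L * ceiling(3 * sigma) + 1L) {
  x <- seq_len(size) - 1 - (size - 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  out <- correlate2(mat, matrix(g, ncol = 1))
  correlate2(out, matrix(g, nrow = 1))
}

#' @rdname gaussian_smooth
#' @export
median_filter <- function(img, radius = 1L) {
  rewrap(img, cpp_median_filter(as_pixels(img), as.integer(radius)))
}

rewrap <- function(img, px) {
  if (inherits(img, "oct_image")) return(oct_image(px, img$axial_um_per_px))
  if (inherits(img, "gray_image")) return(gray_image(px))
  px
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with per-bin clipping and bilinear
#' interpolation of the tile mappings, used for illumination equalization and
#' background normalization of fundus photographs. A flat field maps to a
#' (near-)constant image; a slow illumination ramp is flattened so tile-wise
#' histograms become approximately uniform.
#'
#' @param mat numeric matrix in \[0,1\].
#' @param n_tiles tiles per image side (grid is n_tiles x n_tiles).
#' @param clip_limit per-bin histogram cap as a fraction of the tile pixel
#'   count; higher values give stronger equalization.
#' @param n_bins histogram resolution.
#' @return numeric matrix in \[0,1\].
#' @export
clahe <- function(mat, n_tiles = 8L, clip_limit = 0.01, n_bins = 256L) {
  mat <- as_pixels(mat)
  H <- nrow(mat); W <- ncol(mat)
  n_tiles <- max(1L, as.integer(n_tiles))
  bin <- matrix(pmin(pmax(floor(mat * n_bins) + 1L, 1L), n_bins), H, W)
  # tile boundaries and centers
  rb <- round(seq(0, H, length.out = n_tiles + 1))
  cb <- round(seq(0, W, length.out = n_tiles + 1))
  cdfs <- array(0, c(n_tiles, n_tiles, n_bins))
  rcent <- numeric(n_tiles); ccent <- numeric(n_tiles)
  for (ti in seq_len(n_tiles)) {
    for (tj in seq_len(n_tiles)) {
      rows <- (rb[ti] + 1):rb[ti + 1]
      cols <- (cb[tj] + 1):cb[tj + 1]
      h <- tabulate(bin[rows, cols], nbins = n_bins)
      npix <- sum(h)
      cap <- max(1, clip_limit * npix)
      excess <- sum(pmax(h - cap, 0))
      h <- pmin(h, cap) + excess / n_bins
      cdfs[ti, tj, ] <- cumsum(h) / sum(h)
      rcent[ti] <- mean(rows); ccent[tj] <- mean(cols)
    }
  }
  # bilinear interpolation between the four nearest tile mappings
  ri <- findInterval(seq_len(H), rcent)          # lower tile index (0..n)
  ci <- findInterval(seq_len(W), ccent)
  r0 <- pmax(ri, 1L); r1 <- pmin(ri + 1L, n_tiles)
  c0 <- pmax(ci, 1L); c1 <- pmin(ci + 1L, n_tiles)
  wr <- ifelse(r1 == r0, 0,
               (seq_len(H) - rcent[r0]) / (rcent[r1] - rcent[r0]))
  wc <- ifelse(c1 == c0, 0,
               (seq_len(W) - ccent[c0]) / (ccent[c1] - ccent[c0]))
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)
  out <- matrix(0, H, W)
  idx_r <- rep(seq_len(H), times = W)
  idx_c <- rep(seq_len(W), each = H)
  b <- as.vector(bin)
  look <- function(tr, tc) cdfs[cbind(tr, tc, b)]
  v00 <- look(r0[idx_r], c0[idx_c]); v01 <- look(r0[idx_r], c1[idx_c])
  v10 <- look(r1[idx_r], c0[idx_c]); v11 <- look(r1[idx_r], c1[idx_c])
  fr <- wr[idx_r]; fc <- wc[idx_c]
  out[] <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
    fr * ((1 - fc) * v10 + fc * v11)
  clamp01(out)
}

#' Gradient magnitude by central differences
#'
#' @param mat numeric matrix; replicate borders (one-sided differences vanish
#'   at the edge rows/cols).
#' @return numeric matrix of sqrt(gx^2 + gy^2).
#' @export
grad_magnitude <- function(mat) {
  mat <- as_pixels(mat)
  H <- nrow(mat); W <- ncol(mat)
  up <- mat[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- mat[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- mat[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- mat[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}
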