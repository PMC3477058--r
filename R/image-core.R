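#' Image containers
#'
#' `rgb_image()` wraps an H x W x 3 array of intensities in \[0, 1\];
#' `gray_image()` wraps an H x W matrix; `oct_image()` is a grayscale B-scan
#' carrying its axial pixel pitch in microns per pixel (rows = depth,
#' columns = lateral position).
#'
#' All detectors assume the 0-based (row, col) convention with rows increasing
#' downward; R matrices are addressed 1-based internally, coordinates reported
#' to the user are 1-based (row, col) pixel indices.
#'
#' @param pixels numeric array (H x W x 3) or matrix (H x W), values in \[0,1\].
#' @param axial_um_per_px microns of tissue depth per image row (default 6).
#' @return An object of class `rgb_image`, `gray_image` or `oct_image`.
#' @examples
#' img <- gray_image(matrix(runif(64 * 64), 64))
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_typed("bad_input", "rgb_image: 'pixels' must be an H x W x 3 array")
  check_intensities(pixels)
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L)
    stop_typed("bad_input", "rgb_image: detectors require H >= 64 and W >= 64")
  structure(list(pixels = pixels,
                 height_px = dim(pixels)[1], width_px = dim(pixels)[2]),
            class = "rgb_image")
}

#' @rdname rgb_image
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  check_intensities(pixels)
  structure(list(pixels = pixels,
                 height_px = nrow(pixels), width_px = ncol(pixels)),
            class = "gray_image")
}

#' @rdname rgb_image
#' @export
oct_image <- function(pixels, axial_um_per_px = 6) {
  img <- gray_image(pixels)
  if (!is.numeric(axial_um_per_px) || length(axial_um_per_px) != 1L ||
      !is.finite(axial_um_per_px) || axial_um_per_px <= 0)
    stop_typed("bad_input", "oct_image: axial_um_per_px must be > 0")
  img$axial_um_per_px <- axial_um_per_px
  class(img) <- c("oct_image", "gray_image")
  img
}

check_intensities <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_typed("bad_input", "image intensities must be finite numerics")
  r <- range(x)
  if (r[1] < 0 || r[2] > 1)
    stop_typed("bad_input", "image intensities must lie in [0, 1]")
  invisible(x)
}

stop_typed <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(paste0("retinodiag_", class),
                                             "retinodiag_error")))
}

as_pixels <- function(img) {
  if (inherits(img, "gray_image")) return(img$pixels)
  if (is.matrix(img)) return(img)
  stop_typed("bad_input", "expected a gray_image or a matrix")
}

#' HSI intensity plane of a color image
#'
#' The intensity plane of the HSI decomposition, I = (R + G + B) / 3.
#'
#' @param img an `rgb_image`.
#' @return A `gray_image` of the same height and width.
#' @export
rgb_to_intensity <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  gray_image((p[, , 1] + p[, , 2] + p[, , 3]) / 3)
}

#' Extract one color channel as a matrix
#' @param img an `rgb_image`.
#' @param channel one of "red", "green", "blue".
#' @return numeric matrix.
#' @export
channel <- function(img, channel = c("green", "red", "blue")) {
  stopifnot(inherits(img, "rgb_image"))
  channel <- match.arg(channel)
  img$pixels[, , switch(channel, red = 1L, green = 2L, blue = 3L)]
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<%s> %d x %d, range [%.3f, %.3f]\n",
              class(x)[1], x$height_px, x$width_px,
              min(x$pixels), max(x$pixels)))
  if (!is.null(x$axial_um_per_px))
    cat(sprintf("  axial pitch: %g um/px\n", x$axial_um_per_px))
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d x 3, range [%.3f, %.3f]\n",
              x$height_px, x$width_px, min(x$pixels), max(x$pixels)))
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin histogram; used wherever a
#' data-driven binarization level is needed (vessel/exudate difference images,
#' gradient magnitude fields).
#'
#' @param x numeric vector or matrix of values.
#' @param n_bins number of histogram bins.
#' @return The threshold value (scalar); pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_typed("bad_input", "otsu_threshold: empty input")
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps) return(lo)
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  lo + (k / n_bins) * (hi - lo)
}
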