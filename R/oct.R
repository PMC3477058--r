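#' Per-column boundary trace
#'
#' One row coordinate per image column; `NA` marks columns where the boundary
#' was not observed. After hole filling every column is defined.
#'
#' @param rows numeric vector, one entry per column (NA allowed).
#' @param n_cols image width; defaults to `length(rows)`.
#' @return object of class `boundary_trace` (numeric vector with attribute
#'   `n_cols`).
#' @export
boundary_trace <- function(rows, n_cols = length(rows)) {
  if (length(rows) != n_cols)
    stop_typed("bad_input", "boundary_trace: length(rows) != n_cols")
  structure(as.numeric(rows), n_cols = as.integer(n_cols),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("<boundary_trace> %d columns, %d defined, row range [%g, %g]\n",
              attr(x, "n_cols"), sum(!is.na(x)),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Fill missing trace columns with a least-squares cubic
#'
#' Fits row = p3(col) through the defined boundary points and evaluates the
#' polynomial at the missing columns (measured columns are kept). Exact for
#' boundaries that are themselves cubic.
#'
#' @param trace a [boundary_trace()] with at least 4 defined columns.
#' @param clamp_rows optional c(min, max) to clamp filled values.
#' @return a fully defined `boundary_trace`.
#' @export
fill_trace_cubic <- function(trace, clamp_rows = NULL) {
  rows <- as.numeric(trace)
  def <- which(!is.na(rows))
  if (length(def) < 4L)
    stop_typed("underdetermined",
               "fill_trace_cubic: fewer than 4 defined columns")
  if (length(def) < length(rows)) {
    x <- def / length(rows)  # scaled for conditioning
    fit <- stats::lm.fit(cbind(1, x, x^2, x^3), rows[def])
    miss <- which(is.na(rows))
    xm <- miss / length(rows)
    rows[miss] <- cbind(1, xm, xm^2, xm^3) %*% fit$coefficients
  }
  if (!is.null(clamp_rows))
    rows <- pmin(pmax(rows, clamp_rows[1]), clamp_rows[2])
  boundary_trace(rows)
}

first_white_per_column <- function(mask) {
  rows <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_real_
  })
  boundary_trace(rows)
}

#' Initial anterior-boundary estimate
#'
#' Binarizes the gradient magnitude of the (pre-smoothed) B-scan, removes
#' components with area below 0.07% of the image (158 px at the reference
#' 329 x 689 geometry, recomputed by round-down for other sizes) or
#' horizontal extent below 25 px, takes the first white pixel from the top of
#' each column, and fills missing columns with a least-squares cubic.
#'
#' @param img an `oct_image`, ideally after [gaussian_smooth()] +
#'   [median_filter()].
#' @param area_fraction small-component cutoff as a fraction of total pixels.
#' @param min_length_px minimum component horizontal extent.
#' @param threshold gradient binarization level; NULL = Otsu.
#' @return a fully defined [boundary_trace()], with attribute `area_cutoff_px`
#'   recording the applied area filter.
#' @export
initial_anterior <- function(img, area_fraction = 0.0007, min_length_px = 25,
                             threshold = NULL) {
  g <- grad_magnitude(as_pixels(img))
  if (is.null(threshold)) threshold <- otsu_threshold(g)
  area_cutoff <- floor(area_fraction * length(g))
  mask <- remove_small_components(g > threshold, min_area = area_cutoff,
                                  min_length = min_length_px)
  tr <- first_white_per_column(mask)
  if (sum(!is.na(tr)) < 4L)
    stop_typed("no_boundary",
               "initial_anterior: fewer than 4 boundary columns found")
  out <- fill_trace_cubic(tr, clamp_rows = c(1, nrow(g)))
  attr(out, "area_cutoff_px") <- area_cutoff
  out
}

#' Greedy active-contour parameters
#'
#' @param alpha continuity weight, @param beta curvature weight,
#' @param gamma image-energy (gradient) weight, all >= 0.
#' @param search_window odd vertical window height in px (>= 3).
#' @param max_iter iteration cap.
#' @param move_fraction_stop stop when fewer than this fraction of points
#'   moved in an iteration.
#' @return object of class `snake_params`.
#' @export
snake_params <- function(alpha = 1, beta = 1, gamma = 1.2,
                         search_window = 7L, max_iter = 50L,
                         move_fraction_stop = 0.02) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop_typed("bad_param", "snake_params: weights must be >= 0")
  if (search_window < 3L || search_window %% 2L != 1L)
    stop_typed("bad_param", "snake_params: search_window must be odd and >= 3")
  if (max_iter < 1L) stop_typed("bad_param", "snake_params: max_iter >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 search_window = as.integer(search_window),
                 max_iter = as.integer(max_iter),
                 move_fraction_stop = move_fraction_stop),
            class = "snake_params")
}

#' Total snake energy of a trace
#'
#' E = alpha * sum ((r_c - r_(c-1))^2 / h^4) + beta * sum ((r_(c-1) -
#' 2 r_c + r_(c+1))^2 / h^4) - gamma * sum gnorm(r_c, c), where h is the
#' search-window half-width and gnorm is the gradient magnitude min-max
#' normalized over the image. The h^-4 scaling puts the smoothness terms in
#' window-relative units small enough that the image term - the actual
#' boundary evidence - dominates moves up to a full window, while smoothness
#' still regularizes sub-window jitter; the literature defaults
#' alpha = beta = 1, gamma = 1.2 are kept as relative weights under this
#' scaling. The functional is fixed across iterations, so greedy descent on
#' it is provably non-increasing.
#'
#' @param rows trace row coordinates (integer-valued).
#' @param gnorm normalized gradient-magnitude matrix.
#' @param p a [snake_params()].
#' @return scalar energy.
#' @export
snake_energy <- function(rows, gnorm, p) {
  n <- length(rows)
  h4 <- (p$search_window %/% 2L)^4
  cont <- sum(diff(rows)^2) / h4
  curv <- if (n >= 3) sum((rows[1:(n - 2)] - 2 * rows[2:(n - 1)] +
                             rows[3:n])^2) / h4 else 0
  img <- sum(gnorm[cbind(rows, seq_len(n))])
  p$alpha * cont + p$beta * curv - p$gamma * img
}

#' Greedy snake boundary refinement
#'
#' Each boundary point is visited in turn and moved, within a vertical search
#' window, to the row minimizing its contribution to the total energy
#' (continuity + curvature - normalized gradient magnitude); this greedy
#' coordinate descent makes the total energy non-increasing by construction.
#' Iteration stops at `max_iter` or when fewer than `move_fraction_stop` of
#' the points moved.
#'
#' @param img an `oct_image` (gradient is computed from it).
#' @param init fully defined initial [boundary_trace()].
#' @param p a [snake_params()].
#' @return refined `boundary_trace` with attributes `energy` (per-iteration
#'   total energy, starting with the initial trace) and `iterations`.
#' @export
greedy_snake <- function(img, init, p = snake_params()) {
  I <- as_pixels(img)
  H <- nrow(I); W <- ncol(I)
  if (p$search_window >= H)
    stop_typed("bad_param", "greedy_snake: search window exceeds image height")
  rows <- as.numeric(init)
  if (anyNA(rows) || length(rows) != W)
    stop_typed("bad_input", "greedy_snake: init must define every column")
  rows <- pmin(pmax(round(rows), 1), H)
  g <- grad_magnitude(I)
  rg <- range(g)
  gnorm <- if (rg[2] > rg[1]) (g - rg[1]) / (rg[2] - rg[1]) else g * 0
  half <- p$search_window %/% 2L
  energies <- snake_energy(rows, gnorm, p)
  n_iter <- 0L
  for (iter in seq_len(p$max_iter)) {
    moved <- 0L
    for (cc in seq_len(W)) {
      cand <- (rows[cc] - half):(rows[cc] + half)
      cand <- cand[cand >= 1 & cand <= H]
      prev <- if (cc > 1) rows[cc - 1] else NA
      nxt <- if (cc < W) rows[cc + 1] else NA
      prev2 <- if (cc > 2) rows[cc - 2] else NA
      nxt2 <- if (cc < W - 1) rows[cc + 2] else NA
      e <- -p$gamma * gnorm[cbind(cand, cc)]
      h4 <- half^4
      if (!is.na(prev)) e <- e + p$alpha * (cand - prev)^2 / h4
      if (!is.na(nxt)) e <- e + p$alpha * (nxt - cand)^2 / h4
      # curvature terms in which r_cc participates
      if (!is.na(prev) && !is.na(nxt))
        e <- e + p$beta * (prev - 2 * cand + nxt)^2 / h4
      if (!is.na(prev2) && !is.na(prev))
        e <- e + p$beta * (prev2 - 2 * prev + cand)^2 / h4
      if (!is.na(nxt) && !is.na(nxt2))
        e <- e + p$beta * (cand - 2 * nxt + nxt2)^2 / h4
      best <- cand[which.min(e)]
      if (best != rows[cc]) { rows[cc] <- best; moved <- moved + 1L }
    }
    n_iter <- iter
    energies <- c(energies, snake_energy(rows, gnorm, p))
    if (moved < p$move_fraction_stop * W) break
  }
  out <- boundary_trace(rows)
  attr(out, "energy") <- energies
  attr(out, "iterations") <- n_iter
  out
}

#' 1-D running median with a fixed point count
#'
#' Window of `n` points centered on each sample (shrunk symmetrically at the
#' trace ends); even-sized windows take the mean of the middle pair.
#'
#' @param x numeric vector.
#' @param n window size in points (default 50).
#' @return numeric vector of the same length.
#' @export
median_filter_1d <- function(x, n = 50L) {
  N <- length(x)
  lo <- (n - 1L) %/% 2L
  hi <- n - 1L - lo
  vapply(seq_len(N), function(i) {
    if (i - lo < 1L || i + hi > N) {
      h <- min(i - 1L, N - i)  # symmetric shrink at the borders
      stats::median(x[(i - h):(i + h)])
    } else {
      stats::median(x[(i - lo):(i + hi)])
    }
  }, numeric(1))
}

#' Posterior (RNFL bottom) boundary estimation
#'
#' The field above (and immediately below) the anterior boundary is removed,
#' the remainder is smoothed by 8-neighbor anisotropic diffusion, and the
#' gradient magnitude of the smoothed field is normalized and binarized at
#' mean + 1 SD (the "statistical" level; override with `threshold`). The
#' cleanup cascade then removes components of area < 100 px, deep responses
#' classified as RPE (mean row more than `rpe_depth_px` below the anterior
#' trace), and components of horizontal extent < 25 px or area < 70 px. The
#' first remaining white pixel from the top of each column is the boundary;
#' missing columns are filled with a cubic and the trace is passed through a
#' 50-point median filter.
#'
#' @param img the `oct_image` (original or pre-smoothed).
#' @param anterior fully defined anterior [boundary_trace()].
#' @param p [diffusion_params()] for the smoothing stage.
#' @param area1_px first-area cutoff (100).
#' @param min_length_px,area2_px second-stage cutoffs (25, 70).
#' @param rpe_depth_px responses with mean row deeper than this below the
#'   anterior are treated as RPE and dropped.
#' @param anterior_margin_px rows below the anterior trace also masked, so
#'   the anterior edge response itself is excluded.
#' @param median_points window of the final 1-D median.
#' @param threshold binarization level on the normalized gradient; NULL =
#'   mean + 1 SD.
#' @return a fully defined [boundary_trace()].
#' @export
estimate_posterior <- function(img, anterior, p = diffusion_params(),
                               area1_px = 100, min_length_px = 25,
                               area2_px = 70, rpe_depth_px = 60,
                               anterior_margin_px = 5, median_points = 50L,
                               threshold = NULL) {
  I <- as_pixels(img)
  H <- nrow(I); W <- ncol(I)
  ant <- as.numeric(anterior)
  if (anyNA(ant) || length(ant) != W)
    stop_typed("bad_input", "estimate_posterior: anterior must be fully defined")
  rowidx <- matrix(seq_len(H), H, W)
  above <- rowidx <= matrix(ant + anterior_margin_px, H, W, byrow = TRUE)
  masked <- I
  masked[above] <- 0
  if (is.null(p$K)) {
    # estimate K from the un-masked scan so the artificial zeros above the
    # anterior cannot bias the gradient histogram
    K <- max(stats::quantile(grad_magnitude(I), 0.90, names = FALSE), 1e-3)
    p <- diffusion_params(p$lam, K, p$n_iter, p$neighbors)
  }
  sm <- anisotropic_diffuse(masked, p)
  g <- grad_magnitude(sm)
  # zero the gradient 2 rows past the mask so the artificial 0 -> tissue
  # edge created by the masking cannot be picked up as a boundary
  g[rowidx <= matrix(ant + anterior_margin_px + 2, H, W, byrow = TRUE)] <- 0
  rg <- range(g)
  if (rg[2] <= rg[1])
    stop_typed("no_boundary", "estimate_posterior: flat field below anterior")
  gn <- (g - rg[1]) / (rg[2] - rg[1])
  if (is.null(threshold)) threshold <- mean(gn) + stats::sd(gn)
  mask <- gn > threshold
  mask <- remove_small_components(mask, min_area = area1_px)
  # RPE rejection: components lying deep below the anterior trace
  labels <- label_components(mask)
  if (max(labels) > 0L) {
    depth <- rowidx - matrix(ant, H, W, byrow = TRUE)
    tab <- component_table(labels)
    mean_depth <- vapply(tab$label, function(l) mean(depth[labels == l]),
                         numeric(1))
    drop <- tab$label[mean_depth > rpe_depth_px]
    if (length(drop)) mask[labels %in% drop] <- FALSE
  }
  mask <- remove_small_components(mask, min_area = area2_px,
                                  min_length = min_length_px)
  if (!any(mask))
    stop_typed("no_boundary",
               "estimate_posterior: no candidate field after cleanup")
  tr <- first_white_per_column(mask)
  if (sum(!is.na(tr)) < 4L)
    stop_typed("no_boundary", "estimate_posterior: too few boundary columns")
  tr <- fill_trace_cubic(tr, clamp_rows = c(1, H))
  boundary_trace(median_filter_1d(as.numeric(tr), median_points))
}

#' RNFL thickness profile and report
#'
#' thickness\[c\] = (posterior\[c\] - anterior\[c\]) * axial pitch; negative
#' differences are clipped to zero with a warning. The mean over all columns
#' is classified by [classify_glaucoma()].
#'
#' @param anterior,posterior fully defined [boundary_trace()]s of equal
#'   length.
#' @param axial_um_per_px microns per pixel row (default 6).
#' @return object of class `rnfl_report`: `thickness_um`,
#'   `mean_thickness_um`, `label`.
#' @export
rnfl_thickness <- function(anterior, posterior, axial_um_per_px = 6) {
  a <- as.numeric(anterior); b <- as.numeric(posterior)
  if (length(a) != length(b))
    stop_typed("bad_input", "rnfl_thickness: trace length mismatch")
  if (anyNA(a) || anyNA(b))
    stop_typed("bad_input", "rnfl_thickness: traces must be fully defined")
  if (axial_um_per_px <= 0)
    stop_typed("bad_param", "rnfl_thickness: axial_um_per_px must be > 0")
  d <- b - a
  if (any(d < 0)) {
    warning("negative boundary separations clipped to 0", call. = FALSE)
    d[d < 0] <- 0
  }
  th <- d * axial_um_per_px
  m <- mean(th)
  structure(list(thickness_um = th, mean_thickness_um = m,
                 label = classify_glaucoma(m),
                 axial_um_per_px = axial_um_per_px),
            class = "rnfl_report")
}

#' Glaucoma classification by mean RNFL thickness
#'
#' Mean thickness below 105 um is glaucomatous; 105 um and above is
#' non-glaucomatous (the boundary value is assigned to healthy).
#'
#' @param x an `rnfl_report` or a mean thickness in microns.
#' @param threshold_um decision threshold (default 105).
#' @return "glaucomatous" or "non_glaucomatous".
#' @export
classify_glaucoma <- function(x, threshold_um = 105) {
  m <- if (inherits(x, "rnfl_report")) x$mean_thickness_um else x
  if (!is.finite(m)) stop_typed("bad_input", "classify_glaucoma: non-finite mean")
  if (m < threshold_um) "glaucomatous" else "non_glaucomatous"
}

#' @export
print.rnfl_report <- function(x, ...) {
  cat(sprintf("<rnfl_report> mean thickness %.2f um over %d columns -> %s\n",
              x$mean_thickness_um, length(x$thickness_um), x$label))
  invisible(x)
}
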