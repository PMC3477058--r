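# Brute-force oracles, deliberately independent of the package kernels:
# plain nested loops and direct summation.

bf_minmax <- function(img, se, dilate) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    r <- i + se$dr; c <- j + se$dc
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- img[cbind(r[ok], c[ok])]
    out[i, j] <- if (dilate) max(v) else min(v)
  }
  out
}

bf_close <- function(img, se) bf_minmax(bf_minmax(img, se, TRUE), se, FALSE)

# grayscale fill by iterated parallel reconstruction-by-erosion (8-connected)
bf_fill <- function(img) {
  H <- nrow(img); W <- ncol(img)
  J <- matrix(max(img), H, W)
  J[1, ] <- img[1, ]; J[H, ] <- img[H, ]
  J[, 1] <- img[, 1]; J[, W] <- img[, W]
  se <- list(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))
  repeat {
    J2 <- pmax(bf_minmax(J, se, FALSE), img)
    if (identical(J2, J)) return(J)
    J <- J2
  }
}

bf_median <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rs <- max(1, i - radius):min(H, i + radius)
    cs <- max(1, j - radius):min(W, j + radius)
    out[i, j] <- median(img[rs, cs])
  }
  out
}

# direct-summation correlation with half-sample reflective borders
bf_correlate <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  orow <- kh %/% 2; ocol <- kw %/% 2
  refl <- function(idx, n) {
    while (idx < 0 || idx >= n) {
      if (idx < 0) idx <- -idx - 1
      if (idx >= n) idx <- 2 * n - 1 - idx
    }
    idx
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      r <- refl(i - 1 + a - 1 - orow, H)
      c <- refl(j - 1 + b - 1 - ocol, W)
      s <- s + kernel[a, b] * img[r + 1, c + 1]
    }
    out[i, j] <- s
  }
  out
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# a hand-built optic_disc for tests that need one without running detection
synthetic_disc <- function(shape, center, odd) {
  pr <- rep(seq_len(shape[1]), times = shape[2])
  pc <- rep(seq_len(shape[2]), each = shape[1])
  mask <- matrix((pr - center[1])^2 + (pc - center[2])^2 <= (odd / 2)^2,
                 shape[1], shape[2])
  structure(list(center_rc = center, odd_px = odd, mask = mask,
                 threshold = NA_real_), class = "optic_disc")
}

synthetic_fovea <- function(center, radius) {
  structure(list(center_rc = center, radius_px = radius),
            class = "fovea_region")
}

# small, fast fundus phantom spec for pipeline-level tests; 400 px wide so
# the width-scaled structuring elements (2, 5, 7, 14) still bracket the
# 3-px vessel caliber
small_fundus_spec <- function(seed = 1L, ...) {
  args <- list(shape = c(400L, 400L), disc_center_rc = c(200, 272),
               odd_px = 50, vessel_width_px = 3, n_exudates = 2L,
               n_mahm = 2L, exudate_radius_px = 5, mahm_radius_px = 3,
               min_blob_separation_px = 28, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fundus_phantom_spec, args)
}

small_oct_spec <- function(seed = 1L, ...) {
  args <- list(shape = c(160L, 220L),
               anterior_coef = c(45, 0.05, -1e-4, 1e-7),
               thickness_px = 20, rpe_offset_px = 70,
               rpe_thickness_px = 8, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(oct_phantom_spec, args)
}
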