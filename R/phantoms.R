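#' Fundus phantom specification
#'
#' Describes a stylized fundus photograph with exact ground truth: a bright
#' circular optic disc, a dark parabolic main-vessel arch with straight
#' branches, a dark fovea on the arch axis 2.5 ODD from the vertex, bright
#' exudate blobs, dark MAHM blobs, a linear illumination ramp and additive
#' Gaussian noise. Channel levels are chosen so that the disc is the
#' brightest intensity region, exudates are brighter and vessels / MAHM /
#' fovea darker than background in the green channel, and MAHM holes are
#' deeper than the red-channel mean (the MAHM detector's threshold).
#'
#' @param shape c(H, W), default 700 x 700.
#' @param disc_center_rc,odd_px optic-disc center and diameter in px.
#' @param vessel_width_px main-vessel caliber (must sit between the s1 and s2
#'   closing scales for the extractor to see it).
#' @param n_exudates,n_mahm blob counts when explicit centers are not given.
#' @param exudate_centers,mahm_centers optional 2-column (row, col) matrices.
#' @param exudate_radius_px,mahm_radius_px blob radii.
#' @param fovea_darkness green-channel dip of the foveal blob.
#' @param gradient_amplitude peak-to-center amplitude of the illumination
#'   ramp.
#' @param noise_sd additive Gaussian noise SD.
#' @param min_blob_separation_px minimum center-to-center spacing when
#'   sampling blob positions (default 2 * 25 px, twice the largest dilation
#'   scale, which keeps counts exactly recoverable).
#' @param seed RNG seed; the spec plus seed fully determines the image.
#' @return object of class `fundus_phantom_spec`.
#' @export
fundus_phantom_spec <- function(shape = c(700L, 700L),
                                disc_center_rc = c(350, 480),
                                odd_px = 90,
                                vessel_width_px = 5,
                                n_exudates = 3L, n_mahm = 4L,
                                exudate_centers = NULL, mahm_centers = NULL,
                                exudate_radius_px = 8, mahm_radius_px = 4,
                                fovea_darkness = 0.2,
                                gradient_amplitude = 0.03,
                                noise_sd = 0.01,
                                min_blob_separation_px = 50,
                                seed = 1L) {
  if (any(shape < 64)) stop_typed("bad_param", "phantom: shape too small")
  if (odd_px <= 0 || vessel_width_px <= 0)
    stop_typed("bad_param", "phantom: geometry must be positive")
  if (disc_center_rc[1] < 1 || disc_center_rc[1] > shape[1] ||
      disc_center_rc[2] < 1 || disc_center_rc[2] > shape[2])
    stop_typed("bad_param", "phantom: disc center outside image")
  structure(as.list(environment()), class = "fundus_phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

disk_mask <- function(shape, center, radius) {
  pr <- rep(seq_len(shape[1]), times = shape[2])
  pc <- rep(seq_len(shape[2]), each = shape[1])
  matrix((pr - center[1])^2 + (pc - center[2])^2 <= radius^2,
         shape[1], shape[2])
}

# mark all pixels within width/2 of the polyline sampled in `pts` (n x 2)
stroke_mask <- function(shape, pts, width) {
  m <- matrix(FALSE, shape[1], shape[2])
  r <- width / 2
  k <- floor(r)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  pr <- round(rep(pts[, 1], each = nrow(off)) + off$dr)
  pc <- round(rep(pts[, 2], each = nrow(off)) + off$dc)
  ok <- pr >= 1 & pr <= shape[1] & pc >= 1 & pc <= shape[2]
  m[cbind(pr[ok], pc[ok])] <- TRUE
  m
}

sample_blob_centers <- function(n, shape, min_sep, forbidden_fn, margin) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n && tries < 5000L) {
    tries <- tries + 1L
    p <- c(stats::runif(1, margin, shape[1] - margin),
           stats::runif(1, margin, shape[2] - margin))
    if (forbidden_fn(p)) next
    if (nrow(centers) > 0 &&
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) < min_sep)
      next
    centers <- rbind(centers, p)
  }
  if (nrow(centers) < n)
    stop_typed("bad_param", "phantom: could not place blobs with the ",
               "requested separation")
  centers
}

#' Render a fundus phantom
#'
#' @param spec a [fundus_phantom_spec()].
#' @return list with `image` (an `rgb_image`) and `truth`: disc center / ODD
#'   / mask, vessel mask, fovea center, exudate and MAHM masks and centers.
#'   Ground-truth masks are the exact rendering sets, recorded before noise.
#' @export
make_fundus_phantom <- function(spec) {
  stopifnot(inherits(spec, "fundus_phantom_spec"))
  with_seed(spec$seed, {
    H <- spec$shape[1]; W <- spec$shape[2]
    bg <- c(r = 0.50, g = 0.60, b = 0.30)
    Rch <- matrix(bg["r"], H, W)
    Gch <- matrix(bg["g"], H, W)
    Bch <- matrix(bg["b"], H, W)
    dc <- spec$disc_center_rc; odd <- spec$odd_px

    # main vessel arch: parabola with vertex at the disc center, opening
    # toward the fovea side (horizontal axis)
    open_dir <- if (dc[2] > W / 2) -1 else 1
    a <- 1.8 * odd / (2.5 * odd)^2   # arch half-width 1.8 ODD at fovea depth
    rows <- seq(max(1, dc[1] - 2.8 * odd), min(H, dc[1] + 2.8 * odd), by = 0.5)
    cols <- dc[2] + open_dir * a * (rows - dc[1])^2
    keep <- cols >= 1 & cols <= W
    vessel_mask <- stroke_mask(c(H, W), cbind(rows[keep], cols[keep]),
                               spec$vessel_width_px)
    # two straight branches leaving the arch
    for (s in c(-1, 1)) {
      r0 <- dc[1] + s * 1.2 * odd
      c0 <- dc[2] + open_dir * a * (r0 - dc[1])^2
      tt <- seq(0, 1.6 * odd, by = 0.5)
      vessel_mask <- vessel_mask |
        stroke_mask(c(H, W), cbind(r0 + s * tt * 0.45, c0 + open_dir * tt),
                    max(2, spec$vessel_width_px - 1))
    }
    fovea_center <- c(dc[1], dc[2] + open_dir * 2.5 * odd)

    forbidden <- function(p) {
      sqrt(sum((p - dc)^2)) < 0.9 * odd ||
        sqrt(sum((p - fovea_center)^2)) < 1.3 * odd
    }
    margin <- 2 * spec$exudate_radius_px + 8
    ex_centers <- spec$exudate_centers
    if (is.null(ex_centers))
      ex_centers <- if (spec$n_exudates > 0)
        sample_blob_centers(spec$n_exudates, c(H, W),
                            spec$min_blob_separation_px, forbidden, margin)
      else matrix(numeric(0), 0, 2)
    ma_centers <- spec$mahm_centers
    if (is.null(ma_centers))
      ma_centers <- if (spec$n_mahm > 0)
        sample_blob_centers(spec$n_mahm, c(H, W),
                            spec$min_blob_separation_px,
                            function(p) forbidden(p) || (nrow(ex_centers) &&
                              min(sqrt((ex_centers[, 1] - p[1])^2 +
                                       (ex_centers[, 2] - p[2])^2)) <
                                spec$min_blob_separation_px) ||
                              any(vessel_mask[disk_mask(c(H, W), p,
                                    spec$mahm_radius_px + 4)]),
                            margin)
      else matrix(numeric(0), 0, 2)

    # paint features (order: fovea, vessels, lesions, disc)
    fv <- disk_mask(c(H, W), fovea_center, 0.5 * odd)
    Gch[fv] <- bg["g"] - spec$fovea_darkness
    Rch[fv] <- bg["r"] - 0.10; Bch[fv] <- bg["b"] - 0.05
    Rch[vessel_mask] <- 0.35; Gch[vessel_mask] <- 0.30
    Bch[vessel_mask] <- 0.15
    exudate_mask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(ex_centers)))
      exudate_mask <- exudate_mask |
        disk_mask(c(H, W), ex_centers[i, ], spec$exudate_radius_px)
    Rch[exudate_mask] <- 0.85; Gch[exudate_mask] <- 0.95
    Bch[exudate_mask] <- 0.55
    mahm_mask <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(ma_centers)))
      mahm_mask <- mahm_mask |
        disk_mask(c(H, W), ma_centers[i, ], spec$mahm_radius_px)
    Rch[mahm_mask] <- 0.15; Gch[mahm_mask] <- 0.02; Bch[mahm_mask] <- 0.05
    disc_mask <- disk_mask(c(H, W), dc, odd / 2)
    Rch[disc_mask] <- 0.95; Gch[disc_mask] <- 0.90; Bch[disc_mask] <- 0.80

    ramp <- matrix(rep(seq(-1, 1, length.out = W), each = H), H, W) *
      spec$gradient_amplitude
    px <- array(0, c(H, W, 3))
    px[, , 1] <- Rch + ramp; px[, , 2] <- Gch + ramp; px[, , 3] <- Bch + ramp
    if (spec$noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
    px <- clamp01(px)
    list(image = rgb_image(px),
         truth = list(disc_center_rc = dc, odd_px = odd,
                      disc_mask = disc_mask, vessel_mask = vessel_mask,
                      fovea_center_rc = fovea_center,
                      exudate_mask = exudate_mask,
                      exudate_centers = ex_centers,
                      mahm_mask = mahm_mask, mahm_centers = ma_centers))
  })
}

#' OCT phantom specification
#'
#' A B-scan with a dark vitreous over a bright RNFL band, a darker
#' sub-retinal interior, a bright RPE band deeper down, corrupted by
#' multiplicative L-look speckle. The anterior (RNFL top) boundary follows a
#' cubic in the column index; the posterior truth is anterior + thickness.
#'
#' @param shape c(H, W), default the reference 329 x 689.
#' @param anterior_coef cubic coefficients c(a0, a1, a2, a3) of the anterior
#'   row as a function of column.
#' @param thickness_px RNFL thickness profile: scalar or per-column vector.
#' @param intensities named list: vitreous, rnfl, sub, rpe, deep.
#' @param rpe_offset_px rows between the anterior trace and the RPE top
#'   (must exceed the posterior estimator's RPE depth cutoff).
#' @param rpe_thickness_px thickness of the RPE band.
#' @param looks speckle looks L (>= 1); Inf disables speckle.
#' @param gap_cols columns rendered as a smooth vertical ramp with no
#'   detectable edges at all (a "hole" in the boundary, for testing cubic
#'   trace filling).
#' @param seed RNG seed.
#' @return object of class `oct_phantom_spec`.
#' @export
oct_phantom_spec <- function(shape = c(329L, 689L),
                             anterior_coef = c(95, 0.08, -2e-4, 1.5e-7),
                             thickness_px = 28,
                             intensities = list(vitreous = 0.08, rnfl = 0.85,
                                                sub = 0.30, rpe = 0.80,
                                                deep = 0.15),
                             rpe_offset_px = 80, rpe_thickness_px = 12,
                             looks = 4, gap_cols = NULL, seed = 1L) {
  H <- shape[1]; W <- shape[2]
  cols <- seq_len(W)
  # truth boundaries are rendered at integer rows so a pixel-accurate
  # detector can recover them exactly
  ant <- round(anterior_coef[1] + anterior_coef[2] * cols +
                 anterior_coef[3] * cols^2 + anterior_coef[4] * cols^3)
  th <- round(rep_len(thickness_px, W))
  if (any(ant < 2) || any(ant + th > H - 2))
    stop_typed("bad_param", "oct phantom: bands exceed image height")
  if (any(ant + rpe_offset_px + rpe_thickness_px > H))
    stop_typed("bad_param", "oct phantom: RPE band exceeds image height")
  if (looks < 1) stop_typed("bad_param", "oct phantom: looks must be >= 1")
  structure(list(shape = as.integer(shape), anterior_coef = anterior_coef,
                 anterior_rows = ant, thickness_px = th,
                 intensities = intensities, rpe_offset_px = rpe_offset_px,
                 rpe_thickness_px = rpe_thickness_px, looks = looks,
                 gap_cols = gap_cols, seed = seed),
            class = "oct_phantom_spec")
}

#' Multiplicative speckle
#'
#' Multiplies the image by unit-mean Gamma(L, rate = L) noise (L-look
#' intensity speckle, variance 1/L) and clips to \[0, 1\]. A zero image stays
#' zero. `looks = Inf` returns the input unchanged.
#'
#' @param img matrix or `gray_image`/`oct_image`.
#' @param looks number of looks L >= 1.
#' @param seed optional RNG seed.
#' @return same container type as the input.
#' @export
add_speckle <- function(img, looks, seed = NULL) {
  if (looks < 1) stop_typed("bad_param", "add_speckle: looks must be >= 1")
  px <- as_pixels(img)
  if (is.infinite(looks)) return(rewrap(img, px))
  run <- function() {
    noise <- stats::rgamma(length(px), shape = looks, rate = looks)
    rewrap(img, clamp01(px * matrix(noise, nrow(px), ncol(px))))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Render an OCT phantom
#'
#' @param spec an [oct_phantom_spec()].
#' @param axial_um_per_px axial pitch recorded on the image (default 6).
#' @return list with `image` (an `oct_image`), `anterior_truth` and
#'   `posterior_truth` ([boundary_trace()]s; posterior = anterior +
#'   thickness exactly).
#' @export
make_oct_phantom <- function(spec, axial_um_per_px = 6) {
  stopifnot(inherits(spec, "oct_phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  ant <- spec$anterior_rows
  post <- ant + spec$thickness_px
  iv <- spec$intensities
  rowidx <- matrix(seq_len(H), H, W)
  antm <- matrix(ant, H, W, byrow = TRUE)
  postm <- matrix(post, H, W, byrow = TRUE)
  px <- matrix(iv$vitreous, H, W)
  px[rowidx >= antm & rowidx < postm] <- iv$rnfl
  px[rowidx >= postm] <- iv$sub
  rpem <- antm + spec$rpe_offset_px
  px[rowidx >= rpem & rowidx < rpem + spec$rpe_thickness_px] <- iv$rpe
  px[rowidx >= rpem + spec$rpe_thickness_px] <- iv$deep
  if (!is.null(spec$gap_cols)) {
    # gap columns carry no detectable edges: a single smooth vertical ramp
    for (cc in spec$gap_cols)
      px[, cc] <- seq(iv$vitreous, iv$deep, length.out = H)
  }
  img <- oct_image(clamp01(px), axial_um_per_px)
  img <- add_speckle(img, spec$looks, seed = spec$seed)
  list(image = img,
       anterior_truth = boundary_trace(ant),
       posterior_truth = boundary_trace(post))
}
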