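#' Structuring-element scales for the fundus pipeline
#'
#' Disk diameters for the two vessel closings (s1 < s2) and the two exudate
#' dilations (s2 < s3 < s4). Defaults 3 / 9 / 13 / 25 px refer to a ~700 px
#' wide fundus photograph; [scales_for_width()] rescales them linearly.
#'
#' @param s1_px,s2_px closing scales bracketing the vessel caliber.
#' @param s3_px,s4_px dilation scales for exudate boundary extraction, both
#'   greater than `s2_px`.
#' @return object of class `morph_scales`.
#' @export
morph_scales <- function(s1_px = 3, s2_px = 9, s3_px = 13, s4_px = 25) {
  if (!(s1_px < s2_px))
    stop_typed("bad_param", "morph_scales: need s1_px < s2_px")
  if (!(s2_px < s3_px && s3_px < s4_px))
    stop_typed("bad_param", "morph_scales: need s2_px < s3_px < s4_px")
  structure(list(s1_px = s1_px, s2_px = s2_px, s3_px = s3_px, s4_px = s4_px),
            class = "morph_scales")
}

#' @rdname morph_scales
#' @param width_px image width the scales should be adapted to.
#' @param reference_width_px width at which the defaults are defined.
#' @export
scales_for_width <- function(width_px, reference_width_px = 700) {
  f <- width_px / reference_width_px
  morph_scales(max(1, round(3 * f)), max(2, round(9 * f)),
               max(3, round(13 * f)), max(4, round(25 * f)))
}

# reference-scale area thresholds grow with image area
scale_area <- function(area_px, shape, reference = c(700, 700)) {
  max(1, round(area_px * (shape[1] * shape[2]) / (reference[1] * reference[2])))
}

#' Fundus preprocessing: illumination equalization
#'
#' Per-channel contrast-limited adaptive histogram equalization ([clahe()]),
#' normalizing uneven illumination and background before detection.
#'
#' @param img an `rgb_image`.
#' @param n_tiles,clip_limit CLAHE parameters.
#' @return an `rgb_image`.
#' @export
fundus_preprocess <- function(img, n_tiles = 8L, clip_limit = 0.005) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  for (ch in 1:3) p[, , ch] <- clahe(p[, , ch], n_tiles, clip_limit)
  rgb_image(p)
}

#' Optic disc detection
#'
#' The optic disc is the brightest region of the fundus. The HSI intensity
#' plane is low-pass filtered (Gaussian, sigma = 0.005 * min(H, W), at least
#' 1 px), thresholded just below its maximum (Imax - `threshold_offset`,
#' default offset 0.02), and the maximum-area component above threshold is
#' taken as the disc candidate. A window around the candidate is re-thresholded
#' (Otsu) to delineate the boundary; the disc diameter (ODD) is the
#' equivalent-circle diameter of the boundary component.
#'
#' @param img a preprocessed `rgb_image`.
#' @param threshold_offset subtracted from the smoothed-plane maximum.
#' @param sigma low-pass Gaussian SD in px; NULL = 0.005 * min(H, W).
#' @return object of class `optic_disc`: `center_rc`, `odd_px`, `mask`,
#'   plus the `threshold` actually applied.
#' @export
detect_optic_disc <- function(img, threshold_offset = 0.02, sigma = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  I <- rgb_to_intensity(img)$pixels
  if (is.null(sigma)) sigma <- max(1, 0.005 * min(dim(I)))
  Is <- gaussian_blur(I, sigma)
  imax <- max(Is)
  thr <- imax - threshold_offset
  if (imax - min(Is) < threshold_offset)
    stop_typed("no_disc", "detect_optic_disc: image too flat, no disc found")
  labels <- label_components(Is > thr)
  tab <- component_table(labels)
  cand <- tab[which.max(tab$area_px), ]
  # crop a window around the candidate with a half-size margin
  mr <- ceiling((cand$row_max - cand$row_min + 1) / 2) + 2L
  mc <- ceiling((cand$col_max - cand$col_min + 1) / 2) + 2L
  r0 <- max(1L, cand$row_min - mr); r1 <- min(nrow(I), cand$row_max + mr)
  c0 <- max(1L, cand$col_min - mc); c1 <- min(ncol(I), cand$col_max + mc)
  win <- Is[r0:r1, c0:c1]
  wmask <- win > otsu_threshold(win)
  wlab <- label_components(wmask)
  wtab <- component_table(wlab)
  if (nrow(wtab) == 0L)
    stop_typed("no_disc", "detect_optic_disc: empty disc window")
  best <- wtab[which.max(wtab$area_px), ]
  mask <- matrix(FALSE, nrow(I), ncol(I))
  mask[r0:r1, c0:c1] <- wlab == best$label
  center <- c(best$centroid_row + r0 - 1, best$centroid_col + c0 - 1)
  if (!mask[round(center[1]), round(center[2])]) {
    idx <- which(mask)
    rr <- (idx - 1) %% nrow(mask) + 1; cc <- (idx - 1) %/% nrow(mask) + 1
    k <- which.min((rr - center[1])^2 + (cc - center[2])^2)
    center <- c(rr[k], cc[k])
  }
  structure(list(center_rc = center,
                 odd_px = 2 * sqrt(best$area_px / pi),
                 mask = mask, threshold = thr),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("<optic_disc> center (%.1f, %.1f), ODD %.1f px\n",
              x$center_rc[1], x$center_rc[2], x$odd_px))
  invisible(x)
}

#' Blood-vessel extraction by multiscale closing
#'
#' Closing the green channel with a small disk (s1, below the vessel caliber)
#' leaves vessels intact; closing with a larger disk (s2, above it) removes
#' them. The difference C = close(G, s2) - close(G, s1) isolates the vessel
#' segments, which are thresholded (Otsu over the full response) and cleaned
#' of small components.
#'
#' @param img an `rgb_image`.
#' @param scales a [morph_scales()] object with s1 < s2.
#' @param min_area_px small-component cutoff; NULL = 150 px at the 700 x 700
#'   reference, scaled with image area. The cutoff is sized to remove
#'   punctate dark lesions (microaneurysm-scale blobs) from the vessel map -
#'   they respond to the closing difference exactly like short vessel
#'   segments - so that MAHM candidates survive the later vessel removal.
#' @return a [lesion_mask()].
#' @export
extract_vessels <- function(img, scales = NULL, min_area_px = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  if (is.null(scales)) scales <- scales_for_width(img$width_px)
  stopifnot(inherits(scales, "morph_scales"))
  G <- channel(img, "green")
  C <- mo_close(G, disk_se(scales$s2_px)) - mo_close(G, disk_se(scales$s1_px))
  if (is.null(min_area_px))
    min_area_px <- scale_area(150, dim(G))
  if (!any(C > 1e-12))
    return(lesion_mask(matrix(FALSE, nrow(G), ncol(G)), min_area_px))
  mask <- C > otsu_threshold(C)
  mask <- remove_small_components(mask, min_area_px)
  lesion_mask(mask, min_area_px)
}

#' Exudate detection by multiscale dilation
#'
#' Grayscale dilation enlarges bright regions; at scales s3 and s4 (both
#' above the vessel scale s2) the vessels vanish while bright, sharp-edged
#' exudates respond. The difference P = dilate(G, s4) - dilate(G, s3) traces
#' exudate boundaries; P is thresholded (Otsu) to P_t, holes are filled,
#' candidates are confirmed by green-channel brightness (> mean + 2 SD,
#' disable with `confirm_green = FALSE`), and the optic-disc region is
#' removed (the disc responds exactly like an exudate).
#'
#' @param img an `rgb_image`.
#' @param scales a [morph_scales()].
#' @param disc an `optic_disc` (mandatory: disc removal is part of the
#'   definition).
#' @param confirm_green apply the brightness confirmation.
#' @param min_area_px residual-speck cutoff; NULL = 10 px at reference scale.
#' @return a [lesion_mask()].
#' @export
detect_exudates <- function(img, scales = NULL, disc, confirm_green = TRUE,
                            min_area_px = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  if (missing(disc) || !inherits(disc, "optic_disc"))
    stop_typed("bad_input", "detect_exudates: a detected optic_disc is required")
  if (is.null(scales)) scales <- scales_for_width(img$width_px)
  if (is.null(min_area_px)) min_area_px <- scale_area(10, c(img$height_px, img$width_px))
  G <- channel(img, "green")
  P <- mo_dilate(G, disk_se(scales$s4_px)) - mo_dilate(G, disk_se(scales$s3_px))
  if (!any(P > 1e-12))
    return(lesion_mask(matrix(FALSE, nrow(G), ncol(G)), min_area_px))
  Pt <- P > otsu_threshold(P)
  filled <- mo_fill_holes(matrix(as.numeric(Pt), nrow(Pt), ncol(Pt))) > 0.5
  if (confirm_green)
    filled <- filled & (G > mean(G) + 2 * stats::sd(G))
  # remove the disc region with a 0.5 ODD safety margin: the delineated
  # boundary is conservative and can sit a few px off-center, and bright
  # disc remnants grade exactly like exudates
  rm_disc <- mo_dilate(matrix(as.numeric(disc$mask), nrow(disc$mask)),
                       disk_se(max(1, 0.5 * disc$odd_px))) > 0.5
  filled[rm_disc] <- FALSE
  filled <- remove_small_components(filled, min_area_px)
  lesion_mask(filled, min_area_px)
}

#' Fovea localization from the main vessel arch
#'
#' The main blood vessel is the thickest and largest vessel emanating from
#' the optic disc (component intersecting the disc mask dilated by
#' 0.25 * ODD, maximizing area x mean local caliber). Its course is modeled
#' as a parabola opening horizontally, col = a (row - r0)^2 + b (row - r0)
#' + c0, fit by least squares in a disc-centered frame; the vertex is the
#' vessel pixel closest to the disc center. The fovea is the darkest
#' (smoothed) intensity pixel in the sector 2-3 ODD from the vertex along
#' the parabola's axis, and its region radius is 1 ODD.
#'
#' @param img an `rgb_image`.
#' @param vessels vessel [lesion_mask()] from [extract_vessels()].
#' @param disc an `optic_disc`.
#' @param search_odd distance window along the axis, in ODD units.
#' @param angle_tol_deg half-angle of the search sector about the axis.
#' @return object of class `fovea_region`: `center_rc`, `radius_px`.
#' @export
detect_fovea <- function(img, vessels, disc, search_odd = c(2, 3),
                         angle_tol_deg = 45) {
  stopifnot(inherits(img, "rgb_image"), inherits(vessels, "lesion_mask"),
            inherits(disc, "optic_disc"))
  if (sum(vessels$mask) == 0L)
    stop_typed("no_main_vessel", "detect_fovea: empty vessel mask")
  labels <- label_components(vessels$mask)
  near <- mo_dilate(matrix(as.numeric(disc$mask), nrow(disc$mask)),
                    disk_se(max(1, 0.25 * disc$odd_px))) > 0.5
  touching <- setdiff(unique(labels[near]), 0L)
  if (length(touching) == 0L)
    stop_typed("no_main_vessel",
               "detect_fovea: no vessel component emanates from the disc")
  dt <- distance_transform(vessels$mask)
  tab <- component_table(labels)
  score <- vapply(touching, function(l) {
    sel <- labels == l
    tab$area_px[tab$label == l] * mean(dt[sel])
  }, numeric(1))
  # the disc region interrupts the arch, splitting the main vessel into
  # components; following its continuity from the disc means taking the
  # union of the strong emanating components (weak touchers are spurious)
  main <- touching[score >= 0.5 * max(score)]
  idx <- which(labels %in% main)
  rr <- (idx - 1) %% nrow(labels) + 1
  cc <- (idx - 1) %/% nrow(labels) + 1
  # parabola fit in the disc-centered frame (horizontal axis)
  y <- rr - disc$center_rc[1]
  x <- cc - disc$center_rc[2]
  fit <- stats::lm.fit(cbind(1, y, y^2), x)
  a <- fit$coefficients[3]
  vx_i <- which.min(y^2 + x^2)
  vertex <- c(rr[vx_i], cc[vx_i])
  # axis direction: the parabola opens along +col if a > 0, -col if a < 0;
  # fall back to "away from the disc, toward the image center" when flat
  dir_col <- if (is.finite(a) && abs(a) > 1e-9) sign(a) else
    sign(ncol(labels) / 2 - disc$center_rc[2])
  if (dir_col == 0) dir_col <- 1
  I <- rgb_to_intensity(img)$pixels
  # the fovea is an ODD-scale dark region: smooth at that scale so small
  # dark lesions or noise in the search sector cannot win the darkest-pixel
  # criterion
  sigma <- max(1, 0.15 * disc$odd_px)
  Is <- gaussian_blur(I, sigma)
  H <- nrow(I); W <- ncol(I)
  pr <- rep(seq_len(H), times = W)
  pc <- rep(seq_len(W), each = H)
  dr <- pr - vertex[1]; dc <- pc - vertex[2]
  dist <- sqrt(dr^2 + dc^2)
  ang <- acos(pmin(pmax((dc * dir_col) / pmax(dist, 1e-9), -1), 1)) * 180 / pi
  sel <- dist >= search_odd[1] * disc$odd_px &
    dist <= search_odd[2] * disc$odd_px & ang <= angle_tol_deg
  if (!any(sel))
    stop_typed("no_fovea", "detect_fovea: search sector falls outside image")
  k <- which(sel)[which.min(Is[cbind(pr[sel], pc[sel])])]
  structure(list(center_rc = c(pr[k], pc[k]), radius_px = disc$odd_px),
            class = "fovea_region")
}

#' @export
print.fovea_region <- function(x, ...) {
  cat(sprintf("<fovea_region> center (%.0f, %.0f), radius %.1f px\n",
              x$center_rc[1], x$center_rc[2], x$radius_px))
  invisible(x)
}

#' Microaneurysm and hemorrhage (MAHM) detection
#'
#' Small dark blobs are treated as holes of the green channel: morphological
#' hole filling raises them to their surrounding level, and the difference
#' R = fill(G) - G lights them up. R is thresholded at the mean intensity of
#' the red channel, vessel coordinates (which fill the same way) are removed
#' after a small protective dilation of the vessel mask, and residual specks
#' below `min_area_px` are dropped.
#'
#' @param img an `rgb_image`.
#' @param vessels vessel [lesion_mask()].
#' @param vessel_dilate_px protective dilation of the vessel mask before
#'   removal (default 3 px disk).
#' @param min_area_px residual-speck cutoff; NULL = 5 px at reference scale.
#' @return a [lesion_mask()].
#' @export
detect_mahm <- function(img, vessels, vessel_dilate_px = 3,
                        min_area_px = NULL) {
  stopifnot(inherits(img, "rgb_image"), inherits(vessels, "lesion_mask"))
  if (is.null(min_area_px))
    min_area_px <- scale_area(5, c(img$height_px, img$width_px))
  G <- channel(img, "green")
  R <- mo_fill_holes(G) - G
  thr <- mean(channel(img, "red"))
  mask <- R > thr
  vm <- vessels$mask
  if (vessel_dilate_px >= 1 && any(vm))
    vm <- mo_dilate(matrix(as.numeric(vm), nrow(vm)),
                    disk_se(vessel_dilate_px)) > 0.5
  mask[vm] <- FALSE
  mask <- remove_small_components(mask, min_area_px)
  lesion_mask(mask, min_area_px)
}
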