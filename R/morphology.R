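#' Disk structuring element
#'
#' A disk-shaped structuring element of the given diameter: all integer
#' offsets (dr, dc) with dr^2 + dc^2 <= (size/2)^2. Size 1 degenerates to the
#' identity element.
#'
#' @param size_px diameter in pixels (>= 1).
#' @return list with integer vectors `dr`, `dc` and the `size_px`.
#' @export
disk_se <- function(size_px) {
  if (!is.numeric(size_px) || size_px < 1)
    stop_typed("bad_input", "disk_se: size_px must be >= 1")
  r <- size_px / 2
  k <- floor(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  keep <- g$dr^2 + g$dc^2 <= r^2
  list(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]),
       size_px = size_px)
}

#' Grayscale morphology
#'
#' Erosion, dilation and closing with an arbitrary structuring element, and
#' grayscale hole filling by morphological reconstruction. Windows are
#' restricted to the image near borders, so a flat field is an exact fixed
#' point of every operation. `mo_fill_holes()` raises every regional minimum
#' not connected to the border up to its surrounding level (reconstruction by
#' erosion from a border marker), the standard fill used to pick out small
#' dark blobs.
#'
#' @param mat numeric matrix (or `gray_image`).
#' @param se structuring element from [disk_se()] or a list with `dr`, `dc`.
#' @return numeric matrix of the same shape.
#' @export
mo_erode <- function(mat, se) {
  cpp_minmax_filter(as_pixels(mat), se$dr, se$dc, FALSE)
}

#' @rdname mo_erode
#' @export
mo_dilate <- function(mat, se) {
  cpp_minmax_filter(as_pixels(mat), se$dr, se$dc, TRUE)
}

#' @rdname mo_erode
#' @export
mo_close <- function(mat, se) {
  mo_erode(mo_dilate(mat, se), se)
}

#' @rdname mo_erode
#' @export
mo_fill_holes <- function(mat) {
  mat <- as_pixels(mat)
  H <- nrow(mat); W <- ncol(mat)
  marker <- matrix(max(mat), H, W)
  marker[1, ] <- mat[1, ]; marker[H, ] <- mat[H, ]
  marker[, 1] <- mat[, 1]; marker[, W] <- mat[, W]
  cpp_reconstruct_erode(marker, mat)
}

#' Connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 = background, 1..n = components.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!connectivity %in% c(4L, 8L))
    stop_typed("bad_input", "connectivity must be 4 or 8")
  cpp_label_components(mask, as.integer(connectivity))
}

#' Per-component statistics
#'
#' @param labels integer label matrix from [label_components()].
#' @return data.frame with one row per component: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, bbox (`row_min`,`row_max`,`col_min`,
#'   `col_max`) and `length_px` (horizontal extent).
#' @export
component_table <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer(),
                      length_px = integer()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, nbins = n)
  sum_r <- rowsum(as.numeric(rr), lab)[, 1]
  sum_c <- rowsum(as.numeric(cc), lab)[, 1]
  rmin <- tapply(rr, lab, min); rmax <- tapply(rr, lab, max)
  cmin <- tapply(cc, lab, min); cmax <- tapply(cc, lab, max)
  data.frame(label = seq_len(n), area_px = area,
             centroid_row = sum_r / area, centroid_col = sum_c / area,
             row_min = as.integer(rmin), row_max = as.integer(rmax),
             col_min = as.integer(cmin), col_max = as.integer(cmax),
             length_px = as.integer(cmax - cmin + 1L))
}

#' Remove small or short components from a mask
#'
#' @param mask logical matrix.
#' @param min_area keep components with area >= `min_area` pixels.
#' @param min_length keep components with horizontal extent >= `min_length`.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_area = 0, min_length = 0,
                                    connectivity = 8L) {
  if (!is.logical(mask)) mask <- mask > 0
  if (min_area <= 1 && min_length <= 1) return(mask)
  labels <- label_components(mask, connectivity)
  tab <- component_table(labels)
  bad <- tab$label[tab$area_px < min_area | tab$length_px < min_length]
  if (length(bad)) mask[labels %in% bad] <- FALSE
  mask
}

#' Lesion mask container
#'
#' A binary raster plus its connected-component table. The component areas
#' always sum to the number of foreground pixels.
#'
#' @param mask logical matrix.
#' @param min_area_px minimum component area recorded with the mask (areas in
#'   the table are all >= this filter by construction when the mask was
#'   cleaned with it).
#' @return object of class `lesion_mask` with fields `mask`, `components`,
#'   `min_area_px`.
#' @export
lesion_mask <- function(mask, min_area_px = 0) {
  if (!is.logical(mask)) mask <- mask > 0
  comps <- component_table(label_components(mask))
  structure(list(mask = mask, components = comps, min_area_px = min_area_px),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d, %d component(s), %d px total\n",
              nrow(x$mask), ncol(x$mask), nrow(x$components), sum(x$mask)))
  invisible(x)
}

#' Distance to the nearest background pixel (chamfer approximation)
#'
#' @param mask logical matrix; distance is 0 on background.
#' @return numeric matrix.
#' @export
distance_transform <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  cpp_chamfer_distance(mask)
}
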