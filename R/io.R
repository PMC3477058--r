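#' Read a PNM raster (PGM/PPM, ASCII or binary)
#'
#' Dependency-free reader for portable anymap images: P2/P5 grayscale and
#' P3/P6 color, 8-bit or 16-bit, normalized to \[0, 1\]. This is the
#' plain-text-capable raster interchange format used by the package (no
#' compressed-format codecs are bundled).
#'
#' @param path file path.
#' @param axial_um_per_px if not NULL, return an `oct_image` with this pitch
#'   (grayscale inputs only).
#' @return an `rgb_image`, `gray_image` or `oct_image`.
#' @export
read_pnm <- function(path, axial_um_per_px = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_typed("bad_format", "read_pnm: unsupported magic '", magic, "'")
  ascii <- magic %in% c("P2", "P3")
  color <- magic %in% c("P3", "P6")
  # header tokens (width, height, maxval), '#' comments allowed
  tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1)
    if (length(ch) == 0L) stop_typed("bad_format", "read_pnm: truncated header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  W <- as.integer(tokens[1]); H <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  n <- H * W * if (color) 3L else 1L
  vals <- if (ascii) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n))
  } else {
    readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop_typed("bad_format", "read_pnm: truncated data")
  vals <- vals / maxval
  if (color) {
    px <- array(0, c(H, W, 3))
    for (ch in 1:3)  # pixel-interleaved, row-major
      px[, , ch] <- matrix(vals[seq(ch, n, by = 3)], H, W, byrow = TRUE)
    rgb_image(px)
  } else {
    m <- matrix(vals, H, W, byrow = TRUE)
    if (is.null(axial_um_per_px)) gray_image(m)
    else oct_image(m, axial_um_per_px)
  }
}

#' Write a PNM raster
#'
#' @param img `rgb_image`, `gray_image`, `oct_image`, matrix, or logical
#'   mask.
#' @param path output file path.
#' @param ascii write the text variant (P2/P3) instead of binary (P5/P6).
#' @param maxval 255 or 65535.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE, maxval = 255L) {
  px <- if (inherits(img, "rgb_image")) img$pixels
  else if (is.logical(img)) matrix(as.numeric(img), nrow(img))
  else as_pixels(img)
  color <- length(dim(px)) == 3L
  q <- round(px * maxval)
  H <- dim(px)[1]; W <- dim(px)[2]
  if (color) {
    inter <- integer(H * W * 3L)
    for (ch in 1:3)
      inter[seq(ch, length(inter), by = 3L)] <- as.integer(t(q[, , ch]))
    vals <- inter
  } else {
    vals <- as.integer(t(q))
  }
  magic <- if (ascii) { if (color) "P3" else "P2" }
  else { if (color) "P6" else "P5" }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", magic, W, H, maxval), con,
            eos = NULL)
  if (ascii) {
    writeLines(paste(vals, collapse = " "), con)
  } else if (maxval < 256L) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(vals, con, size = 2, endian = "big")
  }
  invisible(path)
}

#' Export a component table as CSV
#'
#' @param x a `lesion_mask` or a component data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(x, path) {
  tab <- if (inherits(x, "lesion_mask")) x$components else x
  utils::write.csv(tab[, c("label", "area_px", "centroid_row",
                           "centroid_col")], path, row.names = FALSE)
  invisible(path)
}

#' Export a boundary-trace pair as CSV
#'
#' Columns: col, anterior_row, posterior_row, thickness_um.
#'
#' @param anterior,posterior [boundary_trace()]s.
#' @param report the matching `rnfl_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(anterior, posterior, report, path) {
  utils::write.csv(data.frame(col = seq_along(anterior),
                              anterior_row = as.numeric(anterior),
                              posterior_row = as.numeric(posterior),
                              thickness_um = report$thickness_um),
                   path, row.names = FALSE)
  invisible(path)
}

report_to_list <- function(x) {
  if (inherits(x, "dr_report")) {
    list(grade = x$grade,
         exudate_area_px = x$exudate_area_px,
         mahm_area_px = x$mahm_area_px,
         exudate_fovea_px = x$exudate_fovea_px,
         mahm_fovea_px = x$mahm_fovea_px,
         per_region_areas = as.data.frame(x$per_region_areas))
  } else if (inherits(x, "rnfl_report")) {
    list(mean_thickness_um = x$mean_thickness_um, label = x$label,
         axial_um_per_px = x$axial_um_per_px,
         thickness_um = x$thickness_um)
  } else stop_typed("bad_input", "report_to_list: unknown report type")
}

#' Serialize a report to JSON
#'
#' @param x a `dr_report` or `rnfl_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(report_to_list(x), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Render boundary traces over a B-scan
#'
#' Grayscale scan replicated to RGB with the anterior trace drawn in blue
#' and the posterior in red.
#'
#' @param img the `oct_image` (or matrix).
#' @param anterior,posterior fully defined [boundary_trace()]s.
#' @return an `rgb_image`.
#' @export
render_rnfl_overlay <- function(img, anterior, posterior) {
  px <- as_pixels(img)
  H <- nrow(px); W <- ncol(px)
  out <- array(rep(px, 3), c(H, W, 3))
  ai <- cbind(pmin(pmax(round(as.numeric(anterior)), 1), H), seq_len(W))
  pi_ <- cbind(pmin(pmax(round(as.numeric(posterior)), 1), H), seq_len(W))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ai] <- if (ch == 3) 1 else 0      # anterior: blue
    plane[pi_] <- if (ch == 1) 1 else 0     # posterior: red
    out[, , ch] <- plane
  }
  rgb_image(out)
}

#' Render lesion masks over a fundus image
#'
#' Exudates are tinted yellow, MAHM red, the optic-disc boundary ring green.
#'
#' @param img the `rgb_image`.
#' @param exudates,mahm [lesion_mask()]s (optional).
#' @param disc an `optic_disc` (optional).
#' @return an `rgb_image`.
#' @export
render_dr_overlay <- function(img, exudates = NULL, mahm = NULL,
                              disc = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  out <- img$pixels
  tint <- function(px, mask, rgb) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- rgb[ch]
      px[, , ch] <- plane
    }
    px
  }
  if (!is.null(exudates)) out <- tint(out, exudates$mask, c(1, 1, 0))
  if (!is.null(mahm)) out <- tint(out, mahm$mask, c(1, 0, 0))
  if (!is.null(disc)) {
    ring <- (mo_dilate(matrix(as.numeric(disc$mask), nrow(disc$mask)),
                       disk_se(3)) > 0.5) & !disc$mask
    out <- tint(out, ring, c(0, 1, 0))
  }
  rgb_image(out)
}
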