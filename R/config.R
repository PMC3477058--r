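#' Pipeline configuration
#'
#' Collects every tunable of the two pipelines with its default: fundus
#' preprocessing and detector parameters, grading geometry and thresholds,
#' diffusion and snake parameters for the OCT chain, the posterior cleanup
#' cascade and the axial pixel pitch. The object round-trips losslessly
#' through JSON; invalid values are rejected with field-level messages at
#' construction/load time.
#'
#' @param fundus,grading,oct named lists overriding individual defaults.
#' @param axial_um_per_px axial pitch in microns per pixel.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fundus = list(), grading = list(), oct = list(),
                            axial_um_per_px = 6) {
  def_fundus <- list(
    n_tiles = 8L, clip_limit = 0.005, preprocess = TRUE,
    s1_px = 3, s2_px = 9, s3_px = 13, s4_px = 25, scale_with_width = TRUE,
    vessel_min_area_px = 150, exudate_min_area_px = 10, mahm_min_area_px = 5,
    confirm_green = TRUE, vessel_dilate_px = 3,
    disc_threshold_offset = 0.02,
    fovea_search_odd = c(2, 3), fovea_angle_tol_deg = 45)
  def_grading <- list(radii_odd = c(1, 2, 3.5),
                      a_mild_px = 500, a_sev_px = 10000,
                      neovascularization = FALSE)
  def_oct <- list(
    lam = 0.125, K = NULL, n_iter = 40L, neighbors = 8L,
    snake_alpha = 1, snake_beta = 1, snake_gamma = 1.2,
    snake_window = 7L, snake_max_iter = 50L, snake_move_stop = 0.02,
    snake_posterior = FALSE,
    anterior_area_fraction = 0.0007, anterior_min_length_px = 25,
    posterior_area1_px = 100, posterior_min_length_px = 25,
    posterior_area2_px = 70, rpe_depth_px = 60, anterior_margin_px = 5,
    median_points = 50L)
  merge1 <- function(def, user, where) {
    user <- user[!vapply(user, is.null, logical(1))]  # NULL = keep default
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop_typed("bad_config", "pipeline_config: unknown ", where,
                 " field(s): ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- structure(list(fundus = merge1(def_fundus, fundus, "fundus"),
                        grading = merge1(def_grading, grading, "grading"),
                        oct = merge1(def_oct, oct, "oct"),
                        axial_um_per_px = axial_um_per_px),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  f <- cfg$fundus; g <- cfg$grading; o <- cfg$oct
  chk <- function(ok, field, msg) {
    if (!ok) stop_typed("bad_config", "pipeline_config: ", field, " ", msg)
  }
  chk(f$s1_px < f$s2_px && f$s2_px < f$s3_px && f$s3_px < f$s4_px,
      "fundus scales", "must satisfy s1 < s2 < s3 < s4")
  chk(f$clip_limit > 0, "fundus$clip_limit", "must be > 0")
  chk(length(f$fovea_search_odd) == 2 &&
        f$fovea_search_odd[1] < f$fovea_search_odd[2],
      "fundus$fovea_search_odd", "must be an increasing pair")
  chk(length(g$radii_odd) == 3 && all(diff(g$radii_odd) > 0),
      "grading$radii_odd", "must be three increasing radii")
  chk(g$a_mild_px >= 0 && g$a_sev_px >= g$a_mild_px,
      "grading thresholds", "need 0 <= a_mild <= a_sev")
  chk(o$lam > 0 && o$lam <= 0.25, "oct$lam", "must be in (0, 0.25]")
  chk(is.null(o$K) || o$K > 0, "oct$K", "must be > 0 or NULL")
  chk(o$n_iter >= 1, "oct$n_iter", "must be >= 1")
  chk(o$snake_window >= 3 && o$snake_window %% 2 == 1,
      "oct$snake_window", "must be odd and >= 3")
  chk(cfg$axial_um_per_px > 0, "axial_um_per_px", "must be > 0")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @export
config_to_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(fundus = x$fundus %||% list(),
                  grading = x$grading %||% list(),
                  oct = x$oct %||% list(),
                  axial_um_per_px = x$axial_um_per_px %||% 6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
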