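run_stage <- function(name, expr, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop_typed("stage_failure", "stage '", name, "' failed: ",
               conditionMessage(e))
  })
  if (verbose)
    message(sprintf("[retinodiag] %-12s %6.2f s", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

load_rgb <- function(image) {
  if (inherits(image, "rgb_image")) image
  else if (is.character(image)) read_pnm(image)
  else stop_typed("bad_input", "expected an rgb_image or a PNM path")
}

#' Diabetic-retinopathy grading pipeline
#'
#' Runs the full fundus chain in order: preprocessing, optic-disc detection,
#' vessel extraction, exudate detection, fovea localization, MAHM detection,
#' ten-region partition, severity grading. Stage failures propagate with the
#' stage name attached; each stage's timing is logged via `message()`.
#'
#' @param image an `rgb_image` or a PNM file path.
#' @param config a [pipeline_config()].
#' @param out_dir if not NULL, writes report.json, per-region CSV and all
#'   masks (PGM) there.
#' @param verbose log stage timings.
#' @return list with `report` (a `dr_report`) and every intermediate:
#'   `disc`, `vessels`, `exudates`, `fovea`, `mahm`, `partition`.
#' @export
run_dr_pipeline <- function(image, config = pipeline_config(),
                            out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  fc <- config$fundus
  img <- run_stage("load", load_rgb(image), verbose)
  pre <- if (isTRUE(fc$preprocess))
    run_stage("preprocess", fundus_preprocess(img, fc$n_tiles, fc$clip_limit),
              verbose)
  else img
  scales <- if (isTRUE(fc$scale_with_width)) {
    f <- img$width_px / 700
    morph_scales(max(1, round(fc$s1_px * f)), max(2, round(fc$s2_px * f)),
                 max(3, round(fc$s3_px * f)), max(4, round(fc$s4_px * f)))
  } else morph_scales(fc$s1_px, fc$s2_px, fc$s3_px, fc$s4_px)
  shape <- c(img$height_px, img$width_px)
  disc <- run_stage("optic_disc",
                    detect_optic_disc(pre, fc$disc_threshold_offset), verbose)
  vessels <- run_stage("vessels",
                       extract_vessels(pre, scales,
                                       scale_area(fc$vessel_min_area_px, shape)),
                       verbose)
  exudates <- run_stage("exudates",
                        detect_exudates(pre, scales, disc, fc$confirm_green,
                                        scale_area(fc$exudate_min_area_px, shape)),
                        verbose)
  fovea <- run_stage("fovea",
                     detect_fovea(pre, vessels, disc, fc$fovea_search_odd,
                                  fc$fovea_angle_tol_deg), verbose)
  mahm <- run_stage("mahm",
                    detect_mahm(pre, vessels, fc$vessel_dilate_px,
                                scale_area(fc$mahm_min_area_px, shape)),
                    verbose)
  partition <- run_stage("partition",
                         fundus_coordinates(disc, fovea, shape,
                                            config$grading$radii_odd), verbose)
  report <- run_stage("grade",
                      grade_severity(exudates, mahm, partition,
                                     grading_thresholds(config$grading$a_mild_px,
                                                        config$grading$a_sev_px),
                                     config$grading$neovascularization),
                      verbose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "dr_report.json"))
    utils::write.csv(as.data.frame(report$per_region_areas),
                     file.path(out_dir, "per_region_areas.csv"))
    write_pnm(disc$mask, file.path(out_dir, "optic_disc_mask.pgm"))
    write_pnm(vessels$mask, file.path(out_dir, "vessel_mask.pgm"))
    write_pnm(exudates$mask, file.path(out_dir, "exudate_mask.pgm"))
    write_pnm(mahm$mask, file.path(out_dir, "mahm_mask.pgm"))
    write_pnm(partition$label_map / 10, file.path(out_dir, "partition.pgm"))
    write_components_csv(exudates, file.path(out_dir, "exudate_components.csv"))
    write_components_csv(mahm, file.path(out_dir, "mahm_components.csv"))
    write_pnm(render_dr_overlay(img, exudates, mahm, disc),
              file.path(out_dir, "overlay.ppm"))
  }
  list(report = report, disc = disc, vessels = vessels, exudates = exudates,
       fovea = fovea, mahm = mahm, partition = partition)
}

#' RNFL boundary extraction for a single B-scan
#'
#' Pre-smoothing (10 x 10 Gaussian sigma 4, then 3 x 3 median), initial
#' anterior estimate, greedy-snake refinement, posterior estimation with the
#' cleanup cascade, thickness and classification.
#'
#' @param image an `oct_image` or PNM path.
#' @param config a [pipeline_config()].
#' @param verbose log stage timings.
#' @return list with `report` (an `rnfl_report`), `anterior`, `posterior`.
#' @export
run_rnfl_single <- function(image, config = pipeline_config(),
                            verbose = TRUE) {
  oc <- config$oct
  img <- if (inherits(image, "oct_image")) image
  else if (is.character(image)) read_pnm(image, config$axial_um_per_px)
  else stop_typed("bad_input", "expected an oct_image or a PNM path")
  if (!inherits(img, "oct_image"))
    img <- oct_image(img$pixels, config$axial_um_per_px)
  sm <- run_stage("presmooth",
                  median_filter(gaussian_smooth(img)), verbose)
  init <- run_stage("anterior_init",
                    initial_anterior(sm, oc$anterior_area_fraction,
                                     oc$anterior_min_length_px), verbose)
  sp <- snake_params(oc$snake_alpha, oc$snake_beta, oc$snake_gamma,
                     oc$snake_window, oc$snake_max_iter, oc$snake_move_stop)
  dp <- diffusion_params(oc$lam, oc$K, oc$n_iter, oc$neighbors)
  anterior <- run_stage("snake", greedy_snake(sm, init, sp), verbose)
  # posterior stage works on the unsmoothed scan: anisotropic diffusion is
  # its own edge-preserving smoother, and the Gaussian-blurred edge ridge
  # would bias the first-from-top boundary upward
  posterior <- run_stage("posterior",
                         estimate_posterior(img, anterior, dp,
                                            oc$posterior_area1_px,
                                            oc$posterior_min_length_px,
                                            oc$posterior_area2_px,
                                            oc$rpe_depth_px,
                                            oc$anterior_margin_px,
                                            oc$median_points), verbose)
  if (isTRUE(oc$snake_posterior))
    posterior <- run_stage("snake_post", greedy_snake(sm, posterior, sp),
                           verbose)
  report <- run_stage("thickness",
                      rnfl_thickness(anterior, posterior,
                                     img$axial_um_per_px %||%
                                       config$axial_um_per_px), verbose)
  list(report = report, anterior = anterior, posterior = posterior)
}

#' RNFL screening pipeline over one or more B-scans
#'
#' Runs [run_rnfl_single()] per image; with `per_patient = TRUE` the
#' per-image mean thicknesses are averaged (the three-scans-per-eye protocol
#' aggregates by the mean of per-image means) and the aggregate is classified
#' by the 105 um rule. Failed images are reported with a warning and the
#' aggregate is computed over the successes.
#'
#' @param images list/vector of `oct_image`s or PNM paths (at least one).
#' @param config a [pipeline_config()].
#' @param per_patient aggregate across images.
#' @param out_dir if not NULL, write per-image trace CSVs and report JSONs.
#' @param verbose log stage timings.
#' @return list with `results` (per-image lists), `failures` (messages),
#'   and if `per_patient`, `aggregate_mean_um` and `aggregate_label`.
#' @export
run_rnfl_pipeline <- function(images, config = pipeline_config(),
                              per_patient = FALSE, out_dir = NULL,
                              verbose = TRUE) {
  if (is.character(images)) images <- as.list(images)
  if (!is.list(images) || length(images) == 0L)
    stop_typed("usage", "run_rnfl_pipeline: need at least one input image")
  results <- list(); failures <- character(0)
  for (i in seq_along(images)) {
    r <- tryCatch(run_rnfl_single(images[[i]], config, verbose),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, sprintf("image %d: %s", i, conditionMessage(r)))
    } else {
      results[[length(results) + 1L]] <- r
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_report_json(r$report,
                          file.path(out_dir, sprintf("rnfl_%02d.json", i)))
        write_traces_csv(r$anterior, r$posterior, r$report,
                         file.path(out_dir, sprintf("traces_%02d.csv", i)))
        img_i <- if (inherits(images[[i]], "oct_image")) images[[i]]
        else read_pnm(images[[i]], config$axial_um_per_px)
        write_pnm(render_rnfl_overlay(img_i, r$anterior, r$posterior),
                  file.path(out_dir, sprintf("overlay_%02d.ppm", i)))
      }
    }
  }
  if (length(failures))
    warning("failed images: ", paste(failures, collapse = "; "),
            call. = FALSE)
  out <- list(results = results, failures = failures)
  if (per_patient) {
    if (length(results) == 0L)
      stop_typed("all_failed", "run_rnfl_pipeline: every image failed")
    means <- vapply(results, function(r) r$report$mean_thickness_um,
                    numeric(1))
    out$aggregate_mean_um <- mean(means)
    out$aggregate_label <- classify_glaucoma(out$aggregate_mean_um)
  }
  out
}
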