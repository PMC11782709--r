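#' Scripted experiments
#'
#' Each experiment runs a fully specified simulation study, writes CSV
#' tables (and a JSON report for the correction study) into `out_dir`, and
#' returns its results invisibly. Outputs carry provenance metadata (a hash
#' of the experiment arguments, the seed and the package version) and are
#' reproducible bit for bit for a fixed seed.
#'
#' * `exp_ecg_interleaved()`: ECG-interleaved FISP and FLASH phase-contrast
#'   traces versus cardiac phase for several injected background phases —
#'   the transient perturbation that decays toward (without reaching) the
#'   injected value.
#' * `exp_tr_interleaved()`: TR-interleaved deviation-versus-input curves
#'   for FISP and FLASH.
#' * `exp_relaxation()`: relaxation-time sweeps for both interleavings and
#'   contrasts, including the two gel phantom presets.
#' * `exp_correction_bias()`: renders the vessel scene under all four
#'   sequence modes, runs the full static-tissue correction, and reports
#'   corrected mean flow rates and their orderings.
#'
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param phis Injected background phases in percent of venc.
#' @param tissue Tissue simulated (default the long-relaxation gel).
#' @param config_args Named list of [sequence_config()] overrides applied
#'   to every mode (e.g. smaller isochromat counts for quick runs).
#' @param write_plots Also write ggplot PDFs (default FALSE; tables are the
#'   primary output).
#' @name experiments
NULL

experiment_meta <- function(name, args, seed = NA_integer_) {
  list(experiment = name,
       spec_hash = rlang::hash(args),
       seed = seed,
       package_version = as.character(utils::packageVersion("pcsteady")))
}

write_experiment_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

sweep_table <- function(sweep) {
  dplyr::select(tibble::as_tibble(sweep), "phi_pct_venc", "t1_ms", "t2_ms",
                "contrast", "interleave", "deviation_pct_venc")
}

series_table <- function(sweep) {
  tibble::as_tibble(sweep) |>
    dplyr::mutate(series = purrr::map(.data$series, tibble::as_tibble)) |>
    dplyr::select("phi_pct_venc", "t1_ms", "t2_ms", "contrast", "interleave",
                  "series") |>
    tidyr::unnest("series")
}

#' @rdname experiments
#' @export
exp_ecg_interleaved <- function(out_dir = NULL,
                                phis = c(-20, -10, -5, 5, 10, 20),
                                tissue = tissue_p2(),
                                config_args = list(),
                                write_plots = FALSE) {
  sweeps <- purrr::map(c("FISP", "FLASH"), function(con) {
    cfg <- do.call(sequence_config, utils::modifyList(
      list(contrast = con, interleave = "ECG", n_cycles = 8), config_args))
    sweep_background(cfg, tissue, phi_list = phis)
  })
  out <- dplyr::bind_rows(sweeps)
  class(out) <- c("pc_sweep", class(out))
  tab <- series_table(out)
  write_experiment_csv(tab, out_dir, "ecg_interleaved_traces")
  write_experiment_csv(sweep_table(out), out_dir, "ecg_interleaved_deviation")
  if (write_plots && !is.null(out_dir))
    ggplot2::ggsave(file.path(out_dir, "ecg_interleaved_traces.pdf"),
                    autoplot_series_sweep(out), width = 8, height = 5)
  if (!is.null(out_dir))
    jsonlite::write_json(
      experiment_meta("ecg_interleaved", list(phis = phis, tissue = unclass(tissue))),
      file.path(out_dir, "ecg_interleaved_meta.json"), auto_unbox = TRUE)
  invisible(out)
}

#' @rdname experiments
#' @export
exp_tr_interleaved <- function(out_dir = NULL,
                               phis = c(-20, -10, -5, -2, 2, 5, 10, 20),
                               tissue = tissue_p2(),
                               config_args = list(),
                               write_plots = FALSE) {
  sweeps <- purrr::map(c("FISP", "FLASH"), function(con) {
    cfg <- do.call(sequence_config, utils::modifyList(
      list(contrast = con, interleave = "TR"), config_args))
    sweep_background(cfg, tissue, phi_list = phis)
  })
  out <- dplyr::bind_rows(sweeps)
  class(out) <- c("pc_sweep", class(out))
  write_experiment_csv(sweep_table(out), out_dir, "tr_interleaved_deviation")
  if (write_plots && !is.null(out_dir))
    ggplot2::ggsave(file.path(out_dir, "tr_interleaved_deviation.pdf"),
                    ggplot2::autoplot(out), width = 6, height = 4)
  if (!is.null(out_dir))
    jsonlite::write_json(
      experiment_meta("tr_interleaved", list(phis = phis, tissue = unclass(tissue))),
      file.path(out_dir, "tr_interleaved_meta.json"), auto_unbox = TRUE)
  invisible(out)
}

#' @rdname experiments
#' @param t1_list,t2_list Relaxation times swept (ms).
#' @param bg Injected background phase for the relaxation sweep (%venc).
#' @export
exp_relaxation <- function(out_dir = NULL,
                           t1_list = c(10, 300, 720, 2000),
                           t2_list = c(10, 40, 160),
                           bg = 6,
                           config_args = list(),
                           write_plots = FALSE) {
  combos <- tidyr::expand_grid(contrast = c("FISP", "FLASH"),
                               interleave = c("TR", "ECG"))
  out <- purrr::pmap(combos, function(contrast, interleave) {
    cfg <- do.call(sequence_config, utils::modifyList(
      list(contrast = contrast, interleave = interleave,
           n_cycles = if (interleave == "ECG") 8 else 7), config_args))
    suppressWarnings(sweep_relaxation(cfg, t1_list, t2_list, bg = bg))
  }) |> dplyr::bind_rows()
  class(out) <- c("pc_sweep", class(out))
  write_experiment_csv(sweep_table(out), out_dir, "relaxation_deviation")
  write_experiment_csv(series_table(out), out_dir, "relaxation_traces")
  if (!is.null(out_dir))
    jsonlite::write_json(
      experiment_meta("relaxation", list(t1 = t1_list, t2 = t2_list, bg = bg)),
      file.path(out_dir, "relaxation_meta.json"), auto_unbox = TRUE)
  invisible(out)
}

#' @rdname experiments
#' @param seed Seed for the (noisy) scene renders.
#' @param scene_args Overrides passed to [make_scene()].
#' @param render_args Overrides passed to [render_timeseries()].
#' @export
exp_correction_bias <- function(out_dir = NULL, seed = 1L,
                                scene_args = list(), render_args = list(),
                                config_args = list()) {
  modes <- tidyr::expand_grid(contrast = c("FISP", "FLASH"),
                              interleave = c("TR", "ECG"))
  res <- purrr::pmap(modes, function(contrast, interleave) {
    scene <- do.call(make_scene, utils::modifyList(
      list(preset = "vessel_demo", seed = seed), scene_args))
    cfg <- do.call(sequence_config, utils::modifyList(
      list(contrast = contrast, interleave = interleave, venc = 60,
           n_cycles = if (interleave == "ECG") 6 else 5), config_args))
    stack <- do.call(render_timeseries,
                     c(list(scene = scene, config = cfg,
                            vessel_mode = "fresh"), render_args))
    corr <- correct_stack(stack)
    roi <- scene$vessel_mask
    px_area <- prod(scene$grid$px_mm)
    fl_un <- flow_rate(corr$velocity, roi, px_area)
    fl_co <- flow_rate(corr$corrected, roi, px_area)
    truth <- flow_rate(stack$truth_vel, roi, px_area)
    tibble::tibble(
      contrast = contrast, interleave = interleave,
      mode = paste(interleave, contrast, sep = "-"),
      flow_uncorrected_mls = glance(fl_un)$mean_flow_mls,
      flow_corrected_mls = glance(fl_co)$mean_flow_mls,
      flow_truth_mls = glance(truth)$mean_flow_mls,
      mask_pixels = sum(corr$mask))
  }) |> dplyr::bind_rows()

  flows <- setNames(res$flow_corrected_mls, res$mode)
  report <- list(
    meta = experiment_meta("correction_bias",
                           list(scene_args = scene_args,
                                config_args = config_args), seed = seed),
    flows = res,
    orderings = list(
      ecg_fisp_gt_flash = unname(flows["ECG-FISP"] > flows["ECG-FLASH"]),
      tr_fisp_lt_flash = unname(flows["TR-FISP"] < flows["TR-FLASH"])))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_experiment_csv(res, out_dir, "correction_bias_flows")
    jsonlite::write_json(report, file.path(out_dir, "correction_bias.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}
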