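#' Sweep the injected background phase
#'
#' Runs one full simulation per requested background phase and summarizes
#' the steady-state deviation of the measured phase contrast; the full
#' per-cardiac-phase series is kept in a list column for plotting.
#'
#' @inheritParams run_sequence
#' @param phi_list Background phases to simulate, in percent of venc.
#' @param n_avg Trailing pairs averaged by [steady_state_deviation()].
#' @param warmup_cycles Cycles discarded before averaging/plotting
#'   (default 2).
#' @return A `pc_sweep` tibble with columns `phi_pct_venc`, `t1_ms`,
#'   `t2_ms`, `contrast`, `interleave`, `deviation_pct_venc` and a `series`
#'   list column of `pc_series` (warm-up removed).
#' @examples
#' cfg <- sequence_config(n_tr_per_cycle = 30, n_trigger_tr = 2, n_cycles = 4,
#'                        n_slice = 5, n_spoiler = 16)
#' sweep_background(cfg, tissue_p2(), phi_list = c(-5, 0, 5), n_avg = 5)
#' @export
sweep_background <- function(config, tissue, phi_list, n_avg = 20,
                             warmup_cycles = 2) {
  if (length(phi_list) == 0) abort("`phi_list` must be non-empty.")
  rows <- purrr::map(phi_list, function(phi) {
    series <- run_sequence(config, tissue, bg = phi) |>
      phase_contrast() |>
      drop_warmup(warmup_cycles)
    tibble::tibble(
      phi_pct_venc = phi,
      t1_ms = tissue$t1, t2_ms = tissue$t2,
      contrast = config$contrast, interleave = config$interleave,
      deviation_pct_venc = steady_state_deviation(series, phi, n_avg),
      series = list(series))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("pc_sweep", class(out))
  out
}

#' Sweep tissue relaxation times
#'
#' Runs the sequence for every valid combination of the supplied T1 and T2
#' values (pairs with `t2 > t1` are skipped with a warning) and reports the
#' steady-state deviation plus the full series for each.
#'
#' @inheritParams sweep_background
#' @param t1_list,t2_list Relaxation times in ms. Combined as a full grid.
#' @param bg Injected background phase in percent of venc.
#' @return A `pc_sweep` tibble (same columns as [sweep_background()]).
#' @export
sweep_relaxation <- function(config, t1_list, t2_list, bg, n_avg = 20,
                             warmup_cycles = 2) {
  if (length(t1_list) == 0 || length(t2_list) == 0)
    abort("`t1_list` and `t2_list` must be non-empty.")
  grid <- tidyr::expand_grid(t1 = t1_list, t2 = t2_list)
  bad <- grid$t2 > grid$t1
  if (any(bad)) {
    warn(sprintf("Skipping %d (T1, T2) pairs with T2 > T1.", sum(bad)))
    grid <- grid[!bad, ]
  }
  rows <- purrr::pmap(grid, function(t1, t2) {
    tis <- tissue_properties(t1, t2)
    sweep_background(config, tis, phi_list = bg, n_avg = n_avg,
                     warmup_cycles = warmup_cycles)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("pc_sweep", class(out))
  out
}

drop_warmup <- function(series, warmup_cycles) {
  if (warmup_cycles <= 0) return(series)
  cfg <- attr(series, "config")
  out <- dplyr::filter(series, .data$cycle > warmup_cycles)
  if (nrow(out) == 0) {
    warn("Warm-up removal would empty the series; keeping all cycles.")
    return(series)
  }
  attr(out, "config") <- cfg
  class(out) <- unique(c("pc_series", class(out)))
  out
}

#' @method tidy pc_sweep
#' @export
tidy.pc_sweep <- function(x, ...) sweep_table(x)

#' @method glance pc_sweep
#' @export
glance.pc_sweep <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x),
    max_abs_deviation_pct_venc = max(abs(x$deviation_pct_venc)),
    contrasts = paste(sort(unique(x$contrast)), collapse = ","),
    interleaves = paste(sort(unique(x$interleave)), collapse = ","))
}
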