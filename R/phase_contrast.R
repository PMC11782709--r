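#' Phase-contrast series from a signal trace
#'
#' Pairs flow-encoded with flow-compensated echoes and computes the
#' phase difference `arg(S_enc * Conj(S_comp))`, wrapped to `(-pi, pi]`.
#' The sign convention makes the result converge to `+phi_rad` (the injected
#' phase) in the perfect-spoiling limit.
#'
#' * TR-interleaved traces: consecutive in-window repetitions within a cycle
#'   form one pair; an unpaired trailing sample is dropped with a warning.
#' * ECG-interleaved traces: in-window repetition `j` of each encoded cycle
#'   is paired with in-window repetition `j` of the adjacent *preceding*
#'   compensated cycle, giving one series per cycle pair.
#'
#' @param trace A `pc_trace` from [run_sequence()].
#' @param config The sequence configuration; defaults to the one attached to
#'   the trace.
#' @return A `pc_series` tibble with columns `pair` (cycle-pair or pair
#'   counter), `phase_index`, `time_ms`, `dphi_rad`, `pct_venc`
#'   (`= dphi_rad / pi * 100`), `velocity_cms` (`= dphi_rad / pi * venc`)
#'   and `magnitude` (mean magnitude of the paired echoes).
#' @export
phase_contrast <- function(trace, config = attr(trace, "config")) {
  stopifnot(!is.null(config))
  iw <- dplyr::filter(trace, .data$in_window)
  if (config$interleave == "TR") {
    out <- iw |>
      dplyr::group_by(.data$cycle) |>
      dplyr::group_modify(function(d, key) pair_within_cycle(d)) |>
      dplyr::ungroup() |>
      dplyr::mutate(pair = dplyr::row_number()) |>
      dplyr::select("pair", "cycle", "phase_index", "time_ms",
                    "dphi_rad", "magnitude")
  } else {
    enc_cycles <- sort(unique(iw$cycle[iw$encoded]))
    comp_cycles <- sort(unique(iw$cycle[!iw$encoded]))
    pairs <- purrr::keep(enc_cycles, function(c) (c - 1) %in% comp_cycles)
    if (length(pairs) == 0)
      abort("No encoded cycle with a preceding compensated cycle found.")
    out <- purrr::map_dfr(seq_along(pairs), function(i) {
      ce <- pairs[i]
      e <- dplyr::filter(iw, .data$cycle == ce)
      c_ <- dplyr::filter(iw, .data$cycle == ce - 1)
      stopifnot(nrow(e) == nrow(c_))
      tibble::tibble(
        pair = i, cycle = ce,
        phase_index = seq_len(nrow(e)),
        time_ms = e$time_ms,
        dphi_rad = wrap_pi(Arg(e$signal * Conj(c_$signal))),
        magnitude = (Mod(e$signal) + Mod(c_$signal)) / 2
      )
    })
  }
  out <- dplyr::mutate(out,
    pct_venc = .data$dphi_rad / pi * 100,
    velocity_cms = .data$dphi_rad / pi * config$venc)
  attr(out, "config") <- config
  class(out) <- c("pc_series", class(out))
  out
}

pair_within_cycle <- function(d) {
  n <- nrow(d)
  if (n %% 2 == 1) {
    warn("Unpaired trailing in-window repetition dropped.")
    d <- d[seq_len(n - 1), ]
    n <- n - 1
  }
  i1 <- seq(1, n, by = 2)
  i2 <- i1 + 1
  # one of each pair is encoded, the other compensated
  stopifnot(all(xor(d$encoded[i1], d$encoded[i2])))
  s_enc <- ifelse(d$encoded[i1], d$signal[i1], d$signal[i2])
  s_comp <- ifelse(d$encoded[i1], d$signal[i2], d$signal[i1])
  tibble::tibble(
    phase_index = seq_along(i1),
    time_ms = (d$time_ms[i1] + d$time_ms[i2]) / 2,
    dphi_rad = wrap_pi(Arg(s_enc * Conj(s_comp))),
    magnitude = (Mod(s_enc) + Mod(s_comp)) / 2
  )
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Steady-state deviation of the measured background phase
#'
#' Mean difference between the measured phase contrast (in percent of venc)
#' and the injected background phase over the last `n_avg` encoding pairs of
#' the series.
#'
#' @param series A `pc_series` from [phase_contrast()].
#' @param bg The injected [background_phase()] (or a number in %venc).
#' @param n_avg Number of trailing encoding pairs to average (default 20).
#' @return Deviation in percent of venc (scalar).
#' @export
steady_state_deviation <- function(series, bg, n_avg = 20) {
  bg <- as_background(bg)
  if (nrow(series) < n_avg)
    abort(sprintf("Series has %d entries; need at least n_avg = %d.",
                  nrow(series), n_avg))
  mean(tail(series$pct_venc, n_avg)) - bg$phi_pct_venc
}

#' Ernst steady-state signal of an ideally spoiled GRE
#'
#' Closed-form on-resonance steady-state magnitude
#' `M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-tr/t1)`,
#' evaluated immediately after excitation (no T2 decay to the echo).
#'
#' @param flip Flip angle in degrees.
#' @param tr Repetition time in ms.
#' @param t1 Longitudinal relaxation time in ms.
#' @param m0 Equilibrium magnetization.
#' @return Steady-state transverse magnitude.
#' @export
ernst_signal <- function(flip, tr, t1, m0 = 1) {
  a <- flip * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Analytic reference series for the perfect-spoiling limit
#'
#' A memoryless per-repetition model: the magnitude is the Ernst steady
#' state attenuated by `exp(-te/t2)`, and the phase contrast equals the
#' injected background phase exactly. Used as an oracle in tests.
#'
#' @inheritParams run_sequence
#' @return A `pc_series` tibble with the same columns as [phase_contrast()].
#' @export
ideal_spoiled_reference <- function(config, tissue, bg = 0) {
  bg <- as_background(bg)
  n_window <- config$n_tr_per_cycle - config$n_trigger_tr
  n_pairs <- if (config$interleave == "TR") n_window %/% 2 else n_window
  mag <- ernst_signal(config$flip, config$tr, tissue$t1, tissue$m0) *
    exp(-config$te / tissue$t2)
  n_cycle_pairs <- if (config$interleave == "TR") config$n_cycles
                   else config$n_cycles %/% 2
  out <- tidyr::expand_grid(pair = seq_len(max(n_cycle_pairs, 1)),
                            phase_index = seq_len(n_pairs)) |>
    dplyr::mutate(
      cycle = .data$pair,
      time_ms = (config$n_trigger_tr + (.data$phase_index - 0.5) *
                   (if (config$interleave == "TR") 2 else 1)) * config$tr,
      dphi_rad = bg$phi_rad,
      magnitude = mag,
      pct_venc = bg$phi_pct_venc,
      velocity_cms = bg$phi_rad / pi * config$venc)
  attr(out, "config") <- config
  class(out) <- c("pc_series", class(out))
  out
}
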