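#' Phase-contrast GRE sequence configuration
#'
#' Describes the timing, contrast and flow-encoding interleaving of a
#' prospectively triggered 2D through-plane phase-contrast gradient-echo
#' sequence. Each cardiac cycle consists of `n_trigger_tr` steady-state
#' trigger repetitions followed by an acquisition window of
#' `n_tr_per_cycle - n_trigger_tr` repetitions; RF pulses and gradients run
#' continuously so the steady state is never interrupted.
#'
#' Two contrasts are supported: `"FISP"` (gradient spoiling only; transverse
#' coherences survive across TRs) and `"FLASH"` (additional RF spoiling with
#' a quadratic phase schedule `phi_k = phi_{k-1} + k * rf_spoil_increment`,
#' receiver phase matched). Two interleavings are supported: `"TR"`
#' (compensated/encoded alternate every repetition, also through the trigger
#' period) and `"ECG"` (one encoding per cardiac cycle; the steady-state
#' trigger already carries the next cycle's encoding, i.e. the switch happens
#' at the end of the acquisition window).
#'
#' Defaults mirror the simulation study conditions: TR 6.8 ms (150 TR per
#' 1020 ms cardiac cycle), flip 10 degrees, 10 trigger TRs, venc 30 cm/s.
#'
#' @param tr Repetition time in ms.
#' @param te Echo (sampling) time in ms, `0 < te < tr`. Default `tr/2`.
#' @param flip Nominal flip angle in degrees.
#' @param contrast `"FISP"` or `"FLASH"`.
#' @param rf_spoil_increment RF-spoiling phase increment in degrees. Must be
#'   0 for FISP; defaults to 50 for FLASH.
#' @param interleave `"TR"` or `"ECG"`.
#' @param n_tr_per_cycle Repetitions per cardiac cycle (default 150).
#' @param n_trigger_tr Leading steady-state-trigger repetitions per cycle
#'   (default 10); these are excluded from the acquisition window.
#' @param n_cycles Number of simulated cardiac cycles (default 7).
#' @param venc Velocity-encoding parameter in cm/s (default 30). Phase
#'   results in percent of venc are venc-independent.
#' @param n_slice,n_spoiler Isochromat discretization passed to
#'   [equilibrium_ensemble()].
#' @param pulse RF pulse (default windowed sinc with `flip` as nominal flip).
#' @param spoiling `"gradient"` (physical 2-pi spoiler), `"perfect"`
#'   (test-only: transverse magnetization zeroed every TR) or `"fresh"`
#'   (in-flow idealization: full reset to equilibrium every TR).
#' @return A `pc_config` object.
#' @examples
#' sequence_config(contrast = "FLASH", interleave = "TR")
#' @export
sequence_config <- function(tr = 6.8, te = tr / 2, flip = 10,
                            contrast = c("FISP", "FLASH"),
                            rf_spoil_increment = NULL,
                            interleave = c("TR", "ECG"),
                            n_tr_per_cycle = 150, n_trigger_tr = 10,
                            n_cycles = 7, venc = 30,
                            n_slice = 33, n_spoiler = 256,
                            pulse = NULL,
                            spoiling = c("gradient", "perfect", "fresh")) {
  contrast <- match.arg(contrast)
  interleave <- match.arg(interleave)
  spoiling <- match.arg(spoiling)
  rf_spoil_increment <- rf_spoil_increment %||%
    (if (contrast == "FLASH") 50 else 0)
  if (!(te > 0 && te < tr)) abort("Require 0 < te < tr.")
  if (n_trigger_tr >= n_tr_per_cycle)
    abort("`n_trigger_tr` must be smaller than `n_tr_per_cycle`.")
  if ((contrast == "FISP") != (rf_spoil_increment == 0))
    abort("FISP requires rf_spoil_increment = 0; FLASH requires it nonzero.")
  pulse <- pulse %||% rf_pulse_sinc(nominal_flip = flip)
  structure(list(
    tr = tr, te = te, flip = flip, contrast = contrast,
    rf_spoil_increment = rf_spoil_increment, interleave = interleave,
    n_tr_per_cycle = as.integer(n_tr_per_cycle),
    n_trigger_tr = as.integer(n_trigger_tr),
    n_cycles = as.integer(n_cycles), venc = venc,
    n_slice = as.integer(n_slice), n_spoiler = as.integer(n_spoiler),
    pulse = pulse, spoiling = spoiling
  ), class = "pc_config")
}

#' @export
print.pc_config <- function(x, ...) {
  cat(sprintf(
    "<pc_config> %s, %s-interleaved | TR %g ms, TE %g ms, flip %g deg, venc %g cm/s\n",
    x$contrast, x$interleave, x$tr, x$te, x$flip, x$venc))
  cat(sprintf("  %d cycles x %d TR (%d trigger), %d x %d isochromats, %s spoiling\n",
              x$n_cycles, x$n_tr_per_cycle, x$n_trigger_tr,
              x$n_slice, x$n_spoiler, x$spoiling))
  invisible(x)
}

#' Background phase as a fraction of venc
#'
#' The net spurious phase offset (concomitant-field plus eddy-current
#' contribution) that accompanies the flow-encoded acquisition, expressed in
#' percent of venc; 100 %venc corresponds to pi radians. The flow-compensated
#' acquisition carries zero input phase by convention, so the injected phase
#' equals the phase contrast an ideally spoiled sequence would measure.
#'
#' @param phi_pct_venc Background phase in percent of venc.
#' @return A `pc_background` object with fields `phi_pct_venc` and `phi_rad`.
#' @examples
#' background_phase(5)
#' @export
background_phase <- function(phi_pct_venc) {
  if (!is.numeric(phi_pct_venc) || length(phi_pct_venc) != 1 ||
      !is.finite(phi_pct_venc))
    abort("`phi_pct_venc` must be a single finite number.")
  structure(list(phi_pct_venc = phi_pct_venc,
                 phi_rad = phi_pct_venc * pi / 100),
            class = "pc_background")
}

as_background <- function(bg) {
  if (inherits(bg, "pc_background")) bg else background_phase(bg)
}

# Per-TR encoding labels for a full run. TRUE = flow-encoded.
# TR mode alternates every TR (first TR compensated) right through the
# trigger period; ECG mode holds one encoding per cycle (first cycle
# compensated) and the trigger TRs at the start of a cycle already carry
# that cycle's encoding (the switch happened at the end of the previous
# acquisition window).
encoding_pattern <- function(config) {
  n <- config$n_cycles * config$n_tr_per_cycle
  if (config$interleave == "TR") {
    (seq_len(n) %% 2L) == 0L
  } else {
    cyc <- (seq_len(n) - 1L) %/% config$n_tr_per_cycle  # 0-based cycle
    (cyc %% 2L) == 1L
  }
}

# Quadratic RF-spoiling schedule in radians: phi_k = phi_{k-1} + k * inc,
# phi_0 = 0 (k is the 0-based TR counter), i.e. phi_k = inc * k(k+1)/2.
rf_phase_schedule <- function(n, increment_deg) {
  if (increment_deg == 0) return(rep(0, n))
  k <- as.numeric(0:(n - 1))
  (increment_deg * pi / 180) * ((k * (k + 1) / 2) %% (720 / increment_deg))
}

#' Run a phase-contrast sequence on a single voxel
#'
#' Drives the isochromat ensemble through the full triggered schedule, one
#' repetition at a time: RF excitation (quadratic phase schedule for FLASH),
#' injection of the background (plus any flow-encoding) phase on
#' flow-encoded repetitions, relaxation to the echo time, demodulated signal
#' sampling, relaxation to the end of the repetition, and gradient spoiling.
#' The background phase is injected between excitation and echo, where the
#' asymmetric flow-encoding gradient waveform sits, so an ideally spoiled
#' sequence measures exactly the injected phase while the post-echo
#' coherence pathways of a FISP sequence perturb it.
#'
#' @param config A [sequence_config()].
#' @param tissue A [tissue_properties()] object.
#' @param bg Injected background phase: a [background_phase()] or a number
#'   in percent of venc (applies to flow-encoded repetitions only).
#' @param flow_phase_rad Optional per-TR-in-cycle vector (length
#'   `n_tr_per_cycle`) of additional flow phase in radians added on encoded
#'   repetitions; used by the phantom renderer for pulsatile vessels.
#' @return A `pc_trace` tibble with one row per repetition: `tr_global`,
#'   `cycle`, `tr_in_cycle`, `time_ms` (echo time from cycle start),
#'   `encoded`, `in_window`, and the complex `signal`. The configuration is
#'   attached as attribute `config`.
#' @examples
#' cfg <- sequence_config(n_tr_per_cycle = 20, n_trigger_tr = 2, n_cycles = 3,
#'                        n_slice = 5, n_spoiler = 8)
#' tr <- run_sequence(cfg, tissue_p2(), bg = 5)
#' head(tr)
#' @export
run_sequence <- function(config, tissue, bg = 0, flow_phase_rad = NULL) {
  stopifnot(inherits(config, "pc_config"))
  bg <- as_background(bg)
  if (config$interleave == "ECG" && config$n_cycles < 2)
    abort("ECG-interleaved runs need at least 2 cycles (a compensated/encoded pair).")
  if (!is.null(flow_phase_rad) &&
      length(flow_phase_rad) != config$n_tr_per_cycle)
    abort("`flow_phase_rad` must have one entry per TR in the cycle.")

  ens <- equilibrium_ensemble(tissue, config$n_slice, config$n_spoiler,
                              config$pulse)
  n_tr <- config$n_cycles * config$n_tr_per_cycle
  encoded <- encoding_pattern(config)
  rf_phases <- rf_phase_schedule(n_tr, config$rf_spoil_increment)

  # hot loop on the raw state; identical math to the exported operators
  mxy <- ens$mxy; mz <- ens$mz
  alpha <- config$flip * pi / 180 * ens$flip_scale
  ca <- cos(alpha); sa <- sin(alpha)
  m0 <- tissue$m0
  e2_te <- exp(-config$te / tissue$t2)
  e1_te <- exp(-config$te / tissue$t1)
  e2_rest <- exp(-(config$tr - config$te) / tissue$t2)
  e1_rest <- exp(-(config$tr - config$te) / tissue$t1)
  spoil_fac <- exp(2i * pi * ens$spoiler_coord)
  sig <- complex(length.out = n_tr)
  tr_in_cycle <- ((seq_len(n_tr) - 1L) %% config$n_tr_per_cycle) + 1L

  for (k in seq_len(n_tr)) {
    if (config$spoiling == "fresh") { mxy[] <- 0 + 0i; mz[] <- m0 }
    psi <- rf_phases[k]
    e <- exp(1i * psi)
    w <- mxy * Conj(e)
    a <- Re(w); b <- Im(w)
    mxy <- (a + 1i * (b * ca + mz * sa)) * e
    mz <- -b * sa + mz * ca
    if (encoded[k]) {
      phi <- bg$phi_rad
      if (!is.null(flow_phase_rad)) phi <- phi + flow_phase_rad[tr_in_cycle[k]]
      if (phi != 0) mxy <- mxy * exp(1i * phi)
    }
    mxy <- mxy * e2_te
    mz <- m0 + (mz - m0) * e1_te
    sig[k] <- mean(mxy) * Conj(e)
    mxy <- mxy * e2_rest
    mz <- m0 + (mz - m0) * e1_rest
    if (config$spoiling == "perfect") mxy[] <- 0 + 0i
    else if (config$spoiling == "gradient") mxy <- mxy * spoil_fac
  }

  out <- tibble::tibble(
    tr_global = seq_len(n_tr),
    cycle = ((seq_len(n_tr) - 1L) %/% config$n_tr_per_cycle) + 1L,
    tr_in_cycle = tr_in_cycle,
    time_ms = (tr_in_cycle - 1) * config$tr + config$te,
    encoded = encoded,
    in_window = tr_in_cycle > config$n_trigger_tr,
    signal = sig
  )
  attr(out, "config") <- config
  class(out) <- c("pc_trace", class(out))
  out
}
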