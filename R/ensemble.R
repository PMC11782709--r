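#' Isochromat ensemble for a single voxel
#'
#' The simulated voxel is discretized into `n_slice * n_spoiler` isochromats:
#' `n_slice` through-slice positions carrying the relative flip angles of the
#' slice profile, crossed with `n_spoiler` intravoxel positions
#' `u = k/n_spoiler` that control gradient-spoiler dephasing (the spoiler
#' advances each isochromat's transverse phase by `2*pi*u` per repetition).
#'
#' Magnetization is stored as a complex transverse component `mxy = Mx + i*My`
#' plus a real longitudinal component `mz`, one entry per isochromat;
#' [as_tibble()][tibble::as_tibble] exposes the conventional
#' `(Mx, My, Mz)` columns together with the isochromat coordinates.
#'
#' @param tissue A [tissue_properties()] object.
#' @param n_slice,n_spoiler Isochromat counts (>= 1). Defaults (33 and 256)
#'   are converged: doubling either changes simulated phase-contrast traces
#'   by well under 0.01 percent of venc.
#' @param pulse An [rf_pulse()] whose slice profile sets per-isochromat flip
#'   scales (default: windowed sinc, time-bandwidth 2).
#' @return A `pc_ensemble` object at thermal equilibrium (all magnetization
#'   at `(0, 0, M0)`).
#' @examples
#' ens <- equilibrium_ensemble(tissue_p2(), n_slice = 3, n_spoiler = 4)
#' tibble::as_tibble(ens)
#' @export
equilibrium_ensemble <- function(tissue, n_slice = 33, n_spoiler = 256,
                                 pulse = rf_pulse_sinc()) {
  stopifnot(inherits(tissue, "pc_tissue"))
  if (n_slice < 1 || n_spoiler < 1) abort("Isochromat counts must be >= 1.")
  n_slice <- as.integer(n_slice); n_spoiler <- as.integer(n_spoiler)
  fs <- make_slice_profile(pulse, n_slice)
  slab <- if (n_slice == 1) 0 else seq(-0.5, 0.5, length.out = n_slice)
  n <- n_slice * n_spoiler
  structure(list(
    mxy = complex(real = rep(0, n)),
    mz = rep(tissue$m0, n),
    slice_coord = rep(slab, each = n_spoiler),
    flip_scale = rep(fs, each = n_spoiler),
    spoiler_coord = rep((0:(n_spoiler - 1)) / n_spoiler, times = n_slice),
    tissue = tissue,
    nominal_flip = pulse$nominal_flip,
    n_slice = n_slice, n_spoiler = n_spoiler
  ), class = "pc_ensemble")
}

#' @export
print.pc_ensemble <- function(x, ...) {
  cat(sprintf("<pc_ensemble> %d isochromats (%d slice x %d spoiler), T1/T2 = %g/%g ms\n",
              length(x$mz), x$n_slice, x$n_spoiler, x$tissue$t1, x$tissue$t2))
  invisible(x)
}

#' @method as_tibble pc_ensemble
#' @export
as_tibble.pc_ensemble <- function(x, ...) {
  tibble::tibble(
    slice_coord = x$slice_coord,
    spoiler_coord = x$spoiler_coord,
    flip_scale = x$flip_scale,
    Mx = Re(x$mxy), My = Im(x$mxy), Mz = x$mz
  )
}

#' Bloch operators on an isochromat ensemble
#'
#' The elementary operators that [run_sequence()] chains once per repetition:
#'
#' * `apply_rf()` rotates each isochromat by `nominal_flip * flip_scale`
#'   about the transverse axis at azimuth `rf_phase`. The convention is a
#'   left-handed rotation such that a 90 degree flip at `rf_phase = 0` takes
#'   `+z` to `+y`; phase-contrast differences are invariant to this choice.
#' * `relax()` applies free relaxation for `dt` ms: `Mxy` decays by
#'   `exp(-dt/T2)`, `Mz` recovers toward `M0` with rate `1/T1`.
#' * `precess_phase()` rotates every transverse component by `phi` radians
#'   about z; this is how background (and flow-encoding) phase is injected.
#' * `spoil_gradient()` advances each isochromat's transverse phase by
#'   `2*pi*spoiler_coord`; transverse magnetization is not zeroed, so echo
#'   pathways survive and the increment accumulates across repetitions.
#' * `perfect_spoil()` (test-only idealization) zeroes all transverse
#'   magnetization, making the voxel memoryless.
#' * `read_signal()` returns the demodulated complex signal: the mean of
#'   `Mx + i*My` over isochromats times `exp(-i * receiver_phase)`. For
#'   RF-spoiled sequences the receiver phase must match the exciting RF
#'   phase.
#'
#' @param ens A `pc_ensemble`.
#' @param rf_phase,receiver_phase Azimuth of the RF/receiver phase in degrees.
#' @param dt Time interval in ms (>= 0).
#' @param phi Precession angle in radians.
#' @return The modified ensemble (`read_signal()` returns a complex scalar).
#' @name bloch-operators
NULL

#' @rdname bloch-operators
#' @export
apply_rf <- function(ens, rf_phase = 0) {
  alpha <- ens$nominal_flip * pi / 180 * ens$flip_scale
  st <- rot_rf(ens$mxy, ens$mz, alpha, rf_phase * pi / 180)
  ens$mxy <- st$mxy; ens$mz <- st$mz
  ens
}

# left-handed rotation by alpha about the transverse axis at azimuth psi_rad
rot_rf <- function(mxy, mz, alpha, psi_rad) {
  e <- exp(1i * psi_rad)
  w <- mxy * Conj(e)
  a <- Re(w); b <- Im(w)
  ca <- cos(alpha); sa <- sin(alpha)
  list(mxy = (a + 1i * (b * ca + mz * sa)) * e,
       mz = -b * sa + mz * ca)
}

#' @rdname bloch-operators
#' @export
relax <- function(ens, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt < 0)
    abort("`dt` must be a single non-negative time in ms.")
  e2 <- exp(-dt / ens$tissue$t2)
  e1 <- exp(-dt / ens$tissue$t1)
  ens$mxy <- ens$mxy * e2
  ens$mz <- ens$tissue$m0 + (ens$mz - ens$tissue$m0) * e1
  ens
}

#' @rdname bloch-operators
#' @export
precess_phase <- function(ens, phi) {
  ens$mxy <- ens$mxy * exp(1i * phi)
  ens
}

#' @rdname bloch-operators
#' @export
spoil_gradient <- function(ens) {
  ens$mxy <- ens$mxy * exp(2i * pi * ens$spoiler_coord)
  ens
}

#' @rdname bloch-operators
#' @export
perfect_spoil <- function(ens) {
  ens$mxy[] <- 0 + 0i
  ens
}

#' @rdname bloch-operators
#' @export
read_signal <- function(ens, receiver_phase = 0) {
  mean(ens$mxy) * exp(-1i * receiver_phase * pi / 180)
}
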