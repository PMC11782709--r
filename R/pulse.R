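#' RF excitation pulse specification
#'
#' An excitation pulse is described by its sampled (complex) envelope and the
#' prescribed on-resonance flip angle. Only the *shape* of the envelope
#' matters: the through-slice excitation profile is obtained from its Fourier
#' transform (small-tip-angle approximation) and normalized to the slab
#' center, so the absolute envelope scale and duration drop out.
#'
#' `rf_pulse_sinc()` builds the default windowed-sinc pulse (Hann window);
#' `rf_pulse_hard()` builds a single-sample hard pulse whose profile is flat.
#'
#' @param envelope Complex or numeric vector of envelope samples (non-empty).
#' @param nominal_flip Prescribed on-resonance flip angle in degrees,
#'   in (0, 90].
#' @param tbw Time-bandwidth product of the sinc pulse (default 2).
#' @param duration_ms Pulse duration in ms (default 1; informational only).
#' @param n_samples Number of envelope samples (default 256).
#' @return An `rf_pulse` object.
#' @examples
#' p <- rf_pulse_sinc(nominal_flip = 10)
#' make_slice_profile(p, n_slice = 5)
#' @export
rf_pulse <- function(envelope, nominal_flip) {
  if (length(envelope) == 0)
    abort("RF pulse envelope must be non-empty.", class = "pcsteady_invalid_pulse")
  if (!is.numeric(nominal_flip) || length(nominal_flip) != 1 ||
      nominal_flip <= 0 || nominal_flip > 90)
    abort("`nominal_flip` must be a single angle in (0, 90] degrees.")
  structure(
    list(envelope = as.complex(envelope), nominal_flip = nominal_flip,
         duration_ms = attr(envelope, "duration_ms") %||% 1),
    class = "rf_pulse")
}

#' @rdname rf_pulse
#' @export
rf_pulse_sinc <- function(nominal_flip = 10, tbw = 2, duration_ms = 1,
                          n_samples = 256) {
  t <- seq(-0.5, 0.5, length.out = n_samples)
  env <- ifelse(t == 0, 1, sin(pi * tbw * t) / (pi * tbw * t))
  env <- env * (0.5 + 0.5 * cos(2 * pi * t))  # Hann window
  attr(env, "duration_ms") <- duration_ms
  rf_pulse(env, nominal_flip)
}

#' @rdname rf_pulse
#' @export
rf_pulse_hard <- function(nominal_flip = 10) {
  rf_pulse(1 + 0i, nominal_flip)
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("<rf_pulse> %d samples, nominal flip %g deg\n",
              length(x$envelope), x$nominal_flip))
  invisible(x)
}

#' Through-slice excitation profile of an RF pulse
#'
#' Computes relative flip-angle scales across the excited slab from the
#' Fourier transform of the pulse envelope (small-tip-angle approximation).
#' The contiguous region around the profile peak where the magnitude stays
#' at or above `cutoff` times the peak defines the slab support; `n_slice`
#' positions are sampled symmetrically across it and the (signed, real)
#' profile values are normalized to 1 at the slab center.
#'
#' A single-sample (hard) pulse transforms to a flat profile, so all scales
#' are exactly 1.
#'
#' @param pulse An [rf_pulse()] object.
#' @param n_slice Number of through-slice sample positions (>= 1).
#' @param cutoff Support cutoff as a fraction of the profile peak
#'   magnitude (default 0.01).
#' @param n_fft Zero-padded transform length used to resolve the profile
#'   (default 4096).
#' @return Numeric vector of `n_slice` flip scales, peak value 1.
#' @export
make_slice_profile <- function(pulse, n_slice, cutoff = 0.01, n_fft = 4096) {
  if (!inherits(pulse, "rf_pulse"))
    abort("`pulse` must be an rf_pulse object.", class = "pcsteady_invalid_pulse")
  if (!is.numeric(n_slice) || length(n_slice) != 1 || n_slice < 1)
    abort("`n_slice` must be a count >= 1.")
  n_slice <- as.integer(n_slice)
  env <- pulse$envelope
  if (length(env) == 1) return(rep(1, n_slice))
  n_fft <- max(n_fft, 4L * length(env))
  m0 <- (length(env) - 1) / 2  # envelope time origin at its center
  x <- stats::fft(c(env, rep(0 + 0i, n_fft - length(env))))
  k <- 0:(n_fft - 1)
  k <- ifelse(k < n_fft / 2, k, k - n_fft)  # signed frequency bins
  prof <- x * exp(2i * pi * k * m0 / n_fft)  # remove the time-shift phase
  # center the zero-frequency bin
  prof <- c(prof[(n_fft %/% 2 + 1):n_fft], prof[1:(n_fft %/% 2)])
  # for a (conjugate-)symmetric envelope the centered profile is real
  prof <- Re(prof)
  pk <- which.max(abs(prof))
  mag <- abs(prof)
  lo <- pk
  while (lo > 1 && mag[lo - 1] >= cutoff * mag[pk]) lo <- lo - 1
  hi <- pk
  while (hi < n_fft && mag[hi + 1] >= cutoff * mag[pk]) hi <- hi + 1
  idx <- unique(round(seq(lo, hi, length.out = n_slice)))
  # guard: rounding can merge indices when n_slice is close to the support width
  if (length(idx) < n_slice)
    idx <- round(seq(lo, hi, length.out = n_slice))
  prof[idx] / prof[pk]
}
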