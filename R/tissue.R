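#' Tissue relaxation properties
#'
#' Bundles the longitudinal (T1) and transverse (T2) relaxation times of the
#' simulated tissue together with its equilibrium magnetization. Two gel
#' phantom compositions used throughout the package's experiments are exposed
#' as presets: a short-relaxation pineapple-juice/agar gel
#' (T1/T2 = 720/40 ms) and a long-relaxation tap-water/agar gel
#' (T1/T2 = 2000/160 ms).
#'
#' @param t1 Longitudinal relaxation time in ms. Must be positive.
#' @param t2 Transverse relaxation time in ms. Must be positive and not
#'   exceed `t1`.
#' @param m0 Equilibrium magnetization in arbitrary units (default 1).
#' @return A `pc_tissue` object (named list with `t1`, `t2`, `m0`).
#' @examples
#' tissue_properties(2000, 160)
#' tissue_p1()
#' @export
tissue_properties <- function(t1, t2, m0 = 1) {
  if (!is.numeric(t1) || length(t1) != 1 || !is.finite(t1) || t1 <= 0)
    abort("`t1` must be a single positive number (ms).")
  if (!is.numeric(t2) || length(t2) != 1 || !is.finite(t2) || t2 <= 0)
    abort("`t2` must be a single positive number (ms).")
  if (t2 > t1)
    abort("`t2` must not exceed `t1`.")
  if (!is.numeric(m0) || length(m0) != 1 || !is.finite(m0) || m0 <= 0)
    abort("`m0` must be a single positive number.")
  structure(list(t1 = t1, t2 = t2, m0 = m0), class = "pc_tissue")
}

#' @rdname tissue_properties
#' @export
tissue_p1 <- function() tissue_properties(720, 40)

#' @rdname tissue_properties
#' @export
tissue_p2 <- function() tissue_properties(2000, 160)

#' @export
print.pc_tissue <- function(x, ...) {
  cat(sprintf("<pc_tissue> T1 = %g ms, T2 = %g ms, M0 = %g\n",
              x$t1, x$t2, x$m0))
  invisible(x)
}
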