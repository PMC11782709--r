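#' Static-tissue mask for background-phase fitting
#'
#' A pixel is considered static tissue when (a) its time-averaged magnitude
#' is at least `mag_thresh` times the maximum time-averaged magnitude in the
#' image and (b) the temporal standard deviation of its velocity (phase
#' difference) series is at most `tsd_thresh` times the maximum temporal SD
#' in the image. The defaults (20 % minimum signal, 10 % maximum temporal
#' SD) mask out air and pulsatile flow. The temporal-SD criterion can
#' alternatively be evaluated on the magnitude series (`tsd_on =
#' "magnitude"`); the velocity series is the default because the polynomial
#' fit targets the phase and the mask must exclude pulsatile vessels.
#'
#' @param mag_stack Magnitude array `ny x nx x n_phases` (>= 2 phases).
#' @param velocity_stack Velocity (or phase) array of the same dimensions.
#' @param mag_thresh Magnitude threshold fraction (default 0.20).
#' @param tsd_thresh Temporal-SD threshold fraction (default 0.10).
#' @param tsd_on `"velocity"` (default) or `"magnitude"`.
#' @return A logical `ny x nx` matrix of class `pc_mask` with the
#'   thresholds attached as attributes.
#' @export
static_mask <- function(mag_stack, velocity_stack,
                        mag_thresh = 0.20, tsd_thresh = 0.10,
                        tsd_on = c("velocity", "magnitude")) {
  tsd_on <- match.arg(tsd_on)
  if (length(dim(mag_stack)) != 3 || dim(mag_stack)[3] < 2)
    abort("Need at least 2 cardiac phases to form a temporal SD.")
  stopifnot(all(dim(mag_stack) == dim(velocity_stack)))
  mag_avg <- apply(mag_stack, c(1, 2), mean)
  tsd_src <- if (tsd_on == "velocity") velocity_stack else mag_stack
  tsd <- apply(tsd_src, c(1, 2), sd)
  # floor guards the all-static case, where max(tsd) is pure roundoff
  tsd_cut <- max(tsd_thresh * max(tsd), 1e-9 * max(abs(tsd_src)))
  mask <- (mag_avg >= mag_thresh * max(mag_avg)) & (tsd <= tsd_cut)
  structure(mask, class = c("pc_mask", "matrix", "array"),
            mag_thresh = mag_thresh, tsd_thresh = tsd_thresh,
            tsd_on = tsd_on)
}

#' Fit the second-order background-phase polynomial to static tissue
#'
#' Ordinary least squares of the six-coefficient 2D polynomial (see
#' [polynomial_field()]) on the masked pixels of the time-averaged
#' phase-difference image, evaluable over the full field of view. An
#' optional magnitude-weighted fit is available via `weights`.
#'
#' The fitted object carries the residual summary; [tidy()] returns the
#' coefficient table and [glance()] the fit summary.
#'
#' @param phase_timeavg Time-averaged phase-difference image (`ny x nx`
#'   matrix), in percent of venc (or any consistent unit).
#' @param mask Logical `ny x nx` matrix selecting static pixels (>= 6
#'   pixels, non-degenerate geometry).
#' @param grid The [image_grid()] defining the normalized coordinates.
#' @param weights Optional `ny x nx` matrix of fit weights (e.g. the
#'   time-averaged magnitude).
#' @param units Units flag stored on the returned field.
#' @return A `pc_bgfit` object containing `field` (a [polynomial_field()]),
#'   the underlying `lm` fit, and the mask size.
#' @export
fit_background <- function(phase_timeavg, mask, grid, weights = NULL,
                           units = "pct_venc") {
  stopifnot(is.matrix(phase_timeavg), all(dim(mask) == dim(phase_timeavg)))
  idx <- which(mask)
  if (length(idx) < 6)
    abort("Need at least 6 masked pixels for a second-order fit.")
  xy <- grid_coords(grid)
  d <- tibble::tibble(
    z = phase_timeavg[idx],
    x = xy$x[idx], y = xy$y[idx])
  w <- if (!is.null(weights)) weights[idx] else NULL
  fit <- tryCatch(
    lm(z ~ x + y + I(x^2) + I(x * y) + I(y^2), data = d, weights = w),
    error = function(e) abort(paste0("Polynomial fit failed: ",
                                     conditionMessage(e))))
  cf <- coef(fit)
  if (anyNA(cf))
    abort("Degenerate masked-pixel geometry: polynomial design is rank-deficient.",
          class = "pcsteady_degenerate_fit")
  field <- polynomial_field(
    c00 = cf[["(Intercept)"]], c10 = cf[["x"]], c01 = cf[["y"]],
    c20 = cf[["I(x^2)"]], c11 = cf[["I(x * y)"]], c02 = cf[["I(y^2)"]],
    units = units)
  structure(list(field = field, fit = fit, n_pixels = length(idx),
                 grid = grid), class = "pc_bgfit")
}

#' @export
print.pc_bgfit <- function(x, ...) {
  cat(sprintf("<pc_bgfit> second-order background-phase fit on %d static pixels\n",
              x$n_pixels))
  print(round(x$field$coef, 4))
  invisible(x)
}

#' @method tidy pc_bgfit
#' @export
tidy.pc_bgfit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = names(x$field$coef),
                 estimate = unname(x$field$coef),
                 std.error = unname(s[, "Std. Error"]),
                 units = x$field$units)
}

#' @method glance pc_bgfit
#' @export
glance.pc_bgfit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(n_pixels = x$n_pixels, r.squared = s$r.squared,
                 sigma = s$sigma, df.residual = x$fit$df.residual)
}

#' Subtract a fitted background-phase field from a velocity stack
#'
#' Evaluates the field over the full grid, converts it to cm/s through
#' venc (when the field is in percent of venc), and subtracts it from every
#' cardiac phase.
#'
#' @param velocity_stack Velocity array `ny x nx x n_phases` in cm/s.
#' @param field A [polynomial_field()] (or a `pc_bgfit`).
#' @param grid The [image_grid()].
#' @param venc Velocity-encoding parameter in cm/s.
#' @return Corrected velocity array of the same dimensions.
#' @export
apply_correction <- function(velocity_stack, field, grid, venc) {
  if (inherits(field, "pc_bgfit")) field <- field$field
  bg <- eval_field_grid(field, grid)
  bg_cms <- if (field$units == "pct_venc") bg * venc / 100 else bg * venc / pi
  sweep(velocity_stack, c(1, 2), bg_cms, "-")
}

#' Flow rate over a region of interest
#'
#' Integrates velocity over the ROI: per cardiac phase,
#' `flow (mL/s) = sum over ROI pixels of v (cm/s) * pixel area (cm^2)`.
#'
#' @param velocity_stack Velocity array `ny x nx x n_phases` in cm/s.
#' @param roi_mask Logical `ny x nx` matrix (non-empty).
#' @param pixel_area_mm2 Pixel area in mm^2.
#' @return A `pc_flow` object: tibble of per-phase flow with attributes
#'   `mean_flow_mls` and `roi_area_mm2`; [glance()] summarizes it.
#' @examples
#' v <- array(1, c(2, 2, 3))  # uniform 1 cm/s
#' roi <- matrix(TRUE, 2, 2)
#' glance(flow_rate(v, roi, pixel_area_mm2 = 25))$mean_flow_mls  # 1 mL/s
#' @export
flow_rate <- function(velocity_stack, roi_mask, pixel_area_mm2) {
  if (!any(roi_mask)) abort("ROI is empty.")
  area_cm2 <- pixel_area_mm2 / 100
  np <- dim(velocity_stack)[3]
  per_phase <- vapply(seq_len(np), function(j) {
    v <- velocity_stack[, , j]
    sum(v[roi_mask]) * area_cm2
  }, numeric(1))
  out <- tibble::tibble(phase = seq_len(np), flow_mls = per_phase)
  attr(out, "mean_flow_mls") <- mean(per_phase)
  attr(out, "roi_area_mm2") <- sum(roi_mask) * pixel_area_mm2
  class(out) <- c("pc_flow", class(out))
  out
}

#' @method glance pc_flow
#' @export
glance.pc_flow <- function(x, ...) {
  tibble::tibble(mean_flow_mls = attr(x, "mean_flow_mls"),
                 roi_area_mm2 = attr(x, "roi_area_mm2"),
                 n_phases = nrow(x))
}

#' End-to-end static-tissue correction of a rendered stack
#'
#' Convenience pipeline: computes magnitude and velocity stacks, derives the
#' static mask, fits the background polynomial to the time-averaged velocity
#' image, and subtracts the extrapolated field.
#'
#' @param stack A `pc_stack`.
#' @inheritParams static_mask
#' @return A list with `mask`, `bgfit`, `velocity` (uncorrected, cm/s) and
#'   `corrected` (cm/s).
#' @export
correct_stack <- function(stack, mag_thresh = 0.20, tsd_thresh = 0.10,
                          tsd_on = "velocity") {
  vel <- velocity_map(stack)
  mag <- magnitude_map(stack)
  mask <- static_mask(mag, vel, mag_thresh, tsd_thresh, tsd_on)
  vel_avg <- apply(vel, c(1, 2), mean)
  bgfit <- fit_background(vel_avg * 100 / stack$venc, mask, stack$grid,
                          units = "pct_venc")
  corrected <- apply_correction(vel, bgfit, stack$grid, stack$venc)
  list(mask = mask, bgfit = bgfit, velocity = vel, corrected = corrected)
}
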