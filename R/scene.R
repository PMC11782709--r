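#' Synthetic phantom scenes
#'
#' Builds the 2D scenes rendered by [render_timeseries()]:
#'
#' * `"P1_offcenter"` / `"P2_offcenter"`: a homogeneous gel disc of 115 mm
#'   diameter shifted 120 mm in-plane from the isocenter, with the
#'   short-relaxation (T1/T2 = 720/40 ms) or long-relaxation
#'   (T1/T2 = 2000/160 ms) gel, under a smooth background-phase field that
#'   grows with distance from the isocenter.
#' * `"vessel_demo"`: a centered tissue disc containing a small vessel with
#'   a pulsatile through-plane velocity waveform, under a one-signed
#'   background-phase field — the end-to-end test bed for the static-tissue
#'   correction.
#'
#' The default background fields are plausible eddy-current/concomitant
#' stand-ins (roughly linear growth away from the isocenter, spanning about
#' ten percent of venc over the field of view); no coil or gradient physics
#' is simulated.
#'
#' @param preset One of `"P1_offcenter"`, `"P2_offcenter"`, `"vessel_demo"`.
#' @param grid An [image_grid()]; a compact default per preset.
#' @param bg_field A [polynomial_field()] overriding the preset default.
#' @param noise_sigma Complex-noise SD relative to M0 (default 0).
#' @param seed Integer seed used for any noisy render (default 1).
#' @param vessel_velocity Peak-systolic velocity in cm/s of the vessel
#'   waveform (vessel_demo only, default 40).
#' @param vessel_radius_mm Vessel radius in mm (default 6).
#' @return A `pc_scene` object: `grid`, integer `tissue_map` matrix (0 =
#'   air), `tissue_table`, `bg_field`, optional `vessel_mask` and
#'   `velocity_waveform` (a function of cycle fraction, cm/s), `noise_sigma`,
#'   `seed`.
#' @examples
#' sc <- make_scene("P2_offcenter", grid = image_grid(24, 12, c(370, 160)))
#' table(sc$tissue_map)
#' @export
make_scene <- function(preset = c("P1_offcenter", "P2_offcenter", "vessel_demo"),
                       grid = NULL, bg_field = NULL, noise_sigma = 0,
                       seed = 1L, vessel_velocity = 40, vessel_radius_mm = 6) {
  preset <- match.arg(preset)
  if (preset %in% c("P1_offcenter", "P2_offcenter")) {
    grid <- grid %||% image_grid(48, 24, c(370, 160))
    xy <- grid_coords(grid)
    r <- sqrt((xy$x_mm - 120)^2 + xy$y_mm^2)
    tissue_map <- matrix(as.integer(r <= 115 / 2), grid$ny, grid$nx)
    tissue <- if (preset == "P1_offcenter") tissue_p1() else tissue_p2()
    bg_field <- bg_field %||%
      polynomial_field(c00 = 0, c10 = 8, c01 = 3, c20 = 2, c02 = 1)
    scene <- list(grid = grid, tissue_map = tissue_map,
                  tissue_table = list(`1` = tissue),
                  bg_field = bg_field, vessel_mask = NULL,
                  velocity_waveform = NULL,
                  noise_sigma = noise_sigma, seed = as.integer(seed))
  } else {
    grid <- grid %||% image_grid(32, 32, 128)
    xy <- grid_coords(grid)
    r_tis <- sqrt(xy$x_mm^2 + xy$y_mm^2)
    tissue_map <- matrix(as.integer(r_tis <= 55), grid$ny, grid$nx)
    r_ves <- sqrt((xy$x_mm - 15)^2 + (xy$y_mm - 10)^2)
    vessel <- matrix(r_ves <= vessel_radius_mm, grid$ny, grid$nx)
    tissue_map[vessel] <- 2L
    # one-signed field, as over an off-isocenter limb
    bg_field <- bg_field %||%
      polynomial_field(c00 = 4, c10 = 3, c01 = 2, c20 = 1, c02 = 0.5)
    scene <- list(
      grid = grid, tissue_map = tissue_map,
      tissue_table = list(`1` = tissue_properties(1000, 40),  # muscle-like
                          `2` = tissue_properties(1800, 180)),  # blood-like
      bg_field = bg_field, vessel_mask = vessel,
      velocity_waveform = pulsatile_waveform(vessel_velocity),
      noise_sigma = noise_sigma, seed = as.integer(seed))
  }
  structure(scene, class = "pc_scene")
}

# simple one-peak systolic waveform with a low diastolic plateau, cm/s as a
# function of cycle fraction in [0, 1)
pulsatile_waveform <- function(peak = 40, baseline = 4) {
  force(peak); force(baseline)
  function(frac) {
    s <- exp(-((frac - 0.22) / 0.09)^2)
    baseline + (peak - baseline) * s
  }
}

#' @export
print.pc_scene <- function(x, ...) {
  cat(sprintf("<pc_scene> %d x %d px (%g x %g mm), %d tissue labels%s\n",
              x$grid$nx, x$grid$ny, x$grid$fov_mm[1], x$grid$fov_mm[2],
              length(x$tissue_table),
              if (!is.null(x$vessel_mask)) ", with vessel" else ""))
  invisible(x)
}
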