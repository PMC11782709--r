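#' Second-order 2D polynomial field
#'
#' `phi(x, y) = c00 + c10 x + c01 y + c20 x^2 + c11 x y + c02 y^2`, with
#' coordinates in normalized image units (pixel centers, origin at the
#' isocenter, x to the right, y downward, both normalized by half the field
#' of view). The same basis and coordinate convention are shared by the
#' phantom generator and the static-tissue correction, so a fitted field can
#' be compared to the generating one coefficient by coefficient.
#'
#' @param c00,c10,c01,c20,c11,c02 Polynomial coefficients. Values are in
#'   percent of venc unless `units` says otherwise.
#' @param units `"pct_venc"` (default) or `"rad"`.
#' @return A `poly_field` object.
#' @examples
#' f <- polynomial_field(c00 = 2, c10 = 5)
#' eval_field(f, x = c(-1, 0, 1), y = 0)
#' @export
polynomial_field <- function(c00 = 0, c10 = 0, c01 = 0,
                             c20 = 0, c11 = 0, c02 = 0,
                             units = c("pct_venc", "rad")) {
  units <- match.arg(units)
  structure(list(
    coef = c(c00 = c00, c10 = c10, c01 = c01, c20 = c20, c11 = c11, c02 = c02),
    units = units), class = "poly_field")
}

#' @rdname polynomial_field
#' @param field A `poly_field`.
#' @param x,y Normalized coordinates (recycled against each other).
#' @export
eval_field <- function(field, x, y) {
  stopifnot(inherits(field, "poly_field"))
  cf <- field$coef
  cf[["c00"]] + cf[["c10"]] * x + cf[["c01"]] * y +
    cf[["c20"]] * x^2 + cf[["c11"]] * x * y + cf[["c02"]] * y^2
}

# field evaluated on every pixel of a grid (matrix, row = y, col = x)
eval_field_grid <- function(field, grid) {
  xy <- grid_coords(grid)
  matrix(eval_field(field, xy$x, xy$y), nrow = grid$ny, ncol = grid$nx)
}

#' @export
print.poly_field <- function(x, ...) {
  cat("<poly_field> (", x$units, ")\n", sep = "")
  print(round(x$coef, 6))
  invisible(x)
}

#' @method tidy poly_field
#' @export
tidy.poly_field <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 units = x$units)
}

#' Image grid description
#'
#' @param nx,ny Image dimensions in pixels.
#' @param fov_mm Field of view `c(x, y)` in mm (scalar recycled).
#' @return A `pc_grid` object; pixel size is `fov_mm / c(nx, ny)`.
#' @export
image_grid <- function(nx, ny, fov_mm) {
  fov_mm <- rep(fov_mm, length.out = 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), fov_mm = fov_mm,
                 px_mm = fov_mm / c(nx, ny)), class = "pc_grid")
}

# normalized pixel-center coordinates for all pixels, column-major
# (matches matrix(vals, nrow = ny) filling): x right, y down, origin at
# isocenter, normalized by FOV/2
grid_coords <- function(grid) {
  x_mm <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$px_mm[1]
  y_mm <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$px_mm[2]
  list(x = rep(x_mm / (grid$fov_mm[1] / 2), each = grid$ny),
       y = rep(y_mm / (grid$fov_mm[2] / 2), times = grid$nx),
       x_mm = rep(x_mm, each = grid$ny),
       y_mm = rep(y_mm, times = grid$nx))
}
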