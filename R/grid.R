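#' Calibrated raster geometry
#'
#' A `grid_spec` maps integer pixel indices to physical coordinates in
#' micrometres. The field of view is centred on the origin and pixels are
#' addressed by their centres: column `i` (1-based) sits at
#' `x_i = -width/2 + (i - 1/2) * dx` with pixel pitch `dx = width/nx`, and
#' rows follow the same pattern in `y`.
#'
#' @param width,height Physical extent of the field of view in micrometres.
#' @param nx,ny Number of pixel columns and rows (each at least 2).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(15, 15, 255, 255)
#' pixel_pitch(g)   # 15/255 um in x and y
#' @export
grid_spec <- function(width, height, nx, ny) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L)
  if (!(width > 0 && height > 0)) {
    stop("grid_spec: width and height must be positive", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L) {
    stop("grid_spec: nx and ny must be integers >= 2", call. = FALSE)
  }
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 nx = nx, ny = ny),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g x %g um, %d x %d px (pitch %.6g x %.6g um)\n",
              x$width, x$height, x$nx, x$ny,
              x$width / x$nx, x$height / x$ny))
  invisible(x)
}

#' Pixel pitch of a grid
#'
#' @param grid A [grid_spec()].
#' @return Named numeric vector `c(dx, dy)` in micrometres per pixel.
#' @export
pixel_pitch <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  c(dx = grid$width / grid$nx, dy = grid$height / grid$ny)
}

#' Physical coordinates of pixel centres
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of column-centre x (or row-centre y) coordinates, um.
#' @export
x_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  dx <- grid$width / grid$nx
  -grid$width / 2 + (seq_len(grid$nx) - 0.5) * dx
}

#' @rdname x_coords
#' @export
y_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  dy <- grid$height / grid$ny
  -grid$height / 2 + (seq_len(grid$ny) - 0.5) * dy
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}
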