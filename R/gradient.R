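#' Gradient map container
#'
#' A 2D field of lateral phase-gradient values (rad/um), or their square
#' (rad^2/um^2), on the same raster as the source phase map. The final
#' column (x) or row (y) of a forward difference is padded with zero so maps
#' stay aligned with the source; jump detection never reports the padded
#' index.
#'
#' @param values Numeric matrix, shape `(ny, nx)`.
#' @param grid A [grid_spec()].
#' @param axis `"x"`, `"y"`, or `"xy"` (magnitude of both).
#' @param squared Logical: are these squared gradient values?
#' @return An object of class `gradient_map`.
#' @export
gradient_map <- function(values, grid, axis = "x", squared = FALSE) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"),
            axis %in% c("x", "y", "xy"), is.logical(squared))
  if (nrow(values) != grid$ny || ncol(values) != grid$nx) {
    stop("gradient_map: shape does not match grid", call. = FALSE)
  }
  if (squared && any(values < 0)) {
    stop("gradient_map: squared maps must be nonnegative", call. = FALSE)
  }
  structure(list(values = values, grid = grid, axis = axis,
                 squared = squared),
            class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  cat(sprintf("<gradient_map> axis %s%s, %d x %d px; range [%.4g, %.4g] %s\n",
              x$axis, if (x$squared) " (squared)" else "",
              x$grid$ny, x$grid$nx, min(x$values), max(x$values),
              if (x$squared) "rad^2/um^2" else "rad/um"))
  invisible(x)
}

#' Forward-difference lateral phase gradient
#'
#' `g[r, c] = (phi[r, c+1] - phi[r, c]) / dx` along x (and the analogous
#' column difference along y). The last column (or row) has no forward
#' neighbour and is padded with zero.
#'
#' @param map A [phase_map()].
#' @param axis `"x"` (across columns) or `"y"` (across rows).
#' @return A [gradient_map()] in rad/um.
#' @export
forward_diff_gradient <- function(map, axis = c("x", "y")) {
  stopifnot(inherits(map, "phase_map"))
  axis <- match.arg(axis)
  v <- map$values
  pitch <- pixel_pitch(map$grid)
  g <- matrix(0, nrow(v), ncol(v))
  if (axis == "x") {
    if (ncol(v) < 2L) stop("forward_diff_gradient: need nx >= 2", call. = FALSE)
    g[, seq_len(ncol(v) - 1L)] <-
      (v[, 2:ncol(v), drop = FALSE] - v[, seq_len(ncol(v) - 1L), drop = FALSE]) /
      pitch[["dx"]]
  } else {
    if (nrow(v) < 2L) stop("forward_diff_gradient: need ny >= 2", call. = FALSE)
    g[seq_len(nrow(v) - 1L), ] <-
      (v[2:nrow(v), , drop = FALSE] - v[seq_len(nrow(v) - 1L), , drop = FALSE]) /
      pitch[["dy"]]
  }
  gradient_map(g, map$grid, axis = axis, squared = FALSE)
}

#' Modulus-squared gradient ("shadow-artifact"-free edge map)
#'
#' Squaring the first derivative removes its sign reversal across an edge,
#' leaving an all-positive edge-strength map whose extrema sit at the same
#' pixels as the extrema of the gradient magnitude. With one input the
#' result is the squared lateral gradient; with two, the squared gradient
#' magnitude `gx^2 + gy^2`.
#'
#' @param gx A signed [gradient_map()].
#' @param gy Optional second signed [gradient_map()] on the same grid.
#' @return A squared [gradient_map()].
#' @export
modulus_squared <- function(gx, gy = NULL) {
  stopifnot(inherits(gx, "gradient_map"), !gx$squared)
  v <- gx$values^2
  axis <- gx$axis
  if (!is.null(gy)) {
    stopifnot(inherits(gy, "gradient_map"), !gy$squared)
    if (!grids_identical(gx$grid, gy$grid) ||
        !all(dim(gx$values) == dim(gy$values))) {
      stop("modulus_squared: inputs must share grid and shape", call. = FALSE)
    }
    v <- v + gy$values^2
    axis <- "xy"
  }
  gradient_map(v, gx$grid, axis = axis, squared = TRUE)
}

#' Describe a 1D sampling line on a raster
#'
#' Profiles are taken along a full row, a full column, or an oblique segment
#' sampled at the nearest pixel per unit step along its dominant axis (no
#' interpolation, so spikes stay localised to pixels).
#'
#' @param type `"row"`, `"column"`, or `"oblique"`.
#' @param index Row or column index (1-based) for `"row"`/`"column"`.
#' @param from,to Integer `(row, col)` endpoints for `"oblique"`.
#' @return An object of class `profile_line`.
#' @export
profile_line <- function(type = c("row", "column", "oblique"), index = NULL,
                         from = NULL, to = NULL) {
  type <- match.arg(type)
  if (type %in% c("row", "column")) {
    stopifnot(is.numeric(index), length(index) == 1L)
    index <- as.integer(index)
  } else {
    stopifnot(length(from) == 2L, length(to) == 2L)
    from <- as.integer(from); to <- as.integer(to)
  }
  structure(list(type = type, index = index, from = from, to = to),
            class = "profile_line")
}

#' Extract a 1D gradient profile along a line
#'
#' @param map A [gradient_map()] (or [phase_map()]).
#' @param line A [profile_line()].
#' @return An object of class `line_profile` with fields `samples`,
#'   `pixel_indices` (1-based positions along the traversal), `rows`, `cols`,
#'   `step_um` (physical step between consecutive samples), `geometry`,
#'   `axis`, `squared`, and `grid`.
#' @export
extract_profile <- function(map, line) {
  stopifnot(inherits(map, c("gradient_map", "phase_map")),
            inherits(line, "profile_line"))
  grid <- map$grid
  v <- map$values
  pitch <- pixel_pitch(grid)
  if (line$type == "row") {
    if (line$index < 1L || line$index > grid$ny) {
      stop(sprintf("extract_profile: row %d outside raster (1..%d)",
                   line$index, grid$ny), call. = FALSE)
    }
    rows <- rep(line$index, grid$nx); cols <- seq_len(grid$nx)
    step <- pitch[["dx"]]
  } else if (line$type == "column") {
    if (line$index < 1L || line$index > grid$nx) {
      stop(sprintf("extract_profile: column %d outside raster (1..%d)",
                   line$index, grid$nx), call. = FALSE)
    }
    rows <- seq_len(grid$ny); cols <- rep(line$index, grid$ny)
    step <- pitch[["dy"]]
  } else {
    fr <- line$from; to <- line$to
    if (any(c(fr[1], to[1]) < 1L) || any(c(fr[1], to[1]) > grid$ny) ||
        any(c(fr[2], to[2]) < 1L) || any(c(fr[2], to[2]) > grid$nx)) {
      stop("extract_profile: oblique endpoints outside raster", call. = FALSE)
    }
    n <- max(abs(to - fr)) + 1L
    rows <- as.integer(round(seq(fr[1], to[1], length.out = n)))
    cols <- as.integer(round(seq(fr[2], to[2], length.out = n)))
    # physical step per unit advance along the dominant axis
    dom <- if (abs(to[1] - fr[1]) >= abs(to[2] - fr[2])) "dy" else "dx"
    step <- pitch[[dom]]
  }
  samples <- v[cbind(rows, cols)]
  structure(list(samples = samples,
                 pixel_indices = seq_along(samples),
                 rows = rows, cols = cols,
                 step_um = unname(step),
                 geometry = line,
                 axis = if (inherits(map, "gradient_map")) map$axis else NA,
                 squared = if (inherits(map, "gradient_map")) map$squared else FALSE,
                 grid = grid),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %s%s, %d samples, step %.5g um\n",
              x$geometry$type,
              if (x$geometry$type %in% c("row", "column"))
                sprintf(" %d", x$geometry$index) else "",
              length(x$samples), x$step_um))
  invisible(x)
}
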