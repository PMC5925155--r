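#' Spherical component of a cell phantom
#'
#' One homogeneous sphere in a multi-medium refractive-index model: the cell
#' body, or an organelle (e.g. the nucleus) nested inside it.
#'
#' @param center Numeric length-3, sphere centre `(x, y, z)` in micrometres.
#' @param radius Sphere radius in micrometres (> 0).
#' @param index Refractive index of the sphere material (> 1).
#' @param name Optional label used in validation messages.
#' @return An object of class `sphere_component`.
#' @export
sphere_component <- function(center, radius, index, name = "sphere") {
  center <- as.numeric(center)
  if (length(center) == 2L) center <- c(center, 0)
  stopifnot(length(center) == 3L, is.finite(center))
  if (!(is.numeric(radius) && length(radius) == 1L && radius > 0)) {
    stop("sphere_component: radius must be a positive number", call. = FALSE)
  }
  if (!(is.numeric(index) && length(index) == 1L && index > 1)) {
    stop("sphere_component: refractive index must be > 1", call. = FALSE)
  }
  structure(list(center = center, radius = as.numeric(radius),
                 index = as.numeric(index), name = as.character(name)),
            class = "sphere_component")
}

#' Nested-sphere cell phantom
#'
#' A transparent cell model: a large sphere (the cell body, index `n1`)
#' immersed in a medium of index `n_m`, optionally containing nested spheres
#' (e.g. a nucleus of index `n2`). A plane wave of wavelength `wavelength`
#' travelling along z accumulates phase proportional to the chord length it
#' traverses in each component, so each inclusion must project entirely
#' inside the body's disc for the additive chord decomposition to hold.
#'
#' @param body A [sphere_component()] for the cell body.
#' @param inclusions List of [sphere_component()]s nested inside the body
#'   (may be empty). Their index contrast is taken against the body.
#' @param medium_index Refractive index of the surrounding medium (> 1).
#' @param wavelength Illumination wavelength in micrometres.
#' @return An object of class `cell_model`.
#' @examples
#' m <- nucleated_cell_model()
#' phase_at(m, 0, 0)   # 4.766 rad at the body centre
#' @export
cell_model <- function(body, inclusions = list(), medium_index = 1.33,
                       wavelength = 0.6328) {
  stopifnot(inherits(body, "sphere_component"))
  if (inherits(inclusions, "sphere_component")) inclusions <- list(inclusions)
  stopifnot(is.list(inclusions))
  if (!(is.numeric(medium_index) && length(medium_index) == 1L && medium_index > 1)) {
    stop("cell_model: medium_index must be > 1", call. = FALSE)
  }
  if (!(is.numeric(wavelength) && length(wavelength) == 1L && wavelength > 0)) {
    stop("cell_model: wavelength must be positive (um)", call. = FALSE)
  }
  for (inc in inclusions) {
    stopifnot(inherits(inc, "sphere_component"))
    d_xy <- sqrt(sum((inc$center[1:2] - body$center[1:2])^2))
    if (d_xy + inc$radius > body$radius + 1e-12) {
      stop(sprintf(
        "cell_model: inclusion '%s' is not nested inside the body's projected disc (|c_incl - c_body| + R_incl = %.4g > R_body = %.4g)",
        inc$name, d_xy + inc$radius, body$radius), call. = FALSE)
    }
  }
  structure(list(body = body, inclusions = inclusions,
                 medium_index = as.numeric(medium_index),
                 wavelength = as.numeric(wavelength)),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> lambda = %g um, n_m = %g\n", x$wavelength,
              x$medium_index))
  cat(sprintf("  body: R = %g um, n = %g, centre (%g, %g, %g)\n",
              x$body$radius, x$body$index, x$body$center[1],
              x$body$center[2], x$body$center[3]))
  for (inc in x$inclusions) {
    cat(sprintf("  %s: R = %g um, n = %g, centre (%g, %g, %g)\n",
                inc$name, inc$radius, inc$index, inc$center[1],
                inc$center[2], inc$center[3]))
  }
  invisible(x)
}

#' Reference nucleated-cell phantom
#'
#' The eccentric-sphere phantom used throughout the package's examples and
#' tests: a 6 um-radius cell body (n = 1.37) centred at the origin with a
#' 2.5 um-radius nucleus (n = 1.45) centred at (3, 0, 0), in medium
#' n_m = 1.33, illuminated at 632.8 nm. Physiologically plausible values for
#' a nucleated mammalian cell.
#'
#' @return A [cell_model()].
#' @export
nucleated_cell_model <- function() {
  cell_model(
    body = sphere_component(c(0, 0, 0), 6.0, 1.37, name = "body"),
    inclusions = list(sphere_component(c(3, 0, 0), 2.5, 1.45,
                                       name = "nucleus")),
    medium_index = 1.33,
    wavelength = 0.6328
  )
}

#' @rdname nucleated_cell_model
#' @export
reference_grid <- function() grid_spec(15, 15, 255, 255)
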