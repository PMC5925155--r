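#' Quantitative phase map container
#'
#' A 2D field of phase shifts in radians bound to a calibrated grid. Row `r`,
#' column `c` of `values` corresponds to physical coordinates
#' `(x_coords(grid)[c], y_coords(grid)[r])`.
#'
#' @param values Numeric matrix, shape `(ny, nx)`, radians.
#' @param grid A [grid_spec()].
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(values, grid) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"))
  if (nrow(values) != grid$ny || ncol(values) != grid$nx) {
    stop(sprintf("phase_map: values are %d x %d but grid is %d x %d (ny x nx)",
                 nrow(values), ncol(values), grid$ny, grid$nx), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("phase_map: values must be finite", call. = FALSE)
  }
  structure(list(values = values, grid = grid), class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px on %g x %g um; range [%.4g, %.4g] rad\n",
              x$grid$ny, x$grid$nx, x$grid$width, x$grid$height,
              min(x$values), max(x$values)))
  invisible(x)
}

chord_length <- function(R, d2) {
  # axial path length through a sphere at squared in-plane offset d2;
  # exactly 0 on and outside the rim
  ifelse(d2 < R^2, 2 * sqrt(pmax(R^2 - d2, 0)), 0)
}

#' Phase shift of a cell phantom at a point
#'
#' Evaluates the accumulated phase `(2*pi/lambda) * sum_k dn_k * chord_k(x, y)`
#' of a plane wave crossing the phantom at in-plane position `(x, y)`:
#' the body contributes with contrast `n1 - n_m` over its chord
#' `2*sqrt(R1^2 - x^2 - y^2)`, and each inclusion with contrast against the
#' body (`n2 - n1`) over its own chord. The result is exactly zero outside
#' the body's projected disc.
#'
#' @param model A [cell_model()].
#' @param x,y Coordinates in micrometres (vectorised, recycled).
#' @return Phase shift in radians.
#' @export
phase_at <- function(model, x, y) {
  stopifnot(inherits(model, "cell_model"))
  k <- 2 * pi / model$wavelength
  b <- model$body
  d2 <- (x - b$center[1])^2 + (y - b$center[2])^2
  phi <- k * (b$index - model$medium_index) * chord_length(b$radius, d2)
  for (inc in model$inclusions) {
    d2i <- (x - inc$center[1])^2 + (y - inc$center[2])^2
    phi <- phi + k * (inc$index - b$index) * chord_length(inc$radius, d2i)
  }
  phi
}

#' Render a phantom's phase map on a grid
#'
#' Evaluates [phase_at()] at every pixel centre. No supersampling or
#' anti-aliasing is applied: the chord model is sampled exactly at pixel
#' centres, so boundary pixels take the value of their centre coordinate.
#'
#' @param model A [cell_model()].
#' @param grid A [grid_spec()].
#' @return A [phase_map()].
#' @export
render_phase_map <- function(model, grid) {
  stopifnot(inherits(model, "cell_model"), inherits(grid, "grid_spec"))
  xs <- x_coords(grid)
  ys <- y_coords(grid)
  vals <- outer(ys, xs, function(y, x) phase_at(model, x, y))
  phase_map(vals, grid)
}

#' Closed-form lateral phase derivative of a phantom
#'
#' Analytic `d(phase)/dx` of the nested-sphere model at `(x, y)`: each
#' component with index contrast `dn` contributes
#' `(4*pi/lambda) * dn * (-(x - xc) / sqrt(R^2 - (x - xc)^2 - (y - yc)^2))`
#' wherever its radicand is positive, and nothing outside. The expression is
#' singular on a component rim (radicand zero); evaluation there is refused
#' because the one-sided derivative diverges.
#'
#' @param model A [cell_model()].
#' @param x,y Coordinates in micrometres (vectorised, recycled).
#' @return Lateral phase derivative in rad/um.
#' @export
analytic_gradient_profile <- function(model, x, y) {
  stopifnot(inherits(model, "cell_model"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  k4 <- 4 * pi / model$wavelength
  comps <- c(list(list(sph = model$body,
                       dn = model$body$index - model$medium_index)),
             lapply(model$inclusions, function(inc)
               list(sph = inc, dn = inc$index - model$body$index)))
  g <- numeric(n)
  for (cm in comps) {
    s <- cm$sph
    rad <- s$radius^2 - (x - s$center[1])^2 - (y - s$center[2])^2
    at_rim <- abs(rad) < 1e-12
    if (any(at_rim)) {
      stop(sprintf(
        "analytic_gradient_profile: undefined at boundary of '%s' (radicand = 0 at x = %g)",
        s$name, x[which(at_rim)[1]]), call. = FALSE)
    }
    inside <- rad > 0
    g[inside] <- g[inside] + k4 * cm$dn *
      (-(x[inside] - s$center[1]) / sqrt(rad[inside]))
  }
  g
}

#' Noise settings for SNR-controlled Gaussian corruption
#'
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @param seed Integer seed fixing the noise realisation exactly.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db, seed = 1L) {
  stopifnot(is.numeric(snr_db), length(snr_db) == 1L, is.finite(snr_db))
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  structure(list(snr_db = as.numeric(snr_db), seed = seed),
            class = "noise_spec")
}

#' Add white Gaussian noise at a fixed SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise to a phase map. The noise variance is
#' `P_signal / 10^(snr_db/10)` where `P_signal` is the mean of the squared
#' phase values over the full image (zero background included) — the usual
#' white-Gaussian-SNR convention. The realisation is a pure function of
#' `noise$seed`: the caller's RNG state is saved and restored.
#'
#' @param map A [phase_map()] with nonzero signal power.
#' @param noise A [noise_spec()].
#' @return A new [phase_map()] with noise added.
#' @export
add_gaussian_noise <- function(map, noise) {
  stopifnot(inherits(map, "phase_map"), inherits(noise, "noise_spec"))
  p_signal <- mean(map$values^2)
  if (p_signal == 0) {
    stop("add_gaussian_noise: all-zero map has no signal power; SNR undefined",
         call. = FALSE)
  }
  sigma <- sqrt(p_signal / 10^(noise$snr_db / 10))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(noise$seed)
  eps <- matrix(stats::rnorm(length(map$values), 0, sigma),
                nrow(map$values), ncol(map$values))
  phase_map(map$values + eps, map$grid)
}
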