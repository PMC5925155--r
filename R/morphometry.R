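#' Simulate a phantom's phase map
#'
#' Renders the phase map of a nested-sphere phantom and optionally corrupts
#' it with SNR-controlled Gaussian noise.
#'
#' @param model A [cell_model()]; default the reference nucleated phantom.
#' @param grid A [grid_spec()]; default 255 x 255 px over 15 x 15 um.
#' @param noise Optional [noise_spec()].
#' @return A [phase_map()].
#' @export
simulate_phase <- function(model = nucleated_cell_model(),
                           grid = reference_grid(), noise = NULL) {
  map <- render_phase_map(model, grid)
  if (!is.null(noise)) map <- add_gaussian_noise(map, noise)
  map
}

#' Locate the phase centre of a map
#'
#' The pixel of maximum phase, optionally after a 3x3 median filter to
#' suppress single-pixel noise; ties resolve to the lowest row-major index.
#'
#' @param map A [phase_map()].
#' @param median3 Apply a 3x3 median filter before taking the argmax?
#' @return Integer `c(row, col)`.
#' @export
phase_center <- function(map, median3 = FALSE) {
  stopifnot(inherits(map, "phase_map"))
  v <- map$values
  if (median3) {
    ny <- nrow(v); nx <- ncol(v)
    f <- v
    for (r in 2:(ny - 1L)) for (cc in 2:(nx - 1L)) {
      f[r, cc] <- stats::median(v[(r - 1L):(r + 1L), (cc - 1L):(cc + 1L)])
    }
    v <- f
  }
  k <- which.max(t(v))         # row-major scan, lowest index on ties
  cc <- ((k - 1L) %% ncol(v)) + 1L
  r <- ((k - 1L) %/% ncol(v)) + 1L
  c(row = r, col = cc)
}

analyze_direction <- function(gx, gy, line, threshold_fraction) {
  # gradient along the traversal axis, so boundary crossings give +/- pairs
  gmap <- switch(line$type,
                 row = gx,
                 column = gy,
                 oblique = {
                   dom_y <- abs(line$to[1] - line$from[1]) >=
                     abs(line$to[2] - line$from[2])
                   if (dom_y) gy else gx
                 })
  prof <- extract_profile(gmap, line)
  sq <- extract_profile(modulus_squared(gmap), line)
  jumps <- detect_jumps(prof, threshold_fraction)
  pairs <- NULL; report <- NULL; pair_error <- NULL
  if (nrow(jumps) > 0L) {
    pairs <- tryCatch(pair_jumps(jumps), error = function(e) NULL)
    if (is.null(pairs)) {
      pair_error <- "jump signs do not form a nested (+..-) pattern"
    } else {
      report <- build_distance_report(pairs, gmap$grid,
                                      step_um = prof$step_um)
    }
  }
  list(line = line, profile = prof, squared_profile = sq, jumps = jumps,
       pairs = pairs, report = report, pair_error = pair_error)
}

#' Measure cell morphology from a phase map
#'
#' The core analysis: forward-difference gradients of the phase map, 1D
#' profiles along the requested lines (gradient taken along each line's
#' traversal axis), relative-threshold jump detection, nested pairing of the
#' jumps, and conversion of pixel separations to physical sizes. Pair 1 of
#' each direction estimates the outer (cell body) diameter along that line;
#' pair 2, where present, the nucleus.
#'
#' @param map A [phase_map()].
#' @param directions A named list of [profile_line()]s. The default takes
#'   the row and the column through the phase centre (the argmax of the
#'   map), the quick two-orthogonal-profiles reading used on instrument
#'   images.
#' @param threshold_fraction Jump-detection threshold, in (0, 1).
#' @param truth Optional list (named like `directions`) of set values in um,
#'   one per report row, for [diameter_error_stats()].
#' @return An object of class `cell_morphometry`; see
#'   [print.cell_morphometry()], [coef.cell_morphometry()],
#'   [plot.cell_morphometry()].
#' @examples
#' m <- measure_cell(simulate_phase(),
#'                   directions = list(A = profile_line("row", 128),
#'                                     B = profile_line("column", 128)))
#' coef(m)
#' @export
measure_cell <- function(map,
                         directions = NULL,
                         threshold_fraction = 0.3,
                         truth = NULL) {
  stopifnot(inherits(map, "phase_map"))
  if (is.null(directions)) {
    ctr <- phase_center(map)
    directions <- list(horizontal = profile_line("row", ctr[["row"]]),
                       vertical = profile_line("column", ctr[["col"]]))
  }
  if (is.null(names(directions))) {
    names(directions) <- paste0("line", seq_along(directions))
  }
  gx <- forward_diff_gradient(map, "x")
  gy <- forward_diff_gradient(map, "y")
  res <- lapply(directions, analyze_direction, gx = gx, gy = gy,
                threshold_fraction = threshold_fraction)
  stats <- NULL
  if (!is.null(truth)) {
    stats <- list()
    for (nm in names(truth)) {
      if (!is.null(res[[nm]]$report)) {
        stats[[nm]] <- diameter_error_stats(res[[nm]]$report, truth[[nm]])
      }
    }
  }
  structure(list(phase = map, gx = gx, gy = gy,
                 squared = modulus_squared(gx, gy),
                 directions = res, error_stats = stats,
                 threshold_fraction = threshold_fraction),
            class = "cell_morphometry")
}

#' @describeIn measure_cell Estimated pair separations (um) as a named
#'   vector, e.g. `horizontal.1` for the outer pair of the horizontal line.
#' @param object,... S3 method arguments.
#' @export
coef.cell_morphometry <- function(object, ...) {
  out <- numeric(0)
  for (nm in names(object$directions)) {
    rep <- object$directions[[nm]]$report
    if (is.null(rep)) next
    d <- rep[rep$type == "diameter", ]
    v <- d$microns
    names(v) <- paste0(nm, ".", seq_along(v))
    out <- c(out, v)
  }
  out
}

#' Printing and plotting morphometry results
#'
#' @param x A `cell_morphometry` object.
#' @param ... Further arguments (ignored).
#' @export
print.cell_morphometry <- function(x, ...) {
  cat(sprintf("<cell_morphometry> %d x %d px map, threshold %.2g\n",
              x$phase$grid$ny, x$phase$grid$nx, x$threshold_fraction))
  for (nm in names(x$directions)) {
    d <- x$directions[[nm]]
    cat(sprintf("  %s (%s %s): %d jump(s)", nm, d$line$type,
                if (d$line$type == "oblique") "" else d$line$index,
                nrow(d$jumps)))
    if (!is.null(d$report)) {
      diam <- d$report[d$report$type == "diameter", ]
      cat(sprintf("; separations %s um",
                  paste(sprintf("%.3f", diam$microns), collapse = ", ")))
    } else if (!is.null(d$pair_error)) {
      cat(sprintf("; %s", d$pair_error))
    }
    cat("\n")
  }
  if (!is.null(x$error_stats)) {
    for (nm in names(x$error_stats)) {
      s <- x$error_stats[[nm]]
      cat(sprintf("  %s errors: max diameter %.3f um, mean relative %.2g%%\n",
                  nm, s$max_diameter_error_um, s$mean_relative_error_pct))
    }
  }
  invisible(x)
}

#' @rdname print.cell_morphometry
#' @param object A `cell_morphometry` object.
#' @export
summary.cell_morphometry <- function(object, ...) {
  print(object)
  for (nm in names(object$directions)) {
    rep <- object$directions[[nm]]$report
    if (!is.null(rep)) {
      cat(sprintf("-- %s --\n", nm)); print(rep)
    }
  }
  invisible(object)
}

#' @rdname print.cell_morphometry
#' @param which `"phase"` for the phase image, or the name of a direction
#'   for its gradient profile with jump markers.
#' @export
plot.cell_morphometry <- function(x, which = "phase", ...) {
  if (identical(which, "phase")) {
    graphics::image(x_coords(x$phase$grid), y_coords(x$phase$grid),
                    t(x$phase$values),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (um)", ylab = "y (um)",
                    main = "phase (rad)", useRaster = TRUE)
  } else {
    d <- x$directions[[which]]
    if (is.null(d)) stop("plot.cell_morphometry: unknown direction", call. = FALSE)
    graphics::plot(d$profile$pixel_indices, d$profile$samples, type = "l",
                   xlab = "pixel", ylab = "phase gradient (rad/um)",
                   main = which, ...)
    if (nrow(d$jumps) > 0L) {
      graphics::points(d$jumps$index,
                       d$profile$samples[d$jumps$index],
                       col = "red", pch = 19)
    }
  }
  invisible(x)
}
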