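#' Detect jump points on a gradient profile
#'
#' A ray crossing a refractive-index boundary produces a spike ("jump") in
#' the forward-difference phase gradient. Jumps are located with a relative
#' threshold: samples with `|value| >= threshold_fraction * max |value|` are
#' grouped into contiguous runs of one sign, and each run contributes a
#' single jump at its maximum-magnitude index (ties resolved to the lowest
#' index). The final profile index — the zero-padded terminal sample of a
#' forward difference — is excluded from candidacy.
#'
#' A modulus-squared profile is thresholded in equivalent magnitude terms
#' (`g^2 >= (threshold_fraction * max|g|)^2`), so squaring — a monotone
#' transform of the magnitude — never moves a jump: signed and squared
#' profiles yield identical extremum indices. Signs are read from the
#' companion signed profile (`signed`) at the same positions, and reported
#' magnitudes are square roots.
#'
#' A run covering every candidate index (a constant suprathreshold profile)
#' contains no localised spike and yields no jumps.
#'
#' @param profile A [line_profile()].
#' @param threshold_fraction Relative threshold in (0, 1); default 0.3.
#' @param signed Companion signed [line_profile()] with identical geometry;
#'   required when `profile` holds squared values.
#' @return A data.frame of class `jump_set` with columns `index` (1-based
#'   position along the profile), `sign` (+1/-1), and `magnitude`
#'   (|gradient| in rad/um at the extremum), sorted by `index`. An all-zero
#'   profile yields zero rows.
#' @export
detect_jumps <- function(profile, threshold_fraction = 0.3, signed = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  if (!(is.numeric(threshold_fraction) && length(threshold_fraction) == 1L &&
        threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("detect_jumps: threshold_fraction must lie in (0, 1)", call. = FALSE)
  }
  s <- profile$samples
  n <- length(s)
  if (n == 0L) stop("detect_jumps: empty profile", call. = FALSE)
  if (profile$squared) {
    if (is.null(signed)) {
      stop("detect_jumps: a squared profile needs the companion signed profile for jump signs",
           call. = FALSE)
    }
    stopifnot(inherits(signed, "line_profile"),
              length(signed$samples) == n)
    score <- s                       # already nonnegative
    sgn <- sign(signed$samples)
    mag_of <- function(i) sqrt(s[i])
  } else {
    score <- abs(s)
    sgn <- sign(s)
    mag_of <- function(i) abs(s[i])
  }
  empty <- data.frame(index = integer(0), sign = integer(0),
                      magnitude = numeric(0))
  mx <- max(score)
  if (mx == 0) return(structure(empty, class = c("jump_set", "data.frame")))
  # threshold on gradient magnitude; on squared values the equivalent cut
  # is the squared fraction, keeping detection invariant under squaring
  f <- if (profile$squared) threshold_fraction^2 else threshold_fraction
  sup <- score >= f * mx
  sup[n] <- FALSE                    # padded terminal index
  idx <- integer(0); sg <- integer(0); mg <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (sup[i]) {
      j <- i
      while (j < n && sup[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
      seg <- i:j
      k <- seg[which.max(score[seg])]
      idx <- c(idx, k); sg <- c(sg, as.integer(sgn[k])); mg <- c(mg, mag_of(k))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(idx) == 1L && all(sup[seq_len(n - 1L)])) {
    # one run spanning the whole profile: no localised spike
    return(structure(empty, class = c("jump_set", "data.frame")))
  }
  out <- data.frame(index = idx, sign = sg, magnitude = mg)
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("jump_set", "data.frame"),
            step_um = profile$step_um)
}

#' Pair jump points as nested boundaries
#'
#' Crossing a phase "hill" left-to-right, each medium boundary is met twice,
#' so jumps arrive as nested (+, -) pairs: `2m` jumps whose first `m` signs
#' are +1 and last `m` are -1. Pair `k` joins the k-th jump from the left
#' with the k-th from the right; pair 1 is the outermost boundary (cell
#' body), pair 2 the next nesting level (nucleus), and so on.
#'
#' @param jumps A `jump_set` from [detect_jumps()], or a data.frame with
#'   columns `index` and `sign`.
#' @return A data.frame of class `jump_pairs` with columns `level`,
#'   `left_index`, `right_index`.
#' @export
pair_jumps <- function(jumps) {
  stopifnot(is.data.frame(jumps), all(c("index", "sign") %in% names(jumps)))
  n <- nrow(jumps)
  if (n == 0L || n %% 2L != 0L) {
    stop(sprintf(
      "pair_jumps: need an even, positive jump count, got %d (signs: %s)",
      n, paste(jumps$sign, collapse = ", ")), call. = FALSE)
  }
  jumps <- jumps[order(jumps$index), , drop = FALSE]
  m <- n %/% 2L
  if (!all(jumps$sign[seq_len(m)] == 1L) ||
      !all(jumps$sign[m + seq_len(m)] == -1L)) {
    stop(sprintf(
      "pair_jumps: sign pattern (%s) is not the nested-hill pattern (+ x%d, - x%d); media are not strictly nested",
      paste(ifelse(jumps$sign > 0, "+", "-"), collapse = ""), m, m),
      call. = FALSE)
  }
  out <- data.frame(level = seq_len(m),
                    left_index = jumps$index[seq_len(m)],
                    right_index = rev(jumps$index[m + seq_len(m)]))
  structure(out, class = c("jump_pairs", "data.frame"),
            step_um = attr(jumps, "step_um"))
}

#' Convert a pixel-index pair to a physical separation
#'
#' The physical distance between two pixels on the same line is exactly
#' `(j - i)` times the pixel pitch. On the reference 255-pixel / 15-um grid
#' the pair (28, 229) maps to `201 * 15/255 = 11.823` um.
#'
#' @param i,j Pixel indices with `i <= j`, inside the grid along `axis`.
#' @param grid A [grid_spec()].
#' @param axis `"x"` (columns) or `"y"` (rows).
#' @return Separation in micrometres.
#' @export
pixel_pair_distance <- function(i, j, grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "grid_spec"), is.numeric(i), is.numeric(j))
  n <- if (axis == "x") grid$nx else grid$ny
  # indices are accepted on either 0- or 1-based conventions; only the
  # difference enters, but both must address a pixel of the line
  if (any(c(i, j) < 0) || any(c(i, j) > n)) {
    stop(sprintf("pixel_pair_distance: index outside 0..%d", n), call. = FALSE)
  }
  if (any(j < i)) stop("pixel_pair_distance: need i <= j", call. = FALSE)
  pitch <- pixel_pitch(grid)[[if (axis == "x") "dx" else "dy"]]
  (j - i) * pitch
}

#' Tabulate physical separations of nested jump pairs
#'
#' For each pair the report carries its pixel separation and the exact
#' physical separation (pixels times pitch); for each adjacent nesting level
#' it also carries the left-to-left and right-to-right gaps, which measure
#' how far the inner boundary sits from the outer one on each side.
#'
#' @param pairs A `jump_pairs` object from [pair_jumps()].
#' @param grid A [grid_spec()].
#' @param step_um Physical step between profile samples in um; defaults to
#'   the step recorded on `pairs`, falling back to the grid's x pitch.
#' @return A data.frame of class `distance_report` with columns `label`,
#'   `type` ("diameter" or "gap"), `left_px`, `right_px`, `pixels`,
#'   `microns`.
#' @export
build_distance_report <- function(pairs, grid, step_um = NULL) {
  stopifnot(inherits(pairs, "jump_pairs"), nrow(pairs) >= 1L,
            inherits(grid, "grid_spec"))
  if (is.null(step_um)) step_um <- attr(pairs, "step_um")
  if (is.null(step_um)) step_um <- pixel_pitch(grid)[["dx"]]
  rows <- list()
  m <- nrow(pairs)
  for (k in seq_len(m)) {
    px <- pairs$right_index[k] - pairs$left_index[k]
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%d-%d", k, k), type = "diameter",
      left_px = pairs$left_index[k], right_px = pairs$right_index[k],
      pixels = px, microns = px * step_um)
  }
  if (m >= 2L) for (k in seq_len(m - 1L)) {
    lg <- pairs$left_index[k + 1L] - pairs$left_index[k]
    rg <- pairs$right_index[k] - pairs$right_index[k + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%d-%d (left)", k, k + 1L), type = "gap",
      left_px = pairs$left_index[k], right_px = pairs$left_index[k + 1L],
      pixels = lg, microns = lg * step_um)
    rows[[length(rows) + 1L]] <- data.frame(
      label = sprintf("%d-%d (right)", k, k + 1L), type = "gap",
      left_px = pairs$right_index[k + 1L], right_px = pairs$right_index[k],
      pixels = rg, microns = rg * step_um)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("distance_report", "data.frame"))
}

#' Assemble a distance report from already-measured separations
#'
#' Builds a `distance_report` directly from physical separations (e.g.
#' values printed by an instrument or a published table) so that
#' [diameter_error_stats()] can be applied to externally reported distances.
#'
#' @param microns Numeric vector of separations in micrometres.
#' @param type Character vector, "diameter" or "gap", one per entry.
#' @param label Optional labels.
#' @return A `distance_report`.
#' @export
as_distance_report <- function(microns, type, label = NULL) {
  stopifnot(is.numeric(microns), length(type) == length(microns),
            all(type %in% c("diameter", "gap")))
  if (is.null(label)) label <- as.character(seq_along(microns))
  out <- data.frame(label = label, type = type,
                    left_px = NA_integer_, right_px = NA_integer_,
                    pixels = NA_integer_, microns = as.numeric(microns))
  structure(out, class = c("distance_report", "data.frame"))
}

#' @export
print.distance_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$microns <- round(y$microns, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Deviation statistics against known set values
#'
#' Per reported distance: absolute error (um) and relative error against its
#' set value. Aggregates: the maximum absolute error over the *diameter*
#' rows only (the size of each medium), and the mean relative error in
#' percent over all rows with a known set value (gap rows included).
#'
#' @param report A `distance_report`.
#' @param truth Numeric vector of set values in um, one per report row
#'   (`NA` where unknown; must be nonzero where known).
#' @return An object of class `error_stats`: a list with `table` (per-row
#'   errors), `max_diameter_error_um`, and `mean_relative_error_pct`.
#' @export
diameter_error_stats <- function(report, truth) {
  stopifnot(inherits(report, "distance_report"))
  if (length(truth) != nrow(report)) {
    stop(sprintf("diameter_error_stats: %d set values for %d report rows",
                 length(truth), nrow(report)), call. = FALSE)
  }
  if (any(!is.na(truth) & truth == 0)) {
    stop("diameter_error_stats: set values must be nonzero", call. = FALSE)
  }
  tab <- as.data.frame(report)
  tab$set_um <- as.numeric(truth)
  tab$abs_err_um <- abs(tab$microns - tab$set_um)
  tab$rel_err <- tab$abs_err_um / abs(tab$set_um)
  diam <- tab$type == "diameter" & !is.na(tab$set_um)
  known <- !is.na(tab$set_um)
  if (!any(diam)) {
    stop("diameter_error_stats: no diameter row has a set value", call. = FALSE)
  }
  structure(list(table = tab,
                 max_diameter_error_um = max(tab$abs_err_um[diam]),
                 mean_relative_error_pct = 100 * mean(tab$rel_err[known])),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  tab <- x$table
  tab$microns <- round(tab$microns, 3)
  tab$abs_err_um <- round(tab$abs_err_um, 3)
  tab$rel_err <- round(tab$rel_err, 4)
  print(tab[, c("label", "type", "microns", "set_um", "abs_err_um", "rel_err")],
        row.names = FALSE)
  cat(sprintf("max diameter error: %.3f um; mean relative error: %.2g%%\n",
              x$max_diameter_error_um, x$mean_relative_error_pct))
  invisible(x)
}
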