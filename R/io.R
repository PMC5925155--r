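# Map I/O: 32-bit float single-channel TIFF (radians) and plain CSV
# matrices, each with a JSON sidecar carrying the pixel calibration.
# Writing uses a minimal single-strip uncompressed little-endian IEEE-float
# TIFF emitter (general-purpose TIFF writers clamp samples to [0, 1], which
# cannot represent radian-valued phase); reading goes through tiff::readTIFF,
# which handles the float sample format.

write_float_tiff <- function(m, path) {
  ny <- nrow(m); nx <- ncol(m)
  con <- file(path, "wb"); on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  ntags <- 11L
  data_off <- 8L + 2L + ntags * 12L + 4L
  w2(ntags)
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  tag(256L, 3L, 1L, nx)          # ImageWidth
  tag(257L, 3L, 1L, ny)          # ImageLength
  tag(258L, 3L, 1L, 32L)         # BitsPerSample
  tag(259L, 3L, 1L, 1L)          # Compression: none
  tag(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_off)    # StripOffsets
  tag(277L, 3L, 1L, 1L)          # SamplesPerPixel
  tag(278L, 3L, 1L, ny)          # RowsPerStrip
  tag(279L, 4L, 1L, nx * ny * 4L)  # StripByteCounts
  tag(284L, 3L, 1L, 1L)          # PlanarConfiguration
  tag(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
  w4(0L)                         # no further IFD
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

map_metadata <- function(map) {
  pitch <- pixel_pitch(map$grid)
  meta <- list(dx_um = unname(pitch[["dx"]]), dy_um = unname(pitch[["dy"]]),
               width_um = map$grid$width, height_um = map$grid$height,
               nx = map$grid$nx, ny = map$grid$ny, units = "rad")
  if (inherits(map, "gradient_map")) {
    meta$kind <- "gradient"; meta$axis <- map$axis; meta$squared <- map$squared
  } else meta$kind <- "phase"
  meta
}

#' Write a phase or gradient map to disk
#'
#' `.tif`/`.tiff` paths get a single-channel 32-bit float TIFF (values in
#' radians, stored at float32 precision); `.csv` paths get a plain numeric
#' matrix with full double precision. Either way a JSON sidecar
#' (`<path>.json`) records the pixel calibration and, for gradient maps,
#' the axis and squared flag.
#'
#' @param map A [phase_map()] or [gradient_map()].
#' @param path Output path ending in `.tif`, `.tiff`, or `.csv`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, c("phase_map", "gradient_map")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_float_tiff(map$values, path)
  } else if (ext == "csv") {
    utils::write.table(format(map$values, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    stop(sprintf("write_map: unsupported extension '.%s' (use .tif or .csv)",
                 ext), call. = FALSE)
  }
  jsonlite::write_json(map_metadata(map), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase or gradient map from disk
#'
#' Reads a float TIFF or CSV matrix written by [write_map()], or an
#' externally produced one. Calibration is mandatory: it comes from the
#' JSON sidecar when present, otherwise `pixel_um` must give the pixel
#' pitch explicitly.
#'
#' @param path Input `.tif`/`.tiff`/`.csv` path.
#' @param pixel_um Pixel pitch in um (scalar, or length 2 `c(dx, dy)`) when
#'   no sidecar metadata exists.
#' @return A [phase_map()] or, if the sidecar marks a gradient, a
#'   [gradient_map()].
#' @export
read_map <- function(path, pixel_um = NULL) {
  if (!file.exists(path)) stop(sprintf("read_map: no such file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    v
  } else if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else {
    stop(sprintf("read_map: unsupported extension '.%s'", ext), call. = FALSE)
  }
  dimnames(vals) <- NULL
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(meta) && is.null(pixel_um)) {
    stop(paste0("read_map: no calibration for external map '", path,
                "': supply pixel_um (um per pixel) or a ", sidecar_path(path),
                " sidecar"), call. = FALSE)
  }
  if (is.null(meta)) {
    pixel_um <- rep_len(as.numeric(pixel_um), 2L)
    grid <- grid_spec(ncol(vals) * pixel_um[1], nrow(vals) * pixel_um[2],
                      ncol(vals), nrow(vals))
    return(phase_map(vals, grid))
  }
  grid <- grid_spec(meta$width_um, meta$height_um, meta$nx, meta$ny)
  if (identical(meta$kind, "gradient")) {
    gradient_map(vals, grid, axis = meta$axis, squared = isTRUE(meta$squared))
  } else {
    phase_map(vals, grid)
  }
}

#' Serialise a distance report or its error statistics
#'
#' CSV gets one row per labelled pair/gap (`label`, `type`, `left_px`,
#' `right_px`, `pixels`, `microns`, and the error columns when available);
#' JSON mirrors the same records.
#'
#' @param x A `distance_report` or `error_stats` object.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  tab <- if (inherits(x, "error_stats")) x$table else as.data.frame(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else if (ext == "json") {
    payload <- list(rows = tab)
    if (inherits(x, "error_stats")) {
      payload$max_diameter_error_um <- x$max_diameter_error_um
      payload$mean_relative_error_pct <- x$mean_relative_error_pct
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    stop("write_report: use .csv or .json", call. = FALSE)
  }
  invisible(path)
}
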