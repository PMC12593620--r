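#' A registered multi-channel field image
#'
#' Container for one imaged field: a named list of equally shaped intensity
#' matrices (photon counts; channels among `F740`, `F910`, `nuclear`,
#' `immunolabel`, `structural`), the pixel size, per-field metadata and any
#' bleach-mark fiducial rectangles. Matrices are indexed `[row, col]`; all
#' tabular coordinates in the package are 0-based with `x` the column and `y`
#' the row, as stated in the output headers.
#'
#' @param channels Named list of numeric matrices, all the same shape, all
#'   intensities >= 0.
#' @param pixel_size Pixel edge length in micrometres (default 1).
#' @param metadata Named list (slice_id, region, genotype, age_group, state).
#' @param fiducials List of bleach-mark rectangles, each
#'   `list(x, y, size)` in 0-based pixel coordinates.
#' @return An object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size = 1, metadata = list(),
                        fiducials = list()) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a named list of matrices.")
  }
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    abort("All channels must share the same shape.")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) abort(sprintf("Channel `%s` must be a numeric matrix.", nm))
    if (any(ch < 0)) abort(sprintf("Channel `%s` has negative intensities.", nm))
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         metadata = metadata, fiducials = fiducials),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px, channels: %s\n",
              d[1], d[2], paste(names(x$channels), collapse = ", ")))
  if (length(x$fiducials)) cat(sprintf("  %d bleach-mark fiducial(s)\n", length(x$fiducials)))
  md <- x$metadata
  if (length(md)) {
    cat("  ", paste(sprintf("%s=%s", names(md), unlist(md)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

field_dim <- function(field) dim(field$channels[[1]])

require_channels <- function(field, wanted) {
  missing <- setdiff(wanted, names(field$channels))
  if (length(missing)) {
    abort(sprintf("Field is missing required channel(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  invisible(field)
}

#' Bleach a square fiducial mark into a field
#'
#' Emulates the laser bleach marks burned next to imaged tissue regions to
#' allow their re-identification after fixation and staining: a square of
#' side `size` pixels with top-left corner at `(x, y)` (0-based) is set to
#' the dark (bleached) level in every channel, and the mark geometry is
#' recorded in the field's fiducial list.
#'
#' @param field A [field_image()].
#' @param corner Numeric length-2 `(x, y)` top-left corner, 0-based pixels.
#' @param size Side length in pixels; `size = 0` is a no-op.
#' @param level Intensity to write into the bleached square (default 0).
#' @return The modified `field_image`.
#' @export
stamp_bleach_mark <- function(field, corner, size, level = 0) {
  stopifnot(inherits(field, "field_image"), length(corner) == 2)
  if (size < 0) abort("`size` must be >= 0.")
  if (size == 0) return(field)
  d <- field_dim(field)
  x0 <- corner[1]; y0 <- corner[2]
  if (x0 < 0 || y0 < 0 || x0 + size > d[2] || y0 + size > d[1]) {
    abort("Bleach mark falls outside the image.")
  }
  rows <- (y0 + 1):(y0 + size)
  cols <- (x0 + 1):(x0 + size)
  for (nm in names(field$channels)) {
    field$channels[[nm]][rows, cols] <- level
  }
  field$fiducials <- c(field$fiducials, list(list(x = x0, y = y0, size = size)))
  field
}

#' Write and read multi-channel fields as multi-page TIFF with a YAML sidecar
#'
#' One channel per 16-bit TIFF page, in the declared channel order; channel
#' names, pixel size, metadata and fiducials go to a `.yaml` sidecar next to
#' the image so the file pair round-trips exactly.
#'
#' @param field A [field_image()]; intensities are clamped to \[0, 65535\]
#'   and rounded on write.
#' @param path Path to the `.tif` file to write/read.
#' @return `write_field()` returns `path` invisibly; `read_field()` a
#'   `field_image`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) {
    ch <- round(pmin(pmax(ch, 0), 65535))
    ch / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L)
  sidecar <- sidecar_path(path)
  yaml::write_yaml(list(
    channels = as.list(names(field$channels)),
    pixel_size = field$pixel_size,
    metadata = field$metadata,
    fiducials = field$fiducials
  ), sidecar)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such image file: %s", path))
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar)) {
    abort(sprintf("Missing channel-naming sidecar for %s (expected %s).", path, sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ch_names <- unlist(meta$channels)
  if (length(pages) != length(ch_names)) {
    abort(sprintf("%s: %d TIFF pages but %d channel names declared.",
                  path, length(pages), length(ch_names)))
  }
  channels <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  })
  names(channels) <- ch_names
  field_image(channels,
              pixel_size = meta$pixel_size %||% 1,
              metadata = meta$metadata %||% list(),
              fiducials = meta$fiducials %||% list())
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")
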