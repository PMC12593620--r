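#' Pixelwise ratio image with validity mask
#'
#' Divides the F740 channel by the F910 channel pixel by pixel. Pixels whose
#' F910 intensity falls below `f910_floor` carry essentially no sensor signal
#' and would produce unstable quotients, so they are marked invalid and are
#' excluded from every downstream ROI average. Valid pixels are guaranteed
#' finite.
#'
#' @param field A [field_image()] with `F740` and `F910` channels.
#' @param f910_floor Minimum F910 intensity (counts) for a pixel to be
#'   considered valid; default `NULL` estimates it from the image background
#'   as mean + 3 SD of the dimmest half of the F910 pixels
#'   ([estimate_f910_floor()]).
#' @return A list with `ratio` (numeric matrix; `NA` at invalid pixels) and
#'   `valid` (logical matrix).
#' @export
compute_ratio_image <- function(field, f910_floor = NULL) {
  stopifnot(inherits(field, "field_image"))
  require_channels(field, c("F740", "F910"))
  f740 <- field$channels$F740
  f910 <- field$channels$F910
  f910_floor <- f910_floor %||% estimate_f910_floor(field)
  if (f910_floor <= 0) abort("`f910_floor` must be > 0.")
  valid <- f910 >= f910_floor
  ratio <- matrix(NA_real_, nrow(f740), ncol(f740))
  ratio[valid] <- f740[valid] / f910[valid]
  list(ratio = ratio, valid = valid, f910_floor = f910_floor)
}

#' Estimate the F910 validity floor from image background
#'
#' Background statistics are taken from the dimmest half of the F910 pixels
#' (cell somata are sparse and bright, so the lower half is background); the
#' floor is background mean + 3 SD, and at least 1 count.
#'
#' @param field A [field_image()] with an `F910` channel.
#' @return A single positive number (counts).
#' @export
estimate_f910_floor <- function(field) {
  require_channels(field, "F910")
  f910 <- field$channels$F910
  bg <- f910[f910 <= stats::median(f910)]
  max(mean(bg) + 3 * stats::sd(bg), 1)
}

#' Scale a ratio image onto the 12-bit pseudocolor display range
#'
#' For visualization the unitless ratio is multiplied by a scaling factor
#' (1000 by default) and mapped onto the 4096-level pseudocolor palette:
#' valid pixels become `round(ratio * scale)` clipped to \[0, 4095\], invalid
#' pixels get the reserved index 4095 + 1 = `NA`-substitute `reserved_index`.
#' This path is display-only: quantification always uses unscaled ratios.
#'
#' @param ratio_image Output of [compute_ratio_image()] (or a bare matrix,
#'   in which case all finite pixels count as valid).
#' @param scale Display scaling factor (default 1000).
#' @param reserved_index Index written at invalid pixels (default 0).
#' @return An integer matrix of palette indices.
#' @export
render_ratio_display <- function(ratio_image, scale = 1000, reserved_index = 0L) {
  if (scale <= 0) abort("`scale` must be > 0.")
  if (is.matrix(ratio_image)) {
    ratio <- ratio_image
    valid <- is.finite(ratio)
  } else {
    ratio <- ratio_image$ratio
    valid <- ratio_image$valid & is.finite(ratio)
  }
  out <- matrix(as.integer(reserved_index), nrow(ratio), ncol(ratio))
  out[valid] <- pmin(pmax(as.integer(round(ratio[valid] * scale)), 0L), 4095L)
  out
}

#' Detect somatic ROIs on the structural (F910) channel
#'
#' Automated stand-in for manual ROI placement on clearly identifiable
#' sensor-expressing neurons: the F910 channel is Gaussian-smoothed, Otsu
#' thresholded, connected components are labelled and reduced to circular
#' ROIs (centroid + equivalent-area radius). Components outside the radius
#' range, touching the border, or overlapping a brighter accepted component
#' are dropped. Deterministic for a fixed image.
#'
#' @param field A [field_image()] with an `F910` channel (or the channel
#'   named by `channel`).
#' @param min_radius,max_radius Accepted ROI radius range in pixels.
#' @param channel Structural channel name (default "F910").
#' @param sigma Smoothing SD in pixels before thresholding (default 2).
#' @return A tibble with `cell_id`, `x`, `y` (0-based; x = column), `radius`
#'   and `peak_intensity`, ordered by `y` then `x`. May be empty.
#' @export
detect_somata <- function(field, min_radius = 3, max_radius = 15,
                          channel = "F910", sigma = 2) {
  stopifnot(inherits(field, "field_image"))
  require_channels(field, channel)
  img <- field$channels[[channel]]
  rng <- range(img)
  if (diff(rng) <= 0) return(empty_roi_table())
  x <- (img - rng[1]) / diff(rng)
  xs <- EBImage::gblur(EBImage::Image(x), sigma = sigma)
  th <- EBImage::otsu(xs, range = c(0, 1))
  mask <- xs > th
  # distance-map watershed splits touching somata before labelling
  lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  if (max(lab) == 0) return(empty_roi_table())
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(mom))) { mom <- rbind(mom); shp <- rbind(shp) }
  # EBImage's first image dimension is the matrix row: m.cx indexes rows.
  rois <- tibble(
    y = mom[, "m.cx"] - 1,
    x = mom[, "m.cy"] - 1,
    radius = sqrt(shp[, "s.area"] / pi)
  )
  rois$peak_intensity <- purrr::map2_dbl(rois$x, rois$y, function(px, py) {
    img[round(py) + 1, round(px) + 1]
  })
  d <- dim(img)
  rois <- dplyr::filter(
    rois,
    .data$radius >= min_radius, .data$radius <= max_radius,
    .data$x - .data$radius >= 0, .data$y - .data$radius >= 0,
    .data$x + .data$radius <= d[2] - 1, .data$y + .data$radius <= d[1] - 1
  )
  # greedy overlap suppression, brightest first
  rois <- dplyr::arrange(rois, dplyr::desc(.data$peak_intensity))
  keep <- rep(TRUE, nrow(rois))
  if (nrow(rois) > 1) {
    for (i in 2:nrow(rois)) {
      prev <- which(keep[seq_len(i - 1)])
      if (length(prev)) {
        dd <- sqrt((rois$x[prev] - rois$x[i])^2 + (rois$y[prev] - rois$y[i])^2)
        if (any(dd < rois$radius[prev] + rois$radius[i])) keep[i] <- FALSE
      }
    }
  }
  rois <- rois[keep, ]
  rois <- dplyr::arrange(rois, .data$y, .data$x)
  rois$cell_id <- sprintf("roi_%03d", seq_len(nrow(rois)))
  dplyr::select(rois, "cell_id", "x", "y", "radius", "peak_intensity")
}

empty_roi_table <- function() {
  tibble(cell_id = character(), x = numeric(), y = numeric(),
         radius = numeric(), peak_intensity = numeric())
}

#' Average the ratio and channel intensities within circular somatic ROIs
#'
#' The primary per-cell statistic is the mean of pixelwise ratios over the
#' valid pixels of the ROI. The ratio of channel means is carried alongside
#' as a QC cross-check (`ratio_of_means`), flagged when the two statistics
#' disagree by more than 5%. ROIs are measured at `shrink` times their
#' nominal radius so that soma-edge pixels (mixed with background by the
#' point-spread function) do not bias the average.
#'
#' @param field A [field_image()] with `F740`/`F910`.
#' @param rois Tibble with `cell_id`, `x`, `y`, `radius` (0-based pixels).
#' @param ratio_image Optional precomputed [compute_ratio_image()] output.
#' @param shrink Fraction of the nominal radius actually averaged
#'   (default 0.7).
#' @param saturation_level Intensity treated as sensor saturation
#'   (default `0.98 * 65535`).
#' @return A tibble: `cell_id`, `x`, `y`, `radius`, `f740_mean`,
#'   `f910_mean`, `ratio`, `ratio_of_means`, `n_valid_pixels`, `n_pixels`,
#'   `qc_flags` (";"-separated; empty when clean). A ROI without valid
#'   pixels is returned with `ratio = NA` and flag `no_valid_pixels`.
#' @export
measure_rois <- function(field, rois, ratio_image = NULL, shrink = 0.7,
                         saturation_level = 0.98 * 65535) {
  stopifnot(inherits(field, "field_image"))
  require_channels(field, c("F740", "F910"))
  rois <- as_tibble(rois)
  if (nrow(rois) == 0) {
    return(tibble(cell_id = character(), x = numeric(), y = numeric(),
                  radius = numeric(), f740_mean = numeric(), f910_mean = numeric(),
                  ratio = numeric(), ratio_of_means = numeric(),
                  n_valid_pixels = integer(), n_pixels = integer(),
                  qc_flags = character()))
  }
  ri <- ratio_image %||% compute_ratio_image(field)
  f740 <- field$channels$F740
  f910 <- field$channels$F910
  d <- dim(f740)

  out <- purrr::pmap_dfr(
    list(rois$cell_id, rois$x, rois$y, rois$radius),
    function(cell_id, x, y, radius) {
      r <- radius * shrink
      rows <- max(1, floor(y - r) + 1):min(d[1], ceiling(y + r) + 1)
      cols <- max(1, floor(x - r) + 1):min(d[2], ceiling(x + r) + 1)
      inside <- outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+") <= r^2
      n_pix <- sum(inside)
      sel_valid <- inside & ri$valid[rows, cols]
      n_val <- sum(sel_valid)
      f740_mean <- mean(f740[rows, cols][inside])
      f910_mean <- mean(f910[rows, cols][inside])
      flags <- character()
      if (n_val == 0) {
        ratio <- NA_real_
        flags <- c(flags, "no_valid_pixels")
      } else {
        ratio <- mean(ri$ratio[rows, cols][sel_valid])
        if (n_val < 0.5 * n_pix) flags <- c(flags, "low_validity")
      }
      rom <- if (f910_mean > 0) f740_mean / f910_mean else NA_real_
      if (is.finite(ratio) && is.finite(rom) && abs(rom / ratio - 1) > 0.05) {
        flags <- c(flags, "ratio_statistic_mismatch")
      }
      if (max(f740[rows, cols][inside]) >= saturation_level ||
          max(f910[rows, cols][inside]) >= saturation_level) {
        flags <- c(flags, "saturation")
      }
      tibble(cell_id = cell_id, x = x, y = y, radius = radius,
             f740_mean = f740_mean, f910_mean = f910_mean,
             ratio = ratio, ratio_of_means = rom,
             n_valid_pixels = as.integer(n_val), n_pixels = as.integer(n_pix),
             qc_flags = paste(flags, collapse = ";"))
    }
  )
  out
}

#' Quantify one field: detect somata, compute ratios, measure ROIs
#'
#' Convenience wrapper chaining [compute_ratio_image()], [detect_somata()]
#' (unless a ROI list is supplied, preserving the manual-placement workflow)
#' and [measure_rois()], and attaching the field's metadata columns.
#'
#' @param field A [field_image()].
#' @param rois Optional externally supplied ROI tibble.
#' @param f910_floor Optional fixed validity floor.
#' @param ... Passed to [detect_somata()].
#' @return A tibble of ROI measurements with metadata columns appended.
#' @export
quantify_field <- function(field, rois = NULL, f910_floor = NULL, ...) {
  ri <- compute_ratio_image(field, f910_floor = f910_floor)
  rois <- rois %||% detect_somata(field, ...)
  m <- measure_rois(field, rois, ratio_image = ri)
  md <- field$metadata
  for (nm in c("slice_id", "region", "genotype", "age_group", "state")) {
    if (!is.null(md[[nm]])) m[[nm]] <- md[[nm]]
  }
  m
}
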