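#' Register a fixed (post-staining) field onto a live field by bleach marks
#'
#' After fixation and immunostaining, the previously imaged region is
#' re-identified through the square laser bleach marks burned next to it.
#' Both structural channels are binarized into "dark" masks (pixels below
#' half the channel median — the bleached square against the tissue glow)
#' and the integer translation maximizing their normalized cross-correlation
#' within `search_radius` pixels is returned. Exact to one pixel for
#' synthetic pairs.
#'
#' @param live_field [field_image()] holding the ratiometric recording; its
#'   `live_channel` (default `F910`) is the structural reference.
#' @param fixed_field [field_image()] of the stained slice; structural
#'   channel `fixed_channel` (default `structural`).
#' @param search_radius Maximum |shift| searched per axis (default 20 px).
#' @param min_confidence Minimum normalized correlation peak (default 0.3).
#' @param live_channel,fixed_channel Channel names.
#' @return Named numeric `c(x = dx, y = dy)`: a point at `(x, y)` in the
#'   live field sits at `(x + dx, y + dy)` in the fixed field. Attribute
#'   `confidence` carries the peak score.
#' @export
register_by_fiducials <- function(live_field, fixed_field, search_radius = 20,
                                  min_confidence = 0.3,
                                  live_channel = "F910",
                                  fixed_channel = "structural") {
  require_channels(live_field, live_channel)
  require_channels(fixed_field, fixed_channel)
  a <- live_field$channels[[live_channel]]
  b <- fixed_field$channels[[fixed_channel]]
  if (!identical(dim(a), dim(b))) abort("Live and fixed fields must share the same shape.")
  mask_a <- dark_mask(a)
  mask_b <- dark_mask(b)
  min_px <- 0.2 * 25^2  # a detectable mark footprint is tens of pixels across
  if (sum(mask_a) < min_px || sum(mask_b) < min_px) {
    abort("No bleach-mark fiducial detectable in one of the fields.")
  }
  cc <- cross_correlate_masks(mask_a, mask_b)
  d <- dim(a)
  best <- c(0, 0); best_score <- -Inf
  for (dy in -search_radius:search_radius) {
    iy <- ((dy %% d[1]) + 1)
    for (dx in -search_radius:search_radius) {
      ix <- ((dx %% d[2]) + 1)
      s <- cc[iy, ix]
      if (s > best_score) { best_score <- s; best <- c(dx, dy) }
    }
  }
  conf <- best_score / sqrt(sum(mask_a) * sum(mask_b))
  if (conf < min_confidence) {
    abort(sprintf("Registration failed: correlation peak %.3f below confidence threshold %.2f.",
                  conf, min_confidence))
  }
  structure(c(x = best[1], y = best[2]), confidence = conf)
}

dark_mask <- function(img) {
  img < 0.5 * stats::median(img)
}

# Circular cross-correlation via FFT: entry (dy mod n) + 1, (dx mod m) + 1
# holds sum_t A(t) * B(t + (dy, dx)).
cross_correlate_masks <- function(a, b) {
  fa <- stats::fft(a * 1)
  fb <- stats::fft(b * 1)
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(a)
}

#' Classify nuclei as MeCP2-positive or -deficient by immunolabel intensity
#'
#' Detects nuclei on the nuclear-stain channel, averages the immunolabel
#' channel within each nucleus, and splits the log intensities into two
#' classes with a two-component Gaussian mixture (k-means fallback when the
#' mixture fit fails). The class with the higher mean is "positive". A
#' bimodality diagnostic (between-class separation in pooled-SD units) below
#' 2 triggers a warning — the classification is still returned, but the
#' intensity distribution does not support two clear classes.
#'
#' @param fixed_field [field_image()] with `nuclear` and `immunolabel`
#'   channels.
#' @param nuclei Optional tibble of nucleus ROIs (`cell_id`, `x`, `y`,
#'   `radius`); detected from the nuclear channel when `NULL`.
#' @param min_nuclei Minimum number of nuclei required (default 4).
#' @return Tibble: `nucleus_id`, `x`, `y`, `radius`, `score` (mean
#'   immunolabel intensity), `mecp2_positive` (logical); attribute
#'   `bimodality` carries the separation diagnostic.
#' @export
classify_mecp2 <- function(fixed_field, nuclei = NULL, min_nuclei = 4) {
  require_channels(fixed_field, c("nuclear", "immunolabel"))
  nuclei <- nuclei %||% detect_somata(fixed_field, channel = "nuclear",
                                      min_radius = 2, max_radius = 10, sigma = 1.5)
  nuclei <- as_tibble(nuclei)
  if (nrow(nuclei) < min_nuclei) {
    abort(sprintf("Need at least %d nuclei, found %d.", min_nuclei, nrow(nuclei)))
  }
  img <- fixed_field$channels$immunolabel
  d <- dim(img)
  score <- purrr::pmap_dbl(list(nuclei$x, nuclei$y, nuclei$radius), function(x, y, r) {
    r <- r * 0.8
    rows <- max(1, floor(y - r) + 1):min(d[1], ceiling(y + r) + 1)
    cols <- max(1, floor(x - r) + 1):min(d[2], ceiling(x + r) + 1)
    inside <- outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+") <= r^2
    mean(img[rows, cols][inside])
  })
  ls <- log(pmax(score, 1))
  bimod <- NA_real_
  cls <- tryCatch({
    fit2 <- mclust::Mclust(ls, G = 2, modelNames = c("E", "V"), verbose = FALSE)
    fit1 <- mclust::Mclust(ls, G = 1, modelNames = "X", verbose = FALSE)
    if (is.null(fit2)) stop("mixture fit failed")
    # evidence for two classes: BIC difference (positive favours bimodality)
    if (!is.null(fit1)) bimod <- max(fit2$BIC, na.rm = TRUE) - max(fit1$BIC, na.rm = TRUE)
    fit2$classification
  }, error = function(e) {
    stats::kmeans(ls, centers = 2)$cluster
  })
  mu <- tapply(ls, cls, mean)
  pos_class <- as.integer(names(mu)[which.max(mu)])
  # BIC difference below 6 ("strong evidence" on the usual scale) means the
  # data do not clearly support two intensity classes
  if (is.finite(bimod) && bimod < 6) {
    warn(sprintf("Immunolabel intensities look unimodal (two-class BIC evidence %.1f); the split may be arbitrary.", bimod))
  }
  out <- tibble(
    nucleus_id = sprintf("nuc_%03d", seq_len(nrow(nuclei))),
    x = nuclei$x, y = nuclei$y, radius = nuclei$radius,
    score = score,
    mecp2_positive = cls == pos_class
  )
  attr(out, "bimodality") <- bimod
  out
}

#' Match live-imaged somata to fixed-field nuclei
#'
#' Applies the estimated translation to the live ROI centres and pairs them
#' with nuclei by greedy one-to-one nearest-neighbour matching within
#' `matching_radius` pixels.
#'
#' @param live_rois Tibble with `cell_id`, `x`, `y` (live coordinates).
#' @param fixed_nuclei Tibble with `nucleus_id`, `x`, `y`.
#' @param offset Translation from [register_by_fiducials()].
#' @param matching_radius Maximum accepted match distance in pixels
#'   (default 7, about one soma radius).
#' @return Tibble: `cell_id`, `nucleus_id` (`NA` when unmatched),
#'   `distance`, `matched`.
#' @export
match_cells <- function(live_rois, fixed_nuclei, offset, matching_radius = 7) {
  live_rois <- as_tibble(live_rois)
  fixed_nuclei <- as_tibble(fixed_nuclei)
  if (nrow(live_rois) == 0) {
    return(tibble(cell_id = character(), nucleus_id = character(),
                  distance = numeric(), matched = logical()))
  }
  tx <- live_rois$x + offset[["x"]]
  ty <- live_rois$y + offset[["y"]]
  m <- match_points(tx, ty, fixed_nuclei$x, fixed_nuclei$y, radius = matching_radius)
  out <- tibble(
    cell_id = live_rois$cell_id,
    nucleus_id = NA_character_,
    distance = NA_real_,
    matched = FALSE
  )
  if (nrow(m)) {
    out$nucleus_id[m$i] <- fixed_nuclei$nucleus_id[m$j]
    out$distance[m$i] <- m$dist
    out$matched[m$i] <- TRUE
  }
  out
}

#' Normalize ratios per slice and compare expression classes
#'
#' The optical conditions of correlative (post-staining) imaging differ from
#' the calibrated live recordings, so this stage works on raw F740/F910
#' ratios, made comparable across slices by dividing every cell's ratio by
#' the mean ratio of the MeCP2-positive cells of its own slice. With the
#' default inclusive denominator each positive cell enters its own slice
#' mean, so the within-slice positive mean of the normalized values is
#' exactly 1; `denominator = "leave_one_out"` instead excludes each positive
#' cell from its own denominator. Slices with fewer than `min_positive`
#' positive cells are excluded (the denominator would be too unstable). The
#' two classes are then compared with Welch's t-test on the pooled
#' normalized values.
#'
#' @param cells Tibble with `cell_id`, `slice_id`, `mecp2_positive`
#'   (logical) and `ratio`.
#' @param min_positive Minimum positive cells per slice (default 5).
#' @param denominator `"inclusive"` (default) or `"leave_one_out"`.
#' @return An object of class `correlative_result`: list with `normalized`
#'   (tibble incl. `ratio_norm`), `summary` (per-class pooled mean, sd, n),
#'   `test` ([welch_t()] of deficient vs positive) and `excluded_slices`.
#' @export
normalize_and_compare <- function(cells, min_positive = 5,
                                  denominator = c("inclusive", "leave_one_out")) {
  denominator <- match.arg(denominator)
  cells <- as_tibble(cells)
  needed <- c("cell_id", "slice_id", "mecp2_positive", "ratio")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) abort(sprintf("Missing column(s): %s", paste(missing, collapse = ", ")))
  cells <- dplyr::filter(cells, is.finite(.data$ratio), !is.na(.data$mecp2_positive))

  pos_counts <- cells |>
    dplyr::group_by(.data$slice_id) |>
    dplyr::summarise(n_pos = sum(.data$mecp2_positive), .groups = "drop")
  bad <- pos_counts$slice_id[pos_counts$n_pos < min_positive]
  if (length(bad)) {
    message(sprintf("Excluding %d slice(s) with < %d MeCP2-positive cells: %s",
                    length(bad), min_positive, paste(bad, collapse = ", ")))
  }
  cells <- dplyr::filter(cells, !.data$slice_id %in% bad)
  if (nrow(cells) == 0) abort("No slice satisfies the minimum positive-cell count.")

  norm <- cells |>
    dplyr::group_by(.data$slice_id) |>
    dplyr::mutate(
      pos_sum = sum(.data$ratio[.data$mecp2_positive]),
      pos_n = sum(.data$mecp2_positive),
      denom = dplyr::case_when(
        denominator == "leave_one_out" & .data$mecp2_positive ~
          (.data$pos_sum - .data$ratio) / (.data$pos_n - 1),
        TRUE ~ .data$pos_sum / .data$pos_n
      ),
      ratio_norm = .data$ratio / .data$denom
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"pos_sum", -"pos_n", -"denom")

  summary <- norm |>
    dplyr::mutate(class = ifelse(.data$mecp2_positive, "MeCP2-positive", "MeCP2-deficient")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean = mean(.data$ratio_norm),
                     sd = stats::sd(.data$ratio_norm),
                     n = dplyr::n(), .groups = "drop")

  test <- tryCatch(
    welch_t(norm$ratio_norm[!norm$mecp2_positive],
            norm$ratio_norm[norm$mecp2_positive]),
    error = function(e) {
      warn(paste("Welch comparison unavailable:", conditionMessage(e)))
      NULL
    }
  )

  structure(
    list(normalized = norm, summary = summary, test = test,
         excluded_slices = bad, denominator = denominator),
    class = "correlative_result"
  )
}

#' @export
print.correlative_result <- function(x, ...) {
  cat("<correlative_result> per-slice normalized ratios (", x$denominator,
      " denominator)\n", sep = "")
  print(x$summary)
  if (!is.null(x$test)) {
    cat(sprintf("Welch's t: t = %.3f, df = %.1f, p = %.4g %s\n",
                x$test$t, x$test$df, x$test$p, x$test$marker))
  }
  invisible(x)
}

#' Analyze one live/fixed correlative field pair
#'
#' Chains the correlative stage for a single field: quantify the live
#' ratiometric field, register the fixed field by bleach marks, detect and
#' classify nuclei, and match cells to nuclei. Returns one row per matched
#' cell, ready for [normalize_and_compare()].
#'
#' @param live_field,fixed_field The two [field_image()]s.
#' @param matching_radius Passed to [match_cells()].
#' @param search_radius Passed to [register_by_fiducials()].
#' @return Tibble: `cell_id`, `slice_id`, `ratio`, `mecp2_positive`,
#'   `nucleus_id`, `distance`.
#' @export
analyze_correlative_pair <- function(live_field, fixed_field,
                                     matching_radius = 7, search_radius = 20) {
  rois <- quantify_field(live_field)
  offset <- register_by_fiducials(live_field, fixed_field,
                                  search_radius = search_radius)
  nuclei <- classify_mecp2(fixed_field)
  matches <- match_cells(rois, nuclei, offset, matching_radius = matching_radius)
  if (!"slice_id" %in% names(rois)) {
    rois$slice_id <- live_field$metadata$slice_id %||% "slice"
  }
  rois |>
    dplyr::inner_join(dplyr::filter(matches, .data$matched),
                      by = "cell_id") |>
    dplyr::left_join(dplyr::select(nuclei, "nucleus_id", "mecp2_positive"),
                     by = "nucleus_id") |>
    dplyr::transmute(
      cell_id = .data$cell_id,
      slice_id = .data$slice_id,
      ratio = .data$ratio,
      mecp2_positive = .data$mecp2_positive,
      nucleus_id = .data$nucleus_id,
      distance = .data$distance
    )
}
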