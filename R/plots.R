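#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_point
#'   geom_jitter geom_raster facet_wrap labs position_dodge theme_minimal
#'   scale_fill_viridis_c coord_fixed geom_hline
#' @export
ggplot2::autoplot

#' Plot group mean OxD with SD bars per region
#'
#' Bar-and-whisker view of an aggregation table: one panel per region, bars
#' for the four genotype-by-age groups, whiskers at mean +/- SD.
#'
#' @param object An aggregation tibble from [aggregate_redox()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot redox_summary
#' @export
autoplot.redox_summary <- function(object, ...) {
  plot_redox_summary(object)
}

#' @rdname autoplot.redox_summary
#' @param summary Aggregation tibble with `region`, `genotype`, `age_group`,
#'   `mean`, `sd`.
#' @export
plot_redox_summary <- function(summary) {
  summary <- as_tibble(summary)
  ggplot(summary, aes(x = .data$age_group, y = .data$mean, fill = .data$genotype)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.8), width = 0.25) +
    facet_wrap(~region) +
    labs(x = "age group", y = "degree of oxidation (OxD)", fill = "genotype") +
    theme_minimal()
}

#' Plot a field channel or its ratio display as a raster
#'
#' @param object A [field_image()].
#' @param channel Channel to show (default `"F910"`); `"ratio"` renders the
#'   pseudocolor-scaled ratio image.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot field_image
#' @export
autoplot.field_image <- function(object, channel = "F910", ...) {
  if (channel == "ratio") {
    img <- render_ratio_display(compute_ratio_image(object))
    lab <- "ratio x 1000 (12-bit display)"
  } else {
    require_channels(object, channel)
    img <- object$channels[[channel]]
    lab <- paste(channel, "(counts)")
  }
  df <- tidyr::expand_grid(y = seq_len(nrow(img)) - 1, x = seq_len(ncol(img)) - 1)
  df$value <- as.vector(t(img))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = lab) +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' Dot plot of per-slice normalized ratios by expression class
#'
#' @param object A `correlative_result` from [normalize_and_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlative_result
#' @export
autoplot.correlative_result <- function(object, ...) {
  norm <- dplyr::mutate(
    object$normalized,
    class = ifelse(.data$mecp2_positive, "MeCP2-positive", "MeCP2-deficient")
  )
  ggplot(norm, aes(x = .data$class, y = .data$ratio_norm)) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    geom_point(data = object$summary, aes(x = .data$class, y = .data$mean),
               shape = 95, size = 12) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "normalized F740/F910 ratio") +
    theme_minimal()
}
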