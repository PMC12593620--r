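#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the pairwise contrast table of a group comparison
#'
#' @param x A `redox_comparison` from [compare_redox()].
#' @param ... Unused.
#' @return Tibble of pairwise contrasts (one row each) with adjusted
#'   p-values and significance markers.
#' @method tidy redox_comparison
#' @export
tidy.redox_comparison <- function(x, ...) {
  x$pairwise
}

#' One-row summary of a group comparison
#'
#' @param x A `redox_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: number of regions, contrasts, significant
#'   contrasts at the 0.05 and 0.01 level (after adjustment).
#' @method glance redox_comparison
#' @export
glance.redox_comparison <- function(x, ...) {
  tibble(
    n_regions = length(unique(x$anova$region)),
    n_contrasts = nrow(x$pairwise),
    n_sig_05 = sum(x$pairwise$p_adj < 0.05, na.rm = TRUE),
    n_sig_01 = sum(x$pairwise$p_adj < 0.01, na.rm = TRUE),
    method = x$method
  )
}

#' Tidy a correlative comparison result
#'
#' @param x A `correlative_result` from [normalize_and_compare()].
#' @param ... Unused.
#' @return The per-class summary tibble (pooled mean, SD, n of normalized
#'   ratios).
#' @method tidy correlative_result
#' @export
tidy.correlative_result <- function(x, ...) {
  x$summary
}

#' One-row summary of a correlative comparison
#'
#' @param x A `correlative_result`.
#' @param ... Unused.
#' @return One-row tibble with the Welch statistics and class sizes.
#' @method glance correlative_result
#' @export
glance.correlative_result <- function(x, ...) {
  dplyr::transmute(
    x$test,
    mean_deficient = .data$mean_a, mean_positive = .data$mean_b,
    n_deficient = .data$n_a, n_positive = .data$n_b,
    t = .data$t, df = .data$df, p = .data$p, marker = .data$marker
  )
}

#' Tidy a calibration record
#'
#' @param x A [calibration_params()].
#' @param ... Unused.
#' @return Tibble with one row per calibration constant (estimate, sd, n).
#' @method tidy calibration_params
#' @export
tidy.calibration_params <- function(x, ...) {
  tibble(
    term = c("r_ox", "r_red", "instrument_factor"),
    estimate = c(x$r_ox, x$r_red, x$instrument_factor),
    sd = c(x$sd_r_ox, x$sd_r_red, x$sd_if),
    n = c(x$n_ox, x$n_red, min(x$n_ox, x$n_red))
  )
}
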