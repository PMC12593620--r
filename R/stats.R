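#' Intactness screen: keep cells with OxD in the physiological range
#'
#' Neurons whose apparent degree of oxidation falls outside 5--95% are
#' considered damaged or mis-measured (the calibration formula is evaluated
#' without clamping, so out-of-range values exist by design) and are
#' excluded. The interval is closed: boundary values are retained. Cells
#' whose OxD is undefined (`NA`) are excluded with their own reason.
#'
#' @param cells Data frame with an `oxd` column.
#' @param lower,upper Range bounds (defaults 0.05 and 0.95).
#' @return The input as a tibble with logical `included` and character
#'   `exclusion_reason` (`NA` for included cells) columns; idempotent.
#' @export
filter_intact <- function(cells, lower = 0.05, upper = 0.95) {
  cells <- as_tibble(cells)
  if (!"oxd" %in% names(cells)) abort("`cells` must have an `oxd` column.")
  undefined <- !is.finite(cells$oxd)
  in_range <- !undefined & cells$oxd >= lower & cells$oxd <= upper
  cells$included <- in_range
  cells$exclusion_reason <- dplyr::case_when(
    undefined ~ "undefined",
    !in_range ~ "range",
    TRUE ~ NA_character_
  )
  cells
}

#' ROUT outlier detection on a single column of values
#'
#' Robust outlier screening at a controlled false-discovery rate Q, reduced
#' to the constant model for column data: the column is centred at its
#' median; the robust scale is the 68.27th percentile of absolute residuals
#' (which matches the SD for clean normal data) with the small-sample
#' correction factor n/(n-1); each point gets a t-like statistic
#' residual/scale and a two-sided tail probability from the t distribution
#' with n-1 degrees of freedom; finally the points are tested from the most
#' extreme residual inward by the step-up false-discovery rule at rate `q`
#' (the i-th smallest p is flagged, together with all more extreme points,
#' when p <= i * q / n for some i at or beyond it).
#'
#' @param values Numeric vector, length >= 3.
#' @param q Maximum desired false-discovery rate (default 0.01, i.e. Q = 1%).
#' @return A list with `kept`, `flagged` (numeric vectors), and `detail`
#'   (tibble: value, residual, t, p, outlier).
#' @export
rout_outliers <- function(values, q = 0.01) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort("ROUT needs at least 3 values.")
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  res <- values - stats::median(values)
  scale <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (scale <= 0) {
    detail <- tibble(value = values, residual = res, t = 0, p = 1, outlier = FALSE)
    return(list(kept = values, flagged = numeric(), detail = detail))
  }
  tstat <- res / scale
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  # step-up FDR from the most extreme residual inward
  ord <- order(p)
  flag <- rep(FALSE, n)
  thresholds <- q * seq_len(n) / n
  pass <- p[ord] <= thresholds
  if (any(pass)) flag[ord[seq_len(max(which(pass)))]] <- TRUE
  detail <- tibble(value = values, residual = res, t = tstat, p = p, outlier = flag)
  list(kept = values[!flag], flagged = values[flag], detail = detail)
}

#' Flag outliers per analysis column of a cell table
#'
#' Applies [rout_outliers()] within each (region, genotype, age_group)
#' column — the grouping in which per-neuron OxD values are plotted and
#' compared — and marks flagged cells as excluded with reason `"outlier"`.
#' Cells already excluded (by [filter_intact()]) are not re-tested. Groups
#' with fewer than 3 eligible cells are left untouched.
#'
#' @param cells Tibble with `oxd`, `included` columns (output of
#'   [filter_intact()]); grouping columns default to region/genotype/age.
#' @param q FDR level (default 0.01).
#' @param group_vars Character vector of grouping columns.
#' @param response Column screened (default "oxd").
#' @return The tibble with `included`/`exclusion_reason` updated.
#' @export
screen_outliers <- function(cells, q = 0.01,
                            group_vars = c("region", "genotype", "age_group"),
                            response = "oxd") {
  cells <- as_tibble(cells)
  if (!"included" %in% names(cells)) {
    cells$included <- is.finite(cells[[response]])
    cells$exclusion_reason <- ifelse(cells$included, NA_character_, "undefined")
  }
  group_vars <- intersect(group_vars, names(cells))
  key <- if (length(group_vars)) {
    do.call(paste, c(cells[group_vars], sep = "\r"))
  } else rep("all", nrow(cells))
  for (k in unique(key)) {
    idx <- which(key == k & cells$included)
    if (length(idx) < 3) next
    flag <- rout_outliers(cells[[response]][idx], q = q)$detail$outlier
    if (any(flag)) {
      cells$included[idx[flag]] <- FALSE
      cells$exclusion_reason[idx[flag]] <- "outlier"
    }
  }
  cells
}

#' Aggregate per-neuron OxD at the cell or tissue-slice level
#'
#' Cell level: mean, SD and n over individual neurons per (region, genotype,
#' age) group. Slice level: neurons are first averaged within each brain
#' slice, then the slice means are averaged per group — the two orders give
#' different answers when slices contribute unequal cell numbers, and both
#' views are reported in the study design this package supports. Only
#' included cells enter; `n` counts neurons (cell level) or slices (slice
#' level). A single-slice group has `sd = NA` at slice level.
#'
#' @param cells Tibble with `oxd`, `included` and grouping columns.
#' @param level `"cell"` or `"slice"`.
#' @param group_vars Grouping columns (default region, genotype, age_group).
#' @param response Response column (default "oxd").
#' @return A tibble: grouping columns, `mean`, `sd`, `n`, `level`.
#' @export
aggregate_redox <- function(cells, level = c("cell", "slice"),
                            group_vars = c("region", "genotype", "age_group"),
                            response = "oxd") {
  level <- match.arg(level)
  cells <- as_tibble(cells)
  if ("included" %in% names(cells)) cells <- dplyr::filter(cells, .data$included)
  cells <- dplyr::filter(cells, is.finite(.data[[response]]))
  group_vars <- intersect(group_vars, names(cells))
  if (level == "cell") {
    out <- cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
      dplyr::summarise(
        mean = mean(.data[[response]]),
        sd = if (dplyr::n() > 1) stats::sd(.data[[response]]) else NA_real_,
        n = dplyr::n(), .groups = "drop"
      )
  } else {
    if (!"slice_id" %in% names(cells)) abort("Slice-level aggregation needs a `slice_id` column.")
    out <- cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(group_vars, "slice_id")))) |>
      dplyr::summarise(slice_mean = mean(.data[[response]]), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
      dplyr::summarise(
        mean = mean(.data$slice_mean),
        sd = if (dplyr::n() > 1) stats::sd(.data$slice_mean) else NA_real_,
        n = dplyr::n(), .groups = "drop"
      )
  }
  out$level <- level
  class(out) <- c("redox_summary", class(out))
  out
}

#' Holm-Sidak step-down adjustment of a family of p-values
#'
#' Sorts the k raw p-values ascending and adjusts the i-th as
#' `1 - (1 - p_(i))^(k - i + 1)`, then enforces monotone non-decreasing
#' adjusted values along the step-down order. Dominates the single-step
#' Sidak correction and is never smaller than the raw p.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  k <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(k - seq_len(k) + 1)
  adj_sorted <- cummax(adj_sorted)
  adj <- numeric(k)
  adj[ord] <- pmin(adj_sorted, 1)
  adj
}

significance_marker <- function(p, type = c("age", "genotype", "both")) {
  type <- match.arg(type)
  sym <- switch(type, age = "*", genotype = "#", both = "+")
  dplyr::case_when(
    !is.finite(p) ~ "",
    p < 0.01 ~ strrep(sym, 2),
    p < 0.05 ~ sym,
    TRUE ~ ""
  )
}

#' Two-way ANOVA with all-pairwise Holm-Sidak comparisons, per region
#'
#' For each brain region, fits the 2 x 2 genotype-by-age design on the
#' response (marginal / Type-III sums of squares with sum-to-zero coding, so
#' unbalanced group sizes are handled), then compares all six pairs of the
#' four genotype-age groups with t statistics on the pooled ANOVA residual
#' variance. The six raw p-values form one Holm-Sidak family per region; no
#' correction is applied across regions. Significance markers follow the
#' plotting convention: `*`/`**` for age contrasts within a genotype
#' (p < 0.05 / p < 0.01), `#`/`##` for genotype contrasts within an age
#' group, `+`/`++` for the two diagonal contrasts.
#'
#' @param cells Tibble with `oxd` (or `response`), `genotype`, `age_group`,
#'   `region` and (after screening) `included` columns. Rows with
#'   `included = FALSE` are dropped.
#' @param response Response column name (default "oxd").
#' @param regions Optional subset of regions.
#' @return An object of class `redox_comparison`: a list with `anova`
#'   (tibble: region, term, df, F, p) and `pairwise` (tibble: region,
#'   contrast, group means/SD/n, estimate, t, df, p, p_adj, marker,
#'   contrast_type). Regions with an empty design cell are reported with
#'   `NA` statistics rather than dropped.
#' @export
compare_redox <- function(cells, response = "oxd", regions = NULL) {
  cells <- as_tibble(cells)
  if ("included" %in% names(cells)) cells <- dplyr::filter(cells, .data$included)
  cells <- dplyr::filter(cells, is.finite(.data[[response]]))
  needed <- c(response, "genotype", "age_group", "region")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) abort(sprintf("Missing column(s): %s", paste(missing, collapse = ", ")))
  regions <- regions %||% unique(cells$region)

  anova_rows <- list()
  pair_rows <- list()
  for (reg in regions) {
    dat <- cells[cells$region == reg, ]
    dat$genotype <- factor(dat$genotype)
    dat$age_group <- factor(dat$age_group)
    counts <- table(dat$genotype, dat$age_group)
    complete <- nlevels(dat$genotype) == 2 && nlevels(dat$age_group) == 2 &&
      all(counts > 0) && sum(counts > 1) >= 1 && nrow(dat) > 4
    if (!complete) {
      anova_rows[[reg]] <- tibble(region = reg,
                                  term = c("genotype", "age_group", "genotype:age_group"),
                                  df = NA_real_, statistic = NA_real_, p = NA_real_)
      next
    }
    fml <- stats::as.formula(paste(response, "~ genotype * age_group"))
    fit <- withr::with_options(
      list(contrasts = c("contr.sum", "contr.poly")),
      stats::lm(fml, data = dat)
    )
    a3 <- car::Anova(fit, type = 3)
    terms_keep <- c("genotype", "age_group", "genotype:age_group")
    a3 <- a3[rownames(a3) %in% terms_keep, ]
    anova_rows[[reg]] <- tibble(
      region = reg, term = rownames(a3), df = a3$Df,
      statistic = a3$`F value`, p = a3$`Pr(>F)`
    )

    gsum <- dat |>
      dplyr::group_by(.data$genotype, .data$age_group) |>
      dplyr::summarise(mean = mean(.data[[response]]),
                       sd = stats::sd(.data[[response]]),
                       n = dplyr::n(), .groups = "drop")
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    df_res <- stats::df.residual(fit)
    combos <- utils::combn(nrow(gsum), 2)
    pw <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
      i1 <- combos[1, j]; i2 <- combos[2, j]
      g1 <- gsum[i1, ]; g2 <- gsum[i2, ]
      est <- g1$mean - g2$mean
      se <- sqrt(mse * (1 / g1$n + 1 / g2$n))
      tval <- est / se
      p <- 2 * stats::pt(-abs(tval), df_res)
      type <- if (g1$genotype == g2$genotype) "age"
      else if (g1$age_group == g2$age_group) "genotype" else "both"
      tibble(
        region = reg,
        contrast = sprintf("%s.%s - %s.%s", g1$genotype, g1$age_group,
                           g2$genotype, g2$age_group),
        contrast_type = type,
        mean_1 = g1$mean, sd_1 = g1$sd, n_1 = g1$n,
        mean_2 = g2$mean, sd_2 = g2$sd, n_2 = g2$n,
        estimate = est, se = se, t = tval, df = df_res, p = p
      )
    })
    pw$p_adj <- holm_sidak_adjust(pw$p)
    pw$marker <- vapply(seq_len(nrow(pw)), function(i) {
      significance_marker(pw$p_adj[i], pw$contrast_type[i])
    }, character(1))
    pair_rows[[reg]] <- pw
  }

  structure(
    list(
      anova = dplyr::bind_rows(anova_rows),
      pairwise = dplyr::bind_rows(pair_rows),
      response = response,
      method = "two-way ANOVA (Type III) + all-pairwise Holm-Sidak"
    ),
    class = "redox_comparison"
  )
}

#' @export
print.redox_comparison <- function(x, ...) {
  cat("<redox_comparison>", x$method, "\n")
  cat("ANOVA terms:\n"); print(x$anova, n = 12)
  cat("Pairwise contrasts:\n")
  print(dplyr::select(x$pairwise, "region", "contrast", "p", "p_adj", "marker"), n = 12)
  invisible(x)
}

#' Welch's unequal-variance t-test between two groups
#'
#' Plain Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, computed explicitly so tests can cross-check it
#' against `stats::t.test()`.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2 with nonzero variance.
#' @return A tibble: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `estimate` (mean_a - mean_b), `t`, `df`, `p`, `marker` (##-style,
#'   genotype-family symbol).
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) abort("Welch's test needs n >= 2 per group.")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(mean_a = mean(a), sd_a = 0, n_a = length(a),
                    mean_b = mean(b), sd_b = 0, n_b = length(b),
                    estimate = 0, t = 0, df = length(a) + length(b) - 2,
                    p = 1, marker = ""))
    }
    abort("Degenerate variance in both groups with unequal means.")
  }
  if (va == 0) abort("Degenerate (zero) variance in group_a.")
  if (vb == 0) abort("Degenerate (zero) variance in group_b.")
  sa2 <- va / length(a); sb2 <- vb / length(b)
  tval <- (mean(a) - mean(b)) / sqrt(sa2 + sb2)
  df <- (sa2 + sb2)^2 / (sa2^2 / (length(a) - 1) + sb2^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
         mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
         estimate = mean(a) - mean(b), t = tval, df = df, p = p,
         marker = significance_marker(p, "genotype"))
}
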