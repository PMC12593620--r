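#' Calibration parameters of the ratiometric roGFP response range
#'
#' Holds the three constants that map a fluorescence ratio R = F740/F910 onto
#' a relative degree of oxidation: the fully oxidized ratio `r_ox` (strong
#' oxidant endpoint), the fully reduced ratio `r_red` (strong reductant
#' endpoint) and the instrument factor (the ratio of F910 intensities between
#' the two states, an optics- and wavelength-dependent constant), together
#' with their across-cell standard deviations and cell counts.
#'
#' @param r_ox,r_red Unitless endpoint ratios; must satisfy `r_ox > r_red > 0`.
#' @param instrument_factor Unitless F910_ox / F910_red; must be positive.
#' @param sd_r_ox,sd_r_red,sd_if Across-cell standard deviations (default 0).
#' @param n_ox,n_red Number of cells behind each endpoint (default 1).
#' @return An object of class `calibration_params`.
#' @examples
#' # A realistic calibration for cytosolic roGFP in acute slices:
#' calibration_params(r_ox = 0.916, r_red = 0.408, instrument_factor = 0.497)
#' @export
calibration_params <- function(r_ox, r_red, instrument_factor,
                               sd_r_ox = 0, sd_r_red = 0, sd_if = 0,
                               n_ox = 1L, n_red = 1L) {
  stopifnot_scalar_number(r_ox, "r_ox", positive = TRUE)
  stopifnot_scalar_number(r_red, "r_red", positive = TRUE)
  stopifnot_scalar_number(instrument_factor, "instrument_factor", positive = TRUE)
  if (r_ox <= r_red) abort("Invalid calibration: need r_ox > r_red.")
  if (any(c(sd_r_ox, sd_r_red, sd_if) < 0)) abort("Calibration SDs must be >= 0.")
  if (n_ox < 1 || n_red < 1) abort("Calibration cell counts must be >= 1.")
  structure(
    list(r_ox = r_ox, r_red = r_red, instrument_factor = instrument_factor,
         sd_r_ox = sd_r_ox, sd_r_red = sd_r_red, sd_if = sd_if,
         n_ox = as.integer(n_ox), n_red = as.integer(n_red)),
    class = "calibration_params"
  )
}

as_calibration_params <- function(x) {
  if (inherits(x, "calibration_params")) return(x)
  if (is.list(x) && all(c("r_ox", "r_red", "instrument_factor") %in% names(x))) {
    return(calibration_params(
      r_ox = x$r_ox, r_red = x$r_red, instrument_factor = x$instrument_factor,
      sd_r_ox = x$sd_r_ox %||% 0, sd_r_red = x$sd_r_red %||% 0,
      sd_if = x$sd_if %||% 0, n_ox = x$n_ox %||% 1L, n_red = x$n_red %||% 1L
    ))
  }
  abort("Cannot interpret `calib`: supply calibration_params() or a named list.")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_params <- function(x, ...) {
  cat("<calibration_params>\n")
  cat(sprintf("  R_ox  = %.4g +/- %.3g (n = %d)\n", x$r_ox, x$sd_r_ox, x$n_ox))
  cat(sprintf("  R_red = %.4g +/- %.3g (n = %d)\n", x$r_red, x$sd_r_red, x$n_red))
  cat(sprintf("  instrument factor = %.4g +/- %.3g\n", x$instrument_factor, x$sd_if))
  invisible(x)
}

#' Estimate the calibration triple from endpoint ROI measurements
#'
#' Takes per-cell ROI measurements recorded at full oxidation (H2O2-treated
#' slice) and at full reduction (DTT-treated, same slice after wash-out) and
#' estimates `r_ox`, `r_red` and the instrument factor. With
#' `pairing = "matched"` the instrument factor is the mean of per-cell
#' F910_ox/F910_red quotients, which cancels per-cell expression level; cells
#' are paired by shared `cell_id` or, when the two tables carry disjoint ids
#' but positions, by mutual-nearest-neighbour matching within `match_radius`
#' pixels. With `pairing = "unmatched"` it is the quotient of the two group
#' mean F910 intensities.
#'
#' @param ox_measurements,red_measurements Data frames of ROI measurements
#'   ([measure_rois()] output) for the fully oxidized and fully reduced
#'   recordings; need columns `ratio`, `f910_mean` and (for positional
#'   matching) `x`, `y`, `cell_id`.
#' @param pairing `"matched"` (default) or `"unmatched"`.
#' @param match_radius Maximum centre distance in pixels for positional
#'   pairing (default 5).
#' @return A [calibration_params()] with SDs and cell counts filled in.
#' @export
estimate_calibration <- function(ox_measurements, red_measurements,
                                 pairing = c("matched", "unmatched"),
                                 match_radius = 5) {
  pairing <- match.arg(pairing)
  ox <- as_tibble(ox_measurements)
  red <- as_tibble(red_measurements)
  for (tab in list(ox, red)) {
    if (!all(c("ratio", "f910_mean") %in% names(tab))) {
      abort("Endpoint measurements need `ratio` and `f910_mean` columns.")
    }
  }
  ox <- dplyr::filter(ox, is.finite(.data$ratio))
  red <- dplyr::filter(red, is.finite(.data$ratio))
  if (nrow(ox) < 1 || nrow(red) < 1) abort("Need >= 1 valid measurement per endpoint.")

  r_ox <- mean(ox$ratio)
  r_red <- mean(red$ratio)
  if (r_ox <= 0 || r_red <= 0) abort("Endpoint mean ratios must be positive.")

  if (pairing == "matched") {
    # positional pairing first: auto-generated ROI ids are positional labels
    # that can collide across recordings without denoting the same cell
    if (all(c("x", "y") %in% names(ox)) && all(c("x", "y") %in% names(red))) {
      m <- match_points(ox$x, ox$y, red$x, red$y, radius = match_radius)
      if (nrow(m) < 1) abort("Matched pairing requested but no cells could be paired.")
      f_ox <- ox$f910_mean[m$i]
      f_red <- red$f910_mean[m$j]
    } else if (length(intersect(ox$cell_id, red$cell_id)) >= 1) {
      shared <- intersect(ox$cell_id, red$cell_id)
      f_ox <- ox$f910_mean[match(shared, ox$cell_id)]
      f_red <- red$f910_mean[match(shared, red$cell_id)]
    } else {
      abort("Matched pairing requires shared cell ids or x/y positions in both tables.")
    }
    quot <- f_ox / f_red
    instrument_factor <- mean(quot)
    sd_if <- if (length(quot) > 1) stats::sd(quot) else 0
  } else {
    instrument_factor <- mean(ox$f910_mean) / mean(red$f910_mean)
    sd_if <- 0
  }

  calibration_params(
    r_ox = r_ox, r_red = r_red, instrument_factor = instrument_factor,
    sd_r_ox = if (nrow(ox) > 1) stats::sd(ox$ratio) else 0,
    sd_r_red = if (nrow(red) > 1) stats::sd(red$ratio) else 0,
    sd_if = sd_if, n_ox = nrow(ox), n_red = nrow(red)
  )
}

# Greedy mutual nearest-neighbour matching between two point sets; returns a
# tibble of (i, j, dist) with each point used at most once.
match_points <- function(x1, y1, x2, y2, radius) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) return(tibble(i = integer(), j = integer(), dist = numeric()))
  d <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  d <- sqrt(d)
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  repeat {
    k <- which.min(d)
    if (length(k) == 0 || !is.finite(d[k]) || d[k] > radius) break
    i <- ((k - 1) %% n1) + 1
    j <- ((k - 1) %/% n1) + 1
    out_i <- c(out_i, i); out_j <- c(out_j, j); out_d <- c(out_d, d[k])
    d[i, ] <- Inf
    d[, j] <- Inf
    if (length(out_i) == min(n1, n2)) break
  }
  tibble(i = out_i, j = out_j, dist = out_d)
}

#' Convert fluorescence ratios to relative degrees of oxidation (OxD)
#'
#' Applies the standard roGFP calibration formula
#' \deqn{OxD = \frac{R - R_{red}}{IF\,(R_{ox} - R) + (R - R_{red})}}
#' where IF is the instrument factor F910_ox/F910_red. On the open interval
#' (R_red, R_ox) the output lies in (0, 1) and is strictly increasing in R.
#' Ratios outside the calibrated range are still evaluated (the result falls
#' outside \[0, 1\]); screening such cells is the job of [filter_intact()],
#' not of the conversion. Where the denominator is non-positive (possible
#' only for R far above R_ox) the result is `NA` rather than an error.
#'
#' @param r Numeric vector of unitless F740/F910 ratios.
#' @param calib A [calibration_params()].
#' @return Numeric vector of OxD values (unitless; `NA` where undefined).
#' @examples
#' cal <- calibration_params(0.916, 0.408, 0.497)
#' oxd_from_ratio(c(0.408, 0.662, 0.916), cal)
#' @export
oxd_from_ratio <- function(r, calib) {
  calib <- as_calibration_params(calib)
  den <- calib$instrument_factor * (calib$r_ox - r) + (r - calib$r_red)
  out <- (r - calib$r_red) / den
  out[!is.finite(r) | den <= 0] <- NA_real_
  out
}

#' Expected ratio at a given degree of oxidation (inverse of [oxd_from_ratio()])
#'
#' Analytic inverse of the calibration formula:
#' \deqn{R(OxD) = \frac{IF\,R_{ox}\,OxD + R_{red}(1-OxD)}{IF\,OxD + (1-OxD)}}
#' Round-trips with [oxd_from_ratio()] to machine precision.
#'
#' @param oxd Numeric vector in \[0, 1\].
#' @param calib A [calibration_params()].
#' @return Numeric vector of ratios.
#' @export
ratio_from_oxd <- function(oxd, calib) {
  calib <- as_calibration_params(calib)
  if (!is.numeric(oxd) || any(!is.finite(oxd)) || any(oxd < 0 | oxd > 1)) {
    abort("`oxd` must be numeric in [0, 1].")
  }
  f <- calib$instrument_factor
  (f * calib$r_ox * oxd + calib$r_red * (1 - oxd)) / (f * oxd + (1 - oxd))
}

#' Monte-Carlo propagation of calibration uncertainty into OxD
#'
#' The three calibration constants are reported with across-cell SDs. This
#' draws calibration triples from independent normals, discards physically
#' invalid draws (`r_ox <= r_red`, non-positive values, undefined OxD) and
#' summarizes the spread of the resulting OxD at the given ratio.
#'
#' @param r A single ratio.
#' @param calib A [calibration_params()] with SDs.
#' @param n_draws Number of Monte-Carlo draws (>= 100; default 2000).
#' @param seed Integer seed for reproducibility (default 1).
#' @return A tibble with `oxd` (point estimate at the mean calibration),
#'   `median`, `lower`, `upper` (central 95% interval) and `n_valid`.
#' @export
propagate_calibration_uncertainty <- function(r, calib, n_draws = 2000, seed = 1L) {
  calib <- as_calibration_params(calib)
  stopifnot_scalar_number(r, "r")
  if (n_draws < 100) abort("`n_draws` must be >= 100.")
  draws <- with_stream(seed, "calib_mc", 0L, {
    tibble(
      r_ox = stats::rnorm(n_draws, calib$r_ox, calib$sd_r_ox),
      r_red = stats::rnorm(n_draws, calib$r_red, calib$sd_r_red),
      instrument_factor = stats::rnorm(n_draws, calib$instrument_factor, calib$sd_if)
    )
  })
  ok <- draws$r_ox > draws$r_red & draws$r_red > 0 & draws$instrument_factor > 0
  den <- draws$instrument_factor * (draws$r_ox - r) + (r - draws$r_red)
  ok <- ok & den > 0
  if (mean(ok) < 0.5) {
    abort("Calibration too uncertain: more than half of the Monte-Carlo draws are invalid.")
  }
  oxd_draws <- (r - draws$r_red[ok]) / den[ok]
  qs <- stats::quantile(oxd_draws, c(0.025, 0.5, 0.975), names = FALSE)
  tibble(
    r = r,
    oxd = oxd_from_ratio(r, calib),
    median = qs[2], lower = qs[1], upper = qs[3],
    n_valid = sum(ok), n_draws = n_draws
  )
}

#' Read or write a calibration record as YAML
#'
#' @param calib A [calibration_params()].
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a [calibration_params()].
#' @export
write_calibration <- function(calib, path) {
  calib <- as_calibration_params(calib)
  yaml::write_yaml(unclass(calib), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  as_calibration_params(yaml::read_yaml(path))
}
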