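#' Linear two-state fluorophore emission model
#'
#' roGFP is modelled as a two-state sensor: every molecule is either oxidized
#' or reduced, and each state emits linearly in both excitation channels. The
#' model holds four emission coefficients: `a_ox` and `a_red` for the F740
#' channel (740 nm excitation) and `b_ox` and `b_red` for the F910 channel
#' (910 nm excitation). Its three derived constants are exactly the
#' calibration triple used for OxD conversion:
#' \deqn{R_{ox} = a_{ox}/b_{ox}, \quad R_{red} = a_{red}/b_{red}, \quad
#'       IF = b_{ox}/b_{red}}
#' so that inverting the model's expected ratio is the OxD formula of
#' [oxd_from_ratio()] — the generator and the analysis are algebraic inverses
#' by construction.
#'
#' @param a_ox,a_red Emission coefficients of the oxidized and reduced species
#'   in the F740 channel (arbitrary fluorescence units per unit sensor).
#' @param b_ox,b_red Same for the F910 channel.
#' @return An object of class `fluorophore_model`.
#' @examples
#' m <- fluorophore_model(a_ox = 0.455252, a_red = 0.408, b_ox = 0.497, b_red = 1)
#' expected_ratio(m, c(0, 0.5, 1))
#' @export
fluorophore_model <- function(a_ox, a_red, b_ox, b_red) {
  for (nm in c("a_ox", "a_red", "b_ox", "b_red")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (a_ox / b_ox <= a_red / b_red) {
    abort("Oxidation must raise the F740/F910 ratio: need a_ox/b_ox > a_red/b_red.")
  }
  structure(
    list(a_ox = a_ox, a_red = a_red, b_ox = b_ox, b_red = b_red),
    class = "fluorophore_model"
  )
}

#' @export
print.fluorophore_model <- function(x, ...) {
  cat("<fluorophore_model>\n")
  cat(sprintf("  F740: a_ox = %.6g, a_red = %.6g\n", x$a_ox, x$a_red))
  cat(sprintf("  F910: b_ox = %.6g, b_red = %.6g\n", x$b_ox, x$b_red))
  tr <- model_calibration_triple(x)
  cat(sprintf("  derived: R_ox = %.4g, R_red = %.4g, instrument factor = %.4g\n",
              tr$r_ox, tr$r_red, tr$instrument_factor))
  invisible(x)
}

# Calibration triple implied by a forward model.
model_calibration_triple <- function(model) {
  list(
    r_ox = model$a_ox / model$b_ox,
    r_red = model$a_red / model$b_red,
    instrument_factor = model$b_ox / model$b_red
  )
}

#' Build the forward emission model implied by a calibration triple
#'
#' Inverts a measured calibration (R_ox, R_red, instrument factor) into
#' emission coefficients. The absolute brightness scale is not identifiable
#' from ratios, so `b_red_scale` fixes the reduced-state F910 coefficient:
#' `a_ox = R_ox * IF * b_red_scale`, `a_red = R_red * b_red_scale`,
#' `b_ox = IF * b_red_scale`, `b_red = b_red_scale`.
#'
#' @param calib A [calibration_params()] object (only the three point
#'   estimates are used).
#' @param b_red_scale Positive brightness scale of the reduced species in
#'   F910; default 1.
#' @return A [fluorophore_model()] whose derived triple reproduces `calib`
#'   exactly.
#' @export
make_fluorophore_model <- function(calib, b_red_scale = 1) {
  calib <- as_calibration_params(calib)
  stopifnot_scalar_number(b_red_scale, "b_red_scale", positive = TRUE)
  fluorophore_model(
    a_ox = calib$r_ox * calib$instrument_factor * b_red_scale,
    a_red = calib$r_red * b_red_scale,
    b_ox = calib$instrument_factor * b_red_scale,
    b_red = b_red_scale
  )
}

#' Expected F740/F910 ratio at a given degree of oxidation
#'
#' Forward model: a fraction `oxd` of sensor molecules is oxidized, so the
#' expected channel intensities are mixtures of the two species and the ratio
#' is \deqn{R(OxD) = \frac{a_{ox} OxD + a_{red}(1-OxD)}
#'                        {b_{ox} OxD + b_{red}(1-OxD)}.}
#' The function is strictly increasing in `oxd` and maps 0 to R_red and 1 to
#' R_ox.
#'
#' @param model A [fluorophore_model()].
#' @param oxd Degree(s) of oxidation in \[0, 1\]; vectorized.
#' @return Numeric vector of unitless ratios.
#' @export
expected_ratio <- function(model, oxd) {
  stopifnot(inherits(model, "fluorophore_model"))
  if (!is.numeric(oxd) || any(!is.finite(oxd)) || any(oxd < 0 | oxd > 1)) {
    abort("`oxd` must be numeric in [0, 1].")
  }
  (model$a_ox * oxd + model$a_red * (1 - oxd)) /
    (model$b_ox * oxd + model$b_red * (1 - oxd))
}

# Expected per-channel intensities (relative to the reduced-state F910
# brightness) — used by the renderer so that the ratio of the two channel
# amplitudes is exactly expected_ratio(oxd).
expected_channel_intensities <- function(model, oxd) {
  list(
    f740 = (model$a_ox * oxd + model$a_red * (1 - oxd)) / model$b_red,
    f910 = (model$b_ox * oxd + model$b_red * (1 - oxd)) / model$b_red
  )
}
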