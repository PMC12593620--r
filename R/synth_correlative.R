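#' Simulate one correlative live/fixed field pair of a mosaic slice
#'
#' Generates the inputs of the correlative redox-microscopy stage for one
#' brain slice of a mosaic (Mecp2 heterozygous) animal:
#'
#' * a live ratiometric field (F740/F910) with a bleach-mark fiducial and a
#'   mixture of MeCP2-positive and MeCP2-deficient somata, and
#' * the corresponding fixed field (channels `nuclear`, `immunolabel`,
#'   `structural`) of the same cells, translated by an integer pixel shift
#'   (re-mounting of the stained slice) with the bleach mark shifted along.
#'
#' The correlative stage operates on raw ratios (its optical conditions are
#' not covered by the live calibration), so the generator controls ratios
#' directly: positive cells draw ratios around the slice's base ratio with
#' relative spread `sd_positive`, and each deficient cell's true ratio is
#' the slice's positive-cell mean ratio times `effect`, with additive spread
#' `sd_deficient` on the normalized scale. The pooled normalized deficient
#' mean therefore has expectation `effect`.
#'
#' @param scenario A [sim_scenario()] (photon/noise model and geometry).
#' @param slice_id Slice label.
#' @param n_positive,n_deficient Cells per class in this slice.
#' @param effect Deficient-to-positive mean ratio effect (default 1.101).
#' @param sd_positive Relative SD of positive-cell ratios (default 0.311).
#' @param sd_deficient SD of deficient normalized ratios (default 0.348).
#' @param base_oxd Mean degree of oxidation setting the slice's base ratio
#'   (default 0.52, a typical cortical baseline); the slice's base ratio is
#'   `ratio_from_oxd(base_oxd)` under the scenario calibration.
#' @param shift Integer `c(dx, dy)` translation of the fixed field; drawn
#'   uniformly from \[-8, 8\] per axis when `NULL`.
#' @param mark_size Bleach-mark side length in pixels (default 40).
#' @param label_contrast Immunolabel intensity contrast positive:deficient
#'   (default 10).
#' @param seed Override of the scenario seed.
#' @return List with `live`, `fixed` ([field_image()]s) and `truth` (tibble:
#'   cell_id, x, y, radius, ratio_true, mecp2_positive, slice_id, shift_x,
#'   shift_y).
#' @export
simulate_correlative_slice <- function(scenario, slice_id = "s1",
                                       n_positive = 11, n_deficient = 19,
                                       effect = 1.101,
                                       sd_positive = 0.311,
                                       sd_deficient = 0.348,
                                       base_oxd = 0.52,
                                       shift = NULL,
                                       mark_size = 40,
                                       label_contrast = 10,
                                       seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- seed %||% scenario$seed
  n <- n_positive + n_deficient
  idx <- (sum(utf8ToInt(slice_id)) %% 9973L)

  # field large enough for the somata plus the fiducial keep-out
  need <- ceiling(sqrt(n * (4 * scenario$soma_radius)^2 * 2.5 + (mark_size + 20)^2))
  sc <- scenario
  sc$image_size <- max(scenario$image_size, need)

  shift <- shift %||% with_stream(seed, "shift", idx,
                                  sample(-8:8, 2, replace = TRUE))
  shift <- as.integer(round(shift))
  mark <- list(x = 10, y = 10, size = mark_size)  # stays in bounds after any |shift| <= 8

  margin <- max(abs(shift)) + 6
  cells <- with_stream(seed, "corr_placement", idx,
                       place_somata(n, sc$image_size, scenario$soma_radius,
                                    keep_out = mark, margin = margin))
  status <- with_stream(seed, "corr_status", idx,
                        sample(c(rep(TRUE, n_positive), rep(FALSE, n_deficient))))

  base_ratio <- ratio_from_oxd(base_oxd, scenario$calib)
  ratios <- with_stream(seed, "corr_ratio", idx, {
    r <- numeric(n)
    r[status] <- base_ratio * (1 + stats::rnorm(n_positive, 0, sd_positive))
    r[status] <- pmax(r[status], 0.1 * base_ratio)
    pos_mean <- mean(r[status])
    r[!status] <- pos_mean * (effect + stats::rnorm(n_deficient, 0, sd_deficient))
    r[!status] <- pmax(r[!status], 0.1 * base_ratio)
    r
  })

  bright <- with_stream(seed, "corr_expression", idx,
                        stats::rlnorm(n, -scenario$expression_sd^2 / 2,
                                      scenario$expression_sd))
  cells$f910_amp <- scenario$photon_scale * bright
  cells$f740_amp <- ratios * cells$f910_amp

  live <- render_ratiometric_field(sc, cells,
                                   metadata = list(slice_id = slice_id, state = "baseline"),
                                   seed = seed, stream_index = idx + 1L)
  live <- stamp_bleach_mark(live, c(mark$x, mark$y), mark$size)

  # fixed field: same content translated by `shift`
  fx <- cells$x + shift[1]
  fy <- cells$y + shift[2]
  nsz <- sc$image_size
  nuc_r <- pmax(cells$radius * 0.55, 2.5)
  lab_base <- with_stream(seed, "corr_label", idx,
                          stats::rlnorm(n, 0, 0.25))
  nuclear <- matrix(scenario$background, nsz, nsz)
  nuclear <- add_disks(nuclear, fx, fy, nuc_r, 1500 * lab_base)
  immuno <- matrix(scenario$background, nsz, nsz)
  immuno <- add_disks(immuno, fx, fy, nuc_r,
                      ifelse(status, 80 * label_contrast, 80) * lab_base)
  structural <- matrix(scenario$background, nsz, nsz)
  structural <- add_disks(structural, fx, fy, cells$radius, 0.6 * cells$f910_amp)
  if (scenario$noise) {
    nuclear <- with_stream(seed, "noise_nuc", idx, apply_noise(nuclear, scenario$read_noise_sd))
    immuno <- with_stream(seed, "noise_imm", idx, apply_noise(immuno, scenario$read_noise_sd))
    structural <- with_stream(seed, "noise_struct", idx, apply_noise(structural, scenario$read_noise_sd))
  }
  fixed <- field_image(
    list(nuclear = nuclear, immunolabel = immuno, structural = structural),
    metadata = list(slice_id = slice_id, state = "fixed")
  )
  fixed <- stamp_bleach_mark(fixed, c(mark$x + shift[1], mark$y + shift[2]), mark$size)

  truth <- tibble(
    cell_id = sprintf("%s_c%03d", slice_id, seq_len(n)),
    x = cells$x, y = cells$y, radius = cells$radius,
    ratio_true = ratios, mecp2_positive = status,
    slice_id = slice_id, shift_x = shift[1], shift_y = shift[2]
  )
  list(live = live, fixed = fixed, truth = truth)
}
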