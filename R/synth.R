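#' Default ground-truth OxD distributions per region, genotype and age
#'
#' Tissue-slice level mean degrees of oxidation for ten brain regions in
#' wildtype and Mecp2 heterozygous female mice at two maturational stages
#' (young adult p50 and mature >p100), as measured for cytosolic roGFP in
#' acute slices. Cell-level SDs are broader than slice-level SDs; where a
#' cell-level dispersion was measured (CA1 and dentate gyrus at p50 in WT)
#' it is used, elsewhere a typical cell-level SD of 0.15 is assumed.
#'
#' @return A tibble with columns `region`, `genotype`, `age_group`,
#'   `oxd_mean`, `oxd_sd`.
#' @export
default_oxd_groups <- function() {
  g <- tidyr::expand_grid(
    region = c("CA1", "CA3", "DG", "S", "visual", "auditory",
               "somatosensory", "RSA", "Ect", "motor"),
    genotype = c("WT", "Mecp2+/-"),
    age_group = c("p50", "gt_p100")
  )
  means <- c(
    CA1 = NA, CA3 = NA, DG = NA, S = NA, visual = NA,
    auditory = NA, somatosensory = NA, RSA = NA, Ect = NA, motor = NA
  )
  # slice-level group means: region x (WT p50, het p50, WT >p100, het >p100)
  tab <- list(
    CA1           = c(0.452, 0.428, 0.337, 0.409),
    CA3           = c(0.719, 0.664, 0.689, 0.770),
    DG            = c(0.747, 0.721, 0.660, 0.743),
    S             = c(0.699, 0.551, 0.540, 0.557),
    visual        = c(0.568, 0.557, 0.446, 0.549),
    auditory      = c(0.632, 0.535, 0.411, 0.537),
    somatosensory = c(0.593, 0.525, 0.465, 0.518),
    RSA           = c(0.571, 0.573, 0.493, 0.621),
    Ect           = c(0.702, 0.621, 0.495, 0.610),
    motor         = c(0.628, 0.553, 0.450, 0.575)
  )
  g$oxd_mean <- purrr::pmap_dbl(g, function(region, genotype, age_group) {
    i <- if (genotype == "WT" && age_group == "p50") 1L
    else if (genotype != "WT" && age_group == "p50") 2L
    else if (genotype == "WT") 3L else 4L
    tab[[region]][i]
  })
  g$oxd_sd <- 0.15
  # measured cell-level distributions (mean, SD) override where available
  g$oxd_mean[g$region == "CA1" & g$genotype == "WT" & g$age_group == "p50"] <- 0.466
  g$oxd_sd[g$region == "CA1" & g$genotype == "WT" & g$age_group == "p50"] <- 0.172
  g$oxd_mean[g$region == "DG" & g$genotype == "WT" & g$age_group == "p50"] <- 0.719
  g$oxd_sd[g$region == "DG" & g$genotype == "WT" & g$age_group == "p50"] <- 0.132
  g
}

#' Simulation scenario for synthetic redox-imaging data
#'
#' Bundles every knob of the synthetic-data generator: the ground-truth OxD
#' distribution per (region, genotype, age) group, field geometry, the
#' photon-limited noise model and the X-inactivation mosaic model. Defaults
#' reflect the study conditions of quantitative two-photon roGFP imaging in
#' acute mouse brain slices.
#'
#' @param groups Tibble of per-group OxD means/SDs ([default_oxd_groups()]).
#' @param calib Calibration triple the forward fluorophore model is built
#'   from; default `calibration_params(0.916, 0.408, 0.497)`.
#' @param cells_per_field Somata per simulated field (default 12).
#' @param image_size Field edge length in pixels (default 192); must be at
#'   least four soma diameters.
#' @param soma_radius Soma radius in pixels (default 7).
#' @param photon_scale Expected photon counts of a unit-brightness cell at
#'   OxD = 0 in the F910 channel (default 2000).
#' @param read_noise_sd Gaussian read-noise SD in counts (default 3).
#' @param background Uniform tissue background level in counts (default 20);
#'   bleach marks appear dark against it.
#' @param expression_sd Log-scale SD of the per-cell lognormal brightness
#'   factor (default 0.3); the mean brightness factor is 1.
#' @param mosaic_fraction Probability that an X-inactivation clone expresses
#'   MeCP2 (default 0.45).
#' @param clone_count Number of spatial progenitor clones per field
#'   (default 40).
#' @param mcat_effect Multiplicative scaling of the genotype OxD shift
#'   relative to WT (1 = full shift, 0 = shift abolished as under
#'   mitochondrial catalase expression).
#' @param oxd_trunc Truncation bounds of ground-truth OxD draws (default
#'   `c(0.02, 0.98)`, just inside the 5--95% analysis range, keeping the
#'   calibration formula well-conditioned).
#' @param noise Logical: apply Poisson shot noise and read noise (default
#'   TRUE). With `noise = FALSE` expected intensities are rendered exactly.
#' @param seed Integer master seed; all stages draw from substreams of it.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(groups = default_oxd_groups(),
                         calib = calibration_params(0.916, 0.408, 0.497),
                         cells_per_field = 12,
                         image_size = 192,
                         soma_radius = 7,
                         photon_scale = 2000,
                         read_noise_sd = 3,
                         background = 20,
                         expression_sd = 0.3,
                         mosaic_fraction = 0.45,
                         clone_count = 40,
                         mcat_effect = 1,
                         oxd_trunc = c(0.02, 0.98),
                         noise = TRUE,
                         seed = 1L) {
  calib <- as_calibration_params(calib)
  if (mosaic_fraction <= 0 || mosaic_fraction >= 1) abort("`mosaic_fraction` must be in (0, 1).")
  if (clone_count < 1) abort("`clone_count` must be >= 1.")
  stopifnot_scalar_number(photon_scale, "photon_scale", positive = TRUE)
  if (read_noise_sd < 0 || background < 0) abort("Noise parameters must be >= 0.")
  groups <- as_tibble(groups)
  if (any(groups$oxd_mean <= 0 | groups$oxd_mean >= 1)) {
    abort("All group OxD means must lie strictly inside (0, 1).")
  }
  if (image_size < 4 * (2 * soma_radius)) {
    abort("`image_size` must be at least four soma diameters.")
  }
  structure(
    list(groups = groups, calib = calib,
         model = make_fluorophore_model(calib),
         cells_per_field = cells_per_field, image_size = image_size,
         soma_radius = soma_radius, photon_scale = photon_scale,
         read_noise_sd = read_noise_sd, background = background,
         expression_sd = expression_sd, mosaic_fraction = mosaic_fraction,
         clone_count = clone_count, mcat_effect = mcat_effect,
         oxd_trunc = oxd_trunc, noise = isTRUE(noise), seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d px fields, %d cells/field, photon scale %g, seed %d\n",
              x$image_size, x$cells_per_field, x$photon_scale, x$seed))
  invisible(x)
}

scenario_group_row <- function(scenario, region, genotype, age_group) {
  g <- scenario$groups
  row <- g[g$region == region & g$genotype == genotype & g$age_group == age_group, ]
  if (nrow(row) != 1) {
    abort(sprintf("No unique group (%s, %s, %s) in scenario$groups.", region, genotype, age_group))
  }
  mu <- row$oxd_mean[[1]]
  # genotype OxD shift relative to WT, optionally suppressed (mCAT switch)
  if (genotype != "WT" && scenario$mcat_effect != 1) {
    wt <- g[g$region == region & g$genotype == "WT" & g$age_group == age_group, ]
    if (nrow(wt) == 1) mu <- wt$oxd_mean[[1]] + scenario$mcat_effect * (mu - wt$oxd_mean[[1]])
  }
  list(oxd_mean = mu, oxd_sd = row$oxd_sd[[1]])
}

# Non-overlapping circle packing by rejection sampling. `keep_out` is an
# optional list(x, y, size) rectangle (0-based) that centres must avoid.
place_somata <- function(n, image_size, radius, keep_out = NULL, margin = 4) {
  if (n == 0) return(tibble(x = numeric(), y = numeric(), radius = numeric()))
  lo <- radius + margin
  hi <- image_size - 1 - radius - margin
  if (hi <= lo) abort("Image too small for the requested soma radius.")
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; max_tries <- 2000L * n
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf("Infeasible packing: placed %d of %d somata of radius %g in a %d px field.",
                    length(xs), n, radius, image_size))
    }
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    if (!is.null(keep_out)) {
      pad <- radius + 2
      if (x >= keep_out$x - pad && x <= keep_out$x + keep_out$size + pad &&
          y >= keep_out$y - pad && y <= keep_out$y + keep_out$size + pad) next
    }
    if (length(xs) && any((xs - x)^2 + (ys - y)^2 < (2 * radius + 2)^2)) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  tibble(x = xs, y = ys, radius = radius)
}

# Add soft-edged disks to an image matrix. Coordinates are 0-based (x = col,
# y = row); the logistic edge (scale 0.7 px) stands in for the PSF.
add_disks <- function(img, x, y, radius, amplitude) {
  d <- dim(img)
  for (k in seq_along(x)) {
    r <- radius[k]
    rows <- max(1, floor(y[k] - r - 3) + 1):min(d[1], ceiling(y[k] + r + 3) + 1)
    cols <- max(1, floor(x[k] - r - 3) + 1):min(d[2], ceiling(x[k] + r + 3) + 1)
    dy <- (rows - 1) - y[k]
    dx <- (cols - 1) - x[k]
    dist <- sqrt(outer(dy^2, dx^2, "+"))
    img[rows, cols] <- img[rows, cols] + amplitude[k] / (1 + exp((dist - r) / 0.7))
  }
  img
}

# Shot noise + read noise + rounding to integer counts, clamped to 16 bits.
apply_noise <- function(expected, read_noise_sd) {
  counts <- stats::rpois(length(expected), lambda = pmax(expected, 0))
  counts <- counts + stats::rnorm(length(expected), 0, read_noise_sd)
  matrix(pmin(pmax(round(counts), 0), 65535), nrow = nrow(expected))
}

# Shared renderer: cells carry x, y, radius, f740_amp, f910_amp (expected
# peak counts). Returns a field_image with F740 and F910 channels.
render_ratiometric_field <- function(scenario, cells, metadata = list(),
                                     seed = scenario$seed, stream_index = 0L) {
  n <- scenario$image_size
  f740 <- matrix(scenario$background, n, n)
  f910 <- matrix(scenario$background, n, n)
  if (nrow(cells)) {
    f740 <- add_disks(f740, cells$x, cells$y, cells$radius, cells$f740_amp)
    f910 <- add_disks(f910, cells$x, cells$y, cells$radius, cells$f910_amp)
  }
  if (scenario$noise) {
    f740 <- with_stream(seed, "noise_f740", stream_index, apply_noise(f740, scenario$read_noise_sd))
    f910 <- with_stream(seed, "noise_f910", stream_index, apply_noise(f910, scenario$read_noise_sd))
  }
  field_image(list(F740 = f740, F910 = f910), metadata = metadata)
}

#' Simulate one ratiometric field with ground truth
#'
#' Places non-overlapping somata, draws each cell's true degree of oxidation
#' from the (region, genotype, age) ground-truth distribution (normal,
#' truncated to the scenario's `oxd_trunc` bounds), gives each cell a
#' lognormal expression-level factor, and renders the F740 and F910 channels
#' as photon-count images through the scenario's two-state fluorophore model
#' (Poisson shot noise, Gaussian read noise, uniform tissue background). The
#' two channels are pixel-registered by construction.
#'
#' @param scenario A [sim_scenario()].
#' @param slice_id,region,genotype,age_group Metadata labels; the group
#'   determines the OxD distribution.
#' @param field_id Field index within the slice (distinguishes random
#'   substreams of fields of one slice).
#' @param n_cells Number of somata (default `scenario$cells_per_field`).
#' @param oxd_values Optional explicit ground-truth OxD per cell (overrides
#'   the group draw; length `n_cells`).
#' @param seed Override of the scenario seed.
#' @return A list with `field` (a [field_image()]) and `truth` (a tibble:
#'   cell_id, x, y, radius, oxd_true, mecp2_positive, slice_id, region,
#'   genotype, age_group).
#' @export
simulate_field <- function(scenario, slice_id = "s1", region = "CA1",
                           genotype = "WT", age_group = "p50",
                           field_id = 1L, n_cells = NULL, oxd_values = NULL,
                           seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seed <- seed %||% scenario$seed
  n_cells <- n_cells %||% scenario$cells_per_field
  idx <- (sum(utf8ToInt(paste(slice_id, field_id))) %% 9973L) + 1000L * as.integer(field_id)

  cells <- with_stream(seed, "placement", idx,
                       place_somata(n_cells, scenario$image_size, scenario$soma_radius))
  if (is.null(oxd_values)) {
    grp <- scenario_group_row(scenario, region, genotype, age_group)
    oxd <- with_stream(seed, "oxd", idx,
                       rtruncnorm(n_cells, grp$oxd_mean, grp$oxd_sd,
                                  scenario$oxd_trunc[1], scenario$oxd_trunc[2]))
  } else {
    if (length(oxd_values) != n_cells) abort("`oxd_values` must have length `n_cells`.")
    if (any(oxd_values < 0 | oxd_values > 1)) abort("`oxd_values` must lie in [0, 1].")
    oxd <- oxd_values
  }
  bright <- with_stream(seed, "expression", idx,
                        stats::rlnorm(n_cells, -scenario$expression_sd^2 / 2,
                                      scenario$expression_sd))
  inten <- expected_channel_intensities(scenario$model, oxd)
  cells$f740_amp <- scenario$photon_scale * bright * inten$f740
  cells$f910_amp <- scenario$photon_scale * bright * inten$f910

  metadata <- list(slice_id = slice_id, region = region, genotype = genotype,
                   age_group = age_group, state = "baseline", field_id = field_id)
  field <- render_ratiometric_field(scenario, cells, metadata, seed, idx)

  truth <- tibble(
    cell_id = if (n_cells) sprintf("%s_f%d_c%03d", slice_id, field_id, seq_len(n_cells)) else character(),
    x = cells$x, y = cells$y, radius = cells$radius,
    oxd_true = oxd, brightness = bright,
    mecp2_positive = rep(NA, n_cells),
    slice_id = slice_id, region = region, genotype = genotype,
    age_group = age_group, field_id = field_id
  )
  list(field = field, truth = truth)
}

#' Assign mosaic MeCP2 expression status through a spatial clone model
#'
#' Random X-inactivation happens in a small pool of progenitors, so
#' expression status is clonal and spatially patchy rather than independent
#' per cell. `clone_count` seed points are scattered over the cells' extent,
#' each cell joins its nearest clone, and each clone is MeCP2-positive with
#' probability `mosaic_fraction`. With `clone_count` much larger than the
#' number of cells this degenerates to independent Bernoulli labels; the
#' expected positive fraction is `mosaic_fraction` in all cases.
#'
#' @param cells Tibble with `x`, `y` columns (e.g. a truth table).
#' @param mosaic_fraction Probability in (0, 1) that a clone is positive.
#' @param clone_count Number of progenitor clones (>= 1).
#' @param seed Integer seed.
#' @return The input tibble with `mecp2_positive` (logical) and `clone`
#'   (integer) columns set.
#' @export
simulate_mosaic_labels <- function(cells, mosaic_fraction = 0.45,
                                   clone_count = 40, seed = 1L) {
  if (mosaic_fraction <= 0 || mosaic_fraction >= 1) abort("`mosaic_fraction` must be in (0, 1).")
  if (clone_count < 1) abort("`clone_count` must be >= 1.")
  cells <- as_tibble(cells)
  n <- nrow(cells)
  if (n == 0) {
    cells$mecp2_positive <- logical()
    cells$clone <- integer()
    return(cells)
  }
  res <- with_stream(seed, "mosaic", 0L, {
    xr <- range(cells$x); yr <- range(cells$y)
    cx <- stats::runif(clone_count, xr[1], xr[2] + 1e-9)
    cy <- stats::runif(clone_count, yr[1], yr[2] + 1e-9)
    status <- stats::runif(clone_count) < mosaic_fraction
    # chunked nearest-seed search keeps the distance matrix bounded
    chunk <- max(1L, floor(2e6 / clone_count))
    clone <- integer(n)
    for (start in seq(1, n, by = chunk)) {
      idx <- start:min(start + chunk - 1, n)
      d2 <- outer(cells$x[idx], cx, "-")^2 + outer(cells$y[idx], cy, "-")^2
      clone[idx] <- max.col(-d2, ties.method = "first")
    }
    list(clone = clone, status = status)
  })
  cells$clone <- res$clone
  cells$mecp2_positive <- res$status[res$clone]
  cells
}

#' Simulate calibration endpoint recordings (full oxidation / full reduction)
#'
#' Renders the same field of cells twice: once with every sensor molecule
#' oxidized (strong oxidant endpoint, OxD = 1) and once fully reduced
#' (strong reductant endpoint, OxD = 0), with per-cell lognormal brightness
#' shared between the two states so the instrument factor is estimable from
#' matched per-cell F910 intensities. Cell counts may differ between states
#' (cells beyond the smaller count are present only in one state), matching
#' the situation that not every cell is recovered in both recordings.
#'
#' @param scenario A [sim_scenario()]; its `calib`/`model` defines the truth.
#' @param n_ox_cells,n_red_cells Cells visible in the oxidized and reduced
#'   recordings (>= 1 each).
#' @param image_size Edge length of the (larger) calibration field; default
#'   chosen to fit the requested cell count.
#' @param seed Override of the scenario seed.
#' @return List with `ox` and `red` ([field_image()]s), and `truth` (tibble:
#'   cell_id, x, y, radius, brightness, in_ox, in_red).
#' @export
simulate_calibration_endpoints <- function(scenario, n_ox_cells = 76,
                                           n_red_cells = 78,
                                           image_size = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (n_ox_cells < 1 || n_red_cells < 1) abort("Need >= 1 cell per endpoint.")
  seed <- seed %||% scenario$seed
  n <- max(n_ox_cells, n_red_cells)
  image_size <- image_size %||% max(scenario$image_size,
                                    ceiling(sqrt(n * (4 * scenario$soma_radius)^2 * 2.5)))
  sc <- scenario
  sc$image_size <- image_size

  cells <- with_stream(seed, "calib_placement", 0L,
                       place_somata(n, image_size, scenario$soma_radius))
  bright <- with_stream(seed, "calib_expression", 0L,
                        stats::rlnorm(n, -scenario$expression_sd^2 / 2,
                                      scenario$expression_sd))
  ids <- sprintf("calib_c%03d", seq_len(n))

  render_state <- function(keep, oxd, state, stream_index) {
    inten <- expected_channel_intensities(scenario$model, oxd)
    cc <- cells[keep, ]
    cc$f740_amp <- scenario$photon_scale * bright[keep] * inten$f740
    cc$f910_amp <- scenario$photon_scale * bright[keep] * inten$f910
    render_ratiometric_field(sc, cc,
                             metadata = list(slice_id = "calib", state = state),
                             seed = seed, stream_index = stream_index)
  }
  ox <- render_state(seq_len(n_ox_cells), 1, "H2O2", 1L)
  red <- render_state(seq_len(n_red_cells), 0, "DTT", 2L)

  truth <- tibble(
    cell_id = ids, x = cells$x, y = cells$y, radius = cells$radius,
    brightness = bright,
    in_ox = seq_len(n) <= n_ox_cells,
    in_red = seq_len(n) <= n_red_cells
  )
  list(ox = ox, red = red, truth = truth)
}
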