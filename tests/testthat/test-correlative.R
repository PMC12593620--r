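# Bleach-mark registration, immunolabel classification, matching,
# per-slice normalization.

make_pair <- function(seed = 1, n_positive = 11, n_deficient = 19, ...) {
  sc <- sim_scenario(seed = seed)
  simulate_correlative_slice(sc, slice_id = sprintf("s%d", seed),
                             n_positive = n_positive,
                             n_deficient = n_deficient, seed = seed, ...)
}

test_that("registration recovers planted integer shifts exactly", {
  for (s in 1:4) {
    pair <- make_pair(seed = 20 + s)
    off <- register_by_fiducials(pair$live, pair$fixed)
    expect_equal(as.vector(off),
                 c(pair$truth$shift_x[1], pair$truth$shift_y[1]))
  }
  zero <- make_pair(seed = 30, shift = c(0, 0))
  off0 <- register_by_fiducials(zero$live, zero$fixed)
  expect_equal(as.vector(off0), c(0, 0))
})

test_that("registration fails loudly without a fiducial", {
  sc <- sim_scenario(seed = 41)
  pair <- simulate_correlative_slice(sc, seed = 41)
  # strip the bleach mark from the live field: rebuild without stamping
  live_nomark <- field_image(
    lapply(pair$live$channels, function(ch) { ch[11:50, 11:50] <- 20; ch })
  )
  expect_error(register_by_fiducials(live_nomark, pair$fixed),
               "fiducial|Registration failed")
  # with a noise-free field there is no dark pixel at all: precondition error
  sc0 <- sim_scenario(seed = 42, noise = FALSE)
  pair0 <- simulate_correlative_slice(sc0, seed = 42)
  clean <- field_image(
    lapply(pair0$live$channels, function(ch) { ch[11:50, 11:50] <- 20; ch })
  )
  expect_error(register_by_fiducials(clean, pair0$fixed), "fiducial")
})

test_that("MeCP2 classification reaches 98% accuracy at 10:1 label contrast", {
  correct <- 0; total <- 0
  for (s in 1:3) {
    pair <- make_pair(seed = 50 + s)
    nuc <- classify_mecp2(pair$fixed)
    shift <- c(pair$truth$shift_x[1], pair$truth$shift_y[1])
    m <- redoxmap:::match_points(pair$truth$x + shift[1], pair$truth$y + shift[2],
                                 nuc$x, nuc$y, radius = 5)
    correct <- correct + sum(pair$truth$mecp2_positive[m$i] == nuc$mecp2_positive[m$j])
    total <- total + nrow(m)
  }
  expect_gt(total, 80)
  expect_gte(correct / total, 0.98)
})

test_that("a single-class field triggers the unimodality warning but still classifies", {
  pair <- make_pair(seed = 61, n_positive = 20, n_deficient = 0)
  # every nucleus positive: one lognormal intensity mode
  expect_warning(nuc <- classify_mecp2(pair$fixed), "unimodal")
  expect_gte(nrow(nuc), 18L)
  expect_error(classify_mecp2(pair$fixed, nuclei = nuc[1:2, ]), "at least 4")
})

test_that("cell matching is one-to-one, exact at zero jitter, robust at sigma = 1", {
  pts <- tibble::tibble(cell_id = sprintf("c%d", 1:20),
                        x = runif(20, 20, 180), y = runif(20, 20, 180))
  nuc <- tibble::tibble(nucleus_id = sprintf("n%d", 1:20), x = pts$x, y = pts$y)
  m <- match_cells(pts, nuc, offset = c(x = 0, y = 0))
  expect_true(all(m$matched))
  expect_true(all(m$distance == 0))
  expect_identical(m$nucleus_id, nuc$nucleus_id)

  # one cell far from any nucleus stays unmatched with the rest intact
  lone <- dplyr::bind_rows(pts, tibble::tibble(cell_id = "lost", x = 500, y = 500))
  m2 <- match_cells(lone, nuc, offset = c(x = 0, y = 0))
  expect_false(m2$matched[m2$cell_id == "lost"])
  expect_identical(sum(m2$matched), 20L)

  # jittered fixed positions at sigma = 1 px still match >= 95% correctly
  withr::with_seed(5, {
    nucj <- dplyr::mutate(nuc, x = x + rnorm(20), y = y + rnorm(20))
  })
  m3 <- match_cells(pts, nucj, offset = c(x = 0, y = 0))
  ok <- m3$matched & m3$nucleus_id == sub("c", "n", m3$cell_id)
  expect_gte(mean(ok), 0.95)
})

test_that("per-slice normalization follows the inclusive-denominator arithmetic", {
  cells <- tibble::tibble(
    cell_id = c("p1", "p2", "d1"),
    slice_id = "s1",
    mecp2_positive = c(TRUE, TRUE, FALSE),
    ratio = c(0.6, 0.6, 0.66)
  )
  expect_warning(res <- normalize_and_compare(cells, min_positive = 2),
                 "Welch comparison unavailable")
  norm <- res$normalized
  expect_equal(norm$ratio_norm[norm$cell_id == "d1"], 1.1)
  expect_equal(norm$ratio_norm[norm$mecp2_positive], c(1, 1))
})

test_that("normalization is gauge-invariant and centres positives at one", {
  withr::with_seed(17, {
    cells <- tibble::tibble(
      cell_id = sprintf("c%02d", 1:40),
      slice_id = rep(c("a", "b"), each = 20),
      mecp2_positive = rep(c(TRUE, FALSE), 20),
      ratio = runif(40, 0.4, 0.9)
    )
  })
  res <- normalize_and_compare(cells)
  # multiplying all ratios of one slice by c > 0 changes nothing
  scaled <- dplyr::mutate(cells, ratio = ratio * ifelse(slice_id == "a", 3.1, 1))
  res2 <- normalize_and_compare(scaled)
  expect_equal(res2$normalized$ratio_norm, res$normalized$ratio_norm, tolerance = 1e-12)

  # within each slice the positive mean of normalized ratios is exactly 1
  pos_means <- res$normalized |>
    dplyr::filter(mecp2_positive) |>
    dplyr::group_by(slice_id) |>
    dplyr::summarise(m = mean(ratio_norm))
  expect_equal(pos_means$m, c(1, 1), tolerance = 1e-12)

  # leave-one-out denominators break the exact centring
  loo <- normalize_and_compare(cells, denominator = "leave_one_out")
  pos_loo <- loo$normalized |>
    dplyr::filter(mecp2_positive) |>
    dplyr::group_by(slice_id) |>
    dplyr::summarise(m = mean(ratio_norm))
  expect_false(isTRUE(all.equal(pos_loo$m, c(1, 1))))

  # all-equal ratios within a slice: every normalized value is 1
  flat <- dplyr::mutate(cells, ratio = 0.7)
  expect_true(all(normalize_and_compare(flat)$normalized$ratio_norm == 1))
})

test_that("slices below the minimum positive count are excluded with a message", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:24),
    slice_id = rep(c("ok", "thin"), each = 12),
    mecp2_positive = c(rep(c(TRUE, FALSE), 6), rep(c(TRUE, FALSE, FALSE, FALSE), 3)),
    ratio = runif(24, 0.4, 0.9)
  )
  expect_message(res <- normalize_and_compare(cells, min_positive = 5), "thin")
  expect_identical(res$excluded_slices, "thin")
  expect_false(any(res$normalized$slice_id == "thin"))
})

test_that("the full correlative chain recovers matched cells and their status", {
  pair <- make_pair(seed = 71)
  cells <- analyze_correlative_pair(pair$live, pair$fixed)
  expect_gte(nrow(cells), 0.95 * nrow(pair$truth))
  # compare recovered status against truth by position
  rois <- quantify_field(pair$live)
  m <- redoxmap:::match_points(rois$x, rois$y, pair$truth$x, pair$truth$y, radius = 4)
  truth_status <- pair$truth$mecp2_positive[m$j][match(cells$cell_id, rois$cell_id[m$i])]
  expect_gte(mean(cells$mecp2_positive == truth_status, na.rm = TRUE), 0.95)
})
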