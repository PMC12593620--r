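# Synthetic-data generator: determinism, noise-free exactness, packing,
# mosaic clone model, calibration endpoints, bleach marks.

test_that("identical scenario and seed give bit-identical images and truth", {
  a <- simulate_field(small_scenario(seed = 5))
  b <- simulate_field(small_scenario(seed = 5))
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
  c <- simulate_field(small_scenario(seed = 6))
  expect_false(identical(a$field$channels, c$field$channels))
})

test_that("random substreams are independent: toggling noise keeps the truth fixed", {
  on <- simulate_field(small_scenario(seed = 9))
  off <- simulate_field(exact_scenario(seed = 9))
  expect_identical(on$truth$x, off$truth$x)
  expect_identical(on$truth$oxd_true, off$truth$oxd_true)
  expect_false(identical(on$field$channels$F910, off$field$channels$F910))
})

test_that("a zero-cell field is background plus noise only, with empty truth", {
  sim <- simulate_field(exact_scenario(seed = 2), n_cells = 0)
  expect_identical(nrow(sim$truth), 0L)
  expect_true(all(sim$field$channels$F740 == 0))
  sim_bg <- simulate_field(small_scenario(seed = 2, noise = FALSE), n_cells = 0)
  expect_true(all(sim_bg$field$channels$F910 == 20))
})

test_that("noise-free rendering reproduces ground truth through the full pipeline", {
  sc <- exact_scenario(seed = 4)
  sim <- simulate_field(sc, n_cells = 6)
  cells <- add_oxd(quantify_field(sim$field, f910_floor = 50), sc$calib)
  truth <- sim$truth[order(sim$truth$y, sim$truth$x), ]
  expect_equal(nrow(cells), 6)
  expect_lt(max(abs(cells$oxd - truth$oxd_true)), 1e-6)
})

test_that("infeasible soma packing raises rather than silently truncating", {
  sc <- small_scenario(seed = 1)
  expect_error(simulate_field(sc, n_cells = 500), "Infeasible packing")
})

test_that("explicit OxD overrides are honoured and validated", {
  sc <- exact_scenario(seed = 8)
  sim <- simulate_field(sc, n_cells = 3, oxd_values = c(0.1, 0.5, 0.9))
  expect_setequal(round(sim$truth$oxd_true, 10), c(0.1, 0.5, 0.9))
  expect_error(simulate_field(sc, n_cells = 3, oxd_values = c(0.1, 1.5, 0.2)), "\\[0, 1\\]")
  expect_error(simulate_field(sc, n_cells = 2, oxd_values = 0.5), "length")
})

test_that("mosaic labels follow the clone model", {
  pts <- tibble::tibble(x = runif(400, 0, 500), y = runif(400, 0, 500))
  one <- simulate_mosaic_labels(pts, 0.45, clone_count = 1, seed = 3)
  expect_length(unique(one$mecp2_positive), 1L)

  # many clones >> cells: independent Bernoulli, fraction ~ 0.45 +/- binomial
  big <- tibble::tibble(x = runif(10000, 0, 5000), y = runif(10000, 0, 5000))
  lab <- simulate_mosaic_labels(big, 0.45, clone_count = 1e5, seed = 12)
  expect_equal(mean(lab$mecp2_positive), 0.45, tolerance = 0.045)

  again <- simulate_mosaic_labels(big, 0.45, clone_count = 1e5, seed = 12)
  expect_identical(lab$mecp2_positive, again$mecp2_positive)

  # clonal patchiness: with few clones, neighbours share status more often
  few <- simulate_mosaic_labels(big, 0.5, clone_count = 8, seed = 5)
  expect_lte(length(unique(few$clone)), 8L)

  expect_error(simulate_mosaic_labels(pts, 1.2, 10), "\\(0, 1\\)")
})

test_that("mosaic positive fraction is unbiased across seeds", {
  pts <- tibble::tibble(x = runif(300, 0, 1000), y = runif(300, 0, 1000))
  fr <- vapply(1:30, function(s) {
    mean(simulate_mosaic_labels(pts, 0.45, clone_count = 40, seed = s)$mecp2_positive)
  }, numeric(1))
  # clones are spatially correlated within a seed, but the mean is unbiased
  expect_equal(mean(fr), 0.45, tolerance = 0.06)
})

test_that("calibration endpoints render the same cells at OxD one and zero", {
  sc <- exact_scenario(seed = 6)
  ep <- simulate_calibration_endpoints(sc, n_ox_cells = 4, n_red_cells = 6,
                                       image_size = 256)
  expect_identical(nrow(ep$truth), 6L)
  expect_identical(sum(ep$truth$in_ox), 4L)
  # measured ratios at the truth positions are exactly the endpoint ratios
  ri_ox <- compute_ratio_image(ep$ox, f910_floor = 50)
  m_ox <- measure_rois(ep$ox, dplyr::mutate(ep$truth[ep$truth$in_ox, ], cell_id = cell_id),
                       ratio_image = ri_ox)
  expect_equal(m_ox$ratio, rep(0.916, 4), tolerance = 1e-9)
  m_red <- measure_rois(ep$red, ep$truth[ep$truth$in_red, ])
  expect_equal(m_red$ratio, rep(0.408, 6), tolerance = 1e-9)
  expect_error(simulate_calibration_endpoints(sc, 0, 5), ">= 1")
})

test_that("bleach marks overwrite exactly their square and compose", {
  sc <- small_scenario(seed = 1, noise = FALSE)
  sim <- simulate_field(sc, n_cells = 0)
  f <- stamp_bleach_mark(sim$field, c(10, 10), 50)
  expect_true(all(f$channels$F910[11:60, 11:60] == 0))
  expect_true(all(f$channels$F910[61:128, ] == 20))
  expect_length(f$fiducials, 1L)
  expect_identical(f$fiducials[[1]]$size, 50)

  unchanged <- stamp_bleach_mark(sim$field, c(10, 10), 0)
  expect_identical(unchanged$channels, sim$field$channels)

  two <- stamp_bleach_mark(f, c(70, 70), 20)
  expect_length(two$fiducials, 2L)
  expect_true(all(two$channels$F740[71:90, 71:90] == 0))
  expect_true(all(two$channels$F910[11:60, 11:60] == 0))

  expect_error(stamp_bleach_mark(f, c(100, 100), 50), "outside")
})
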