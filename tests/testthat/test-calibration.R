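# Ratio -> OxD conversion, its inverse, endpoint estimation, uncertainty.

test_that("OxD conversion is exact at the calibration endpoints and midpoint", {
  cal <- ref_calib()
  expect_equal(oxd_from_ratio(0.408, cal), 0)
  expect_equal(oxd_from_ratio(0.916, cal), 1)
  # arithmetic midpoint of the endpoints: OxD = 1 / (1 + IF) exactly
  expect_equal(oxd_from_ratio((0.408 + 0.916) / 2, cal), 1 / (1 + 0.497),
               tolerance = 1e-12)
  expect_equal(oxd_from_ratio(0.662, cal), 0.6680, tolerance = 1e-4)
  # forward-model midpoint ratio maps back to one half
  expect_equal(oxd_from_ratio(0.5766546, cal), 0.5, tolerance = 1e-6)
})

test_that("ratio_from_oxd inverts oxd_from_ratio to machine precision", {
  cal <- ref_calib()
  expect_equal(ratio_from_oxd(0, cal), 0.408)
  expect_equal(ratio_from_oxd(1, cal), 0.916)
  expect_equal(ratio_from_oxd(1 / 1.497, cal), 0.662, tolerance = 1e-12)
  withr::with_seed(1, {
    x <- runif(1000)
    expect_lt(max(abs(oxd_from_ratio(ratio_from_oxd(x, cal), cal) - x)), 1e-12)
  })
  expect_error(ratio_from_oxd(1.01, cal), "\\[0, 1\\]")
})

test_that("Eq.-1 conversion inverts the forward model for arbitrary valid models", {
  withr::with_seed(7, {
    worst <- 0
    for (i in 1:200) {
      m <- random_fluorophore_model()
      tr <- redoxmap:::model_calibration_triple(m)
      cal <- calibration_params(tr$r_ox, tr$r_red, tr$instrument_factor)
      x <- runif(5)
      worst <- max(worst, abs(oxd_from_ratio(expected_ratio(m, x), cal) - x))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("conversion is monotone on the calibrated range and evaluates outside it", {
  cal <- ref_calib()
  r <- seq(0.41, 0.915, length.out = 200)
  expect_true(all(diff(oxd_from_ratio(r, cal)) > 0))
  expect_lt(oxd_from_ratio(0.30, cal), 0)       # below reduced endpoint
  expect_gt(oxd_from_ratio(0.95, cal), 1)       # above oxidized endpoint
  # the denominator can only cross zero when the instrument factor exceeds 1
  # (then R far above R_ox makes Eq. 1 undefined): NA marker, no error
  cal_hi <- calibration_params(0.9, 0.4, 2)
  expect_true(is.na(oxd_from_ratio(2, cal_hi)))
  expect_false(is.na(oxd_from_ratio(1.0, cal_hi)))
})

test_that("noise-free synthetic endpoints recover the generating triple", {
  sc <- exact_scenario(seed = 3)
  ep <- simulate_calibration_endpoints(sc, n_ox_cells = 12, n_red_cells = 12,
                                       image_size = 256)
  ox <- quantify_field(ep$ox, f910_floor = 50)
  red <- quantify_field(ep$red, f910_floor = 50)
  est <- estimate_calibration(ox, red, pairing = "matched")
  expect_equal(est$r_ox, 0.916, tolerance = 1e-6)
  expect_equal(est$r_red, 0.408, tolerance = 1e-6)
  expect_equal(est$instrument_factor, 0.497, tolerance = 1e-3)
  expect_equal(est$n_ox, nrow(ox))

  # unmatched estimator agrees in the noise-free limit up to expression
  # heterogeneity (quotient of means vs mean of quotients)
  est2 <- estimate_calibration(ox, red, pairing = "unmatched")
  expect_equal(est2$instrument_factor, 0.497, tolerance = 0.1)
})

test_that("matched pairing with a single shared cell uses its F910 quotient", {
  ox <- tibble::tibble(cell_id = "c1", ratio = 0.9, f910_mean = 50)
  red <- tibble::tibble(cell_id = "c1", ratio = 0.4, f910_mean = 100)
  est <- estimate_calibration(ox, red, pairing = "matched")
  expect_equal(est$instrument_factor, 0.5)
  expect_equal(est$r_ox, 0.9)
  expect_equal(est$r_red, 0.4)
})

test_that("estimation rejects impossible inputs", {
  ox <- tibble::tibble(cell_id = "a", ratio = 0.9, f910_mean = 50)
  red <- tibble::tibble(cell_id = "b", ratio = 0.4, f910_mean = 100)
  expect_error(estimate_calibration(ox, red, pairing = "matched"),
               "shared cell ids|paired")
  expect_error(estimate_calibration(ox[0, ], red), ">= 1")
})

test_that("calibration uncertainty propagates and collapses when SDs are zero", {
  cal0 <- ref_calib()
  out0 <- propagate_calibration_uncertainty(0.662, cal0, n_draws = 500, seed = 2)
  expect_equal(out0$lower, out0$upper)
  expect_equal(out0$median, out0$oxd)

  cal <- calibration_params(0.916, 0.408, 0.497,
                            sd_r_ox = 0.106, sd_r_red = 0.063, sd_if = 0.126,
                            n_ox = 76, n_red = 78)
  out <- propagate_calibration_uncertainty(0.662, cal, n_draws = 4000, seed = 2)
  expect_lt(out$lower, 0.668)
  expect_gt(out$upper, 0.668)
  out_rep <- propagate_calibration_uncertainty(0.662, cal, n_draws = 4000, seed = 2)
  expect_identical(out, out_rep)
  expect_error(propagate_calibration_uncertainty(0.662, cal, n_draws = 50), "100")
})

test_that("calibration records round-trip through YAML", {
  cal <- calibration_params(0.916, 0.408, 0.497, sd_r_ox = 0.106,
                            sd_r_red = 0.063, sd_if = 0.126, n_ox = 76, n_red = 78)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(unclass(cal2), unclass(cal))
  expect_equal(tidy(cal)$estimate, c(0.916, 0.408, 0.497))
})
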