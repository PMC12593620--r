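# Intactness filter, ROUT outlier screen, aggregation, Holm-Sidak, ANOVA, Welch.

test_that("the 5-95% intactness filter keeps the closed interval", {
  cells <- tibble::tibble(oxd = c(0.03, 0.50, 0.96, 0.05, 0.95, NA))
  out <- filter_intact(cells)
  expect_identical(out$included, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(out$exclusion_reason,
                   c("range", NA, "range", NA, NA, "undefined"))
  # idempotent
  expect_identical(filter_intact(out)$included, out$included)
  expect_identical(nrow(filter_intact(cells[0, ])), 0L)
})

test_that("ROUT flags a gross planted outlier and nothing else", {
  r <- rout_outliers(c(1.0, 1.1, 0.9, 1.05, 0.95, 50.0), q = 0.01)
  expect_identical(r$flagged, 50.0)
  expect_setequal(r$kept, c(1.0, 1.1, 0.9, 1.05, 0.95))

  none <- rout_outliers(rep(2.5, 10))
  expect_length(none$flagged, 0L)
  expect_error(rout_outliers(c(1, 2)), "3")
})

test_that("ROUT false-flag rate on clean normal columns stays at or below 2%", {
  for (n in c(20, 100, 1000)) {
    rate <- withr::with_seed(n, {
      mean(replicate(60, length(rout_outliers(rnorm(n), q = 0.01)$flagged) / n))
    })
    expect_lte(rate, 0.02)
  }
})

test_that("outlier screening operates per analysis column and respects prior exclusions", {
  cells <- tibble::tibble(
    oxd = c(0.5, 0.52, 0.48, 0.51, 0.49, 0.94, 0.6, 0.62, 0.58, 0.61),
    region = rep(c("CA1", "DG"), c(6, 4)),
    genotype = "WT", age_group = "p50"
  )
  cells <- filter_intact(cells)
  out <- screen_outliers(cells, q = 0.01)
  expect_identical(out$exclusion_reason[6], "outlier")   # 0.94 within CA1 column
  expect_true(all(out$included[7:10]))                   # DG column untouched
  # screening its own output changes nothing (idempotence after filtering)
  expect_identical(screen_outliers(out, q = 0.01)$included, out$included)
})

test_that("cell-level and slice-level aggregation differ under unequal slice sizes", {
  cells <- tibble::tibble(
    oxd = c(rep(0.6, 4), 0.8), slice_id = c(rep("s1", 4), "s2"),
    region = "DG", genotype = "WT", age_group = "p50", included = TRUE
  )
  slice <- aggregate_redox(cells, "slice")
  expect_equal(slice$mean, 0.7)
  expect_identical(slice$n, 2L)
  cell <- aggregate_redox(cells, "cell")
  expect_equal(cell$mean, 0.64)
  expect_identical(cell$n, 5L)
  expect_true(slice$mean != cell$mean)

  one <- aggregate_redox(cells[cells$slice_id == "s1", ], "slice")
  expect_true(is.na(one$sd))
  expect_identical(one$n, 1L)
})

test_that("Holm-Sidak adjustment matches the step-down formula and is monotone", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.03, 0.04)),
               c(1 - 0.99^3, 0.0591, 0.0591), tolerance = 1e-4)
  expect_equal(holm_sidak_adjust(c(0.01, 0.03, 0.04))[1], 0.029701)

  withr::with_seed(31, {
    for (i in 1:50) {
      p <- runif(sample(2:12, 1))^sample(1:3, 1)
      adj <- holm_sidak_adjust(p)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-15))
      # never more conservative than the single-step Sidak correction
      expect_true(all(adj <= 1 - (1 - p)^length(p) + 1e-12))
    }
  })
})

test_that("two-way ANOVA with pairwise contrasts recovers planted group structure", {
  d <- tidyr::expand_grid(genotype = c("WT", "Mecp2+/-"),
                          age_group = c("p50", "gt_p100"), i = 1:40)
  withr::with_seed(13, {
    d$oxd <- 0.45 + 0.12 * (d$genotype != "WT") + rnorm(nrow(d), 0, 0.08)
  })
  d$region <- "auditory"
  cmp <- compare_redox(d)
  a <- cmp$anova
  expect_lt(a$p[a$term == "genotype"], 0.001)
  expect_gt(a$p[a$term == "age_group"], 0.01)
  pw <- cmp$pairwise
  expect_identical(nrow(pw), 6L)
  expect_true(all(pw$p_adj >= pw$p - 1e-15))
  gen_rows <- pw$contrast_type == "genotype"
  expect_true(all(pw$marker[gen_rows] == "##"))
  expect_true(all(pw$marker[pw$contrast_type == "age"] == ""))
})

test_that("identical groups give a unit p-value for their contrast", {
  base <- c(0.5, 0.6, 0.55, 0.45, 0.52)
  d <- tibble::tibble(
    oxd = c(base, base, base + 0.2, base + 0.21),
    genotype = rep(c("WT", "Mecp2+/-", "WT", "Mecp2+/-"), each = 5),
    age_group = rep(c("p50", "p50", "gt_p100", "gt_p100"), each = 5),
    region = "CA1"
  )
  cmp <- compare_redox(d)
  pw <- cmp$pairwise
  same <- pw$contrast == "Mecp2+/-.p50 - WT.p50"
  expect_equal(pw$p[same], 1)
  expect_equal(pw$p_adj[same], 1)
})

test_that("a region with an empty design cell reports NA rather than dropping out", {
  d <- tibble::tibble(
    oxd = runif(12, 0.4, 0.6),
    genotype = rep(c("WT", "Mecp2+/-"), 6),
    age_group = "p50",          # only one age level present
    region = "S"
  )
  cmp <- compare_redox(d)
  expect_true(all(is.na(cmp$anova$statistic)))
  expect_identical(nrow(cmp$pairwise), 0L)
})

test_that("under a null generator, familywise marker rate is near nominal", {
  n_sig <- withr::with_seed(99, {
    sum(replicate(80, {
      d <- tidyr::expand_grid(genotype = c("WT", "het"),
                              age_group = c("p50", "gt_p100"), i = 1:12)
      d$oxd <- rnorm(nrow(d), 0.5, 0.1)
      d$region <- "CA1"
      any(compare_redox(d)$pairwise$marker != "")
    }))
  })
  # familywise alpha 0.05: expect ~4 of 80; allow generous binomial slack
  expect_lte(n_sig, 12)
})

test_that("Welch's t matches stats::t.test and is antisymmetric", {
  withr::with_seed(8, {
    a <- rnorm(25, 1, 0.5); b <- rnorm(14, 1.4, 0.9)
  })
  w <- welch_t(a, b)
  tt <- stats::t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)

  expect_equal(welch_t(b, a)$t, -w$t, tolerance = 1e-12)

  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t(rep(1, 5), b), "group_a")
  expect_error(welch_t(a, 1), "n >= 2")
})
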