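test_that("generated landscapes validate and round-trip through the CSV layer", {
  land <- generate_landscape(dgm_config(n_indicators = 4, seed = 7))
  expect_silent(validate_records(land$field))
  expect_silent(validate_records(land$reference))

  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(land$field, path)
  back <- read_estimates(path)
  expect_equal(back, land$field[, names(back)])
})

test_that("the landscape is byte-identical under a fixed seed", {
  cfg <- dgm_config(n_indicators = 3, seed = 1234)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$field, b$field)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth$prevalence, b$truth$prevalence)
  c <- generate_landscape(dgm_config(n_indicators = 3, seed = 1235))
  expect_false(identical(a$field, c$field))
})

test_that("the all-zero DGM produces pure binomial noise tied to the closed form", {
  res <- landscape_pairs(dgm_all_zero(seed = 61))
  land <- res$land
  pairs <- res$pairs
  expect_equal(nrow(res$no_match), 0L)

  n_eff <- land$truth$n_eff
  expect_equal(n_eff, 500L)
  for (ind in land$truth$indicators$indicator_id) {
    d <- pairs$difference[pairs$indicator_id == ind]
    p <- land$truth$indicators$baseline_prevalence[
      land$truth$indicators$indicator_id == ind
    ]
    target <- analytic_sd(p, n_eff)
    mcse <- target * sqrt(2 / (4 * length(d)))
    expect_lt(abs(sd(d) - target), 3 * mcse)
  }
})

test_that("a large method bias shifts per-indicator mean differences by the logit mapping", {
  cfg <- dgm_all_zero(seed = 62, method_bias_sd = 1.0)
  res <- landscape_pairs(cfg)
  land <- res$land
  truth <- land$truth
  for (ind in truth$indicators$indicator_id) {
    d <- res$pairs$difference[res$pairs$indicator_id == ind]
    mu <- truth$indicators$mu[truth$indicators$indicator_id == ind]
    delta_ref <- truth$bias$delta[truth$bias$source_kind == "reference" &
                                    truth$bias$indicator_id == ind]
    delta_fld <- truth$bias$delta[truth$bias$source_kind == "field" &
                                    truth$bias$indicator_id == ind]
    expected <- 100 * (plogis(mu + delta_ref) - plogis(mu + delta_fld))
    mcse <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - expected), 3 * mcse + 1e-9)
  }
})

test_that("a larger design effect widens pair differences", {
  narrow <- landscape_pairs(dgm_all_zero(seed = 63, deff = 1))
  wide <- landscape_pairs(dgm_all_zero(seed = 63, deff = 4))
  expect_equal(wide$land$truth$n_eff, 125L)
  expect_gt(mean(wide$pairs$abs_difference), mean(narrow$pairs$abs_difference))
})

test_that("aggregate_up pools children by sample-size weighting", {
  kids <- make_records(c(40, 80), n = c(100L, 300L),
                       geo_path = c("X>A", "X>B"), geo_level = 4L,
                       source_kind = "reference")
  up <- aggregate_up(kids, "X", 5)
  expect_equal(up$estimate, 70)
  expect_equal(up$n, 400L)
  expect_equal(up$geo_level, 5L)
  expect_equal(up$geo_path, "X")

  # order-invariant over children
  up_rev <- aggregate_up(kids[2:1, ], "X", 5)
  expect_equal(up_rev$estimate, up$estimate)

  # single record passes through; re-aggregating the result is idempotent
  solo <- aggregate_up(kids[1, ], "X", 5)
  expect_equal(solo$estimate, kids$estimate[1])
  again <- aggregate_up(solo, "X", 5)
  expect_equal(again$estimate, solo$estimate)

  # equal child estimates are preserved exactly
  flat <- make_records(c(33.3, 33.3), n = c(10L, 999L),
                       geo_path = c("X>A", "X>B"), geo_level = 4L)
  expect_equal(aggregate_up(flat, "X", 5)$estimate, 33.3)

  expect_error(aggregate_up(kids[0, ], "X", 5), "no records")
  mixed <- dplyr::bind_rows(kids, make_records(10, geo_path = "X>C",
                                               geo_level = 4L,
                                               indicator_id = "other"))
  expect_error(aggregate_up(mixed, "X", 5), "mixed indicator")
  outside <- make_records(10, geo_path = "Y>A", geo_level = 4L, country = "Y")
  expect_error(aggregate_up(outside, "X", 5), "not contained")
})

test_that("recovery_report lines shares up with injected mechanisms", {
  res <- landscape_pairs(dgm_all_zero(seed = 64, method_bias_sd = 1.0))
  vp <- partition_variance(res$pairs)
  rep0 <- recovery_report(res$land$truth, vp)
  expect_setequal(rep0$term, c("indicator_id", "level_diff_band",
                               "year_difference", "season_concordance",
                               "Other"))
  expect_true(rep0$largest_factor[rep0$term == "indicator_id"])
  expect_gt(rep0$injected_sd[rep0$term == "indicator_id"], 0)
  expect_equal(sum(rep0$share), 100, tolerance = 1e-6)
})

test_that("field site-selection bias restricts coverage to worse-off units", {
  cfg <- dgm_config(n_indicators = 2, field_site_quantile = 0.5, seed = 65)
  land <- generate_landscape(cfg)
  full <- generate_landscape(dgm_config(n_indicators = 2, seed = 65))
  expect_lt(length(unique(land$field$geo_path)),
            length(unique(full$field$geo_path)))
  covered <- unique(land$field$geo_path)
  eff <- land$truth$units
  eff <- eff[eff$geo_level == 2, ]
  expect_lte(max(eff$cum_effect[eff$geo_path %in% covered]),
             stats::quantile(eff$cum_effect, 0.5, type = 7))
})

test_that("season labels can be masked to unknown at a configured rate", {
  cfg <- dgm_config(n_indicators = 5, season_unknown_frac = 0.3, seed = 66)
  land <- generate_landscape(cfg)
  frac <- mean(land$field$season == "unknown")
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
})
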