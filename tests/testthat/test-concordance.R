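test_that("within_band_proportion counts pairs inside +/- k percentage points", {
  all_zero <- make_pairs(c(10, 50, 90))
  expect_equal(within_band_proportion(all_zero, 5), 100)

  p <- make_pairs(ref_estimate = c(53, 43, 71), field_estimate = c(50, 50, 50))
  # differences 3, -7, 21
  expect_equal(within_band_proportion(p, 5), 100 / 3)
  expect_equal(within_band_proportion(p, 20), 200 / 3)
  # inclusive boundary
  b <- make_pairs(55, 50)
  expect_equal(within_band_proportion(b, 5), 100)

  expect_error(within_band_proportion(p[0, ], 5), "empty")
  expect_error(within_band_proportion(p, 0), "positive")
})

test_that("within_band_proportion is monotone non-decreasing in k", {
  set.seed(21)
  p <- make_pairs(runif(40, 0, 100), runif(40, 0, 100))
  ks <- c(1, 2, 5, 10, 20, 50, 100)
  props <- vapply(ks, function(k) within_band_proportion(p, k), numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("subgroup summaries report pair counts, moments and within-band shares", {
  cat0 <- indicator_catalog(tibble::tibble(
    indicator_id = c("a", "b"), subgroup_id = c("Sub A", "Sub B"),
    group_id = "G"
  ))
  pairs <- dplyr::bind_rows(
    make_pairs(c(48, 52), c(50, 50), indicator_id = "a"), # differences -2, +2
    make_pairs(30, 20, indicator_id = "b")                # single pair
  )
  s <- summarize_subgroups(pairs, cat0)
  a <- s[s$subgroup_id == "Sub A", ]
  expect_equal(a$n_pairs, 2L)
  expect_equal(a$diff_mean, 0)
  expect_equal(a$diff_sd, sd(c(-2, 2))) # sample SD, 2.828
  expect_equal(a$diff_min, -2)
  expect_equal(a$diff_max, 2)
  expect_equal(a$pct_within_5, 100)
  b <- s[s$subgroup_id == "Sub B", ]
  expect_true(is.na(b$diff_sd)) # SD undefined for one pair
  expect_equal(b$pct_within_5, 0)
  expect_equal(b$pct_within_20, 100)

  # identical sides: zero mean difference, full concordance everywhere
  ident <- make_pairs(c(10, 70), indicator_id = "a")
  si <- summarize_subgroups(ident, cat0)
  expect_equal(si$diff_mean, 0)
  expect_equal(si$pct_within_5, 100)

  expect_error(summarize_subgroups(make_pairs(50, indicator_id = "zzz"), cat0),
               "not in catalog")
})

test_that("strata summaries band years, seasons, levels and size tertiles", {
  pairs <- dplyr::bind_rows(
    make_pairs(60, 50, ref_year = 2015.5, field_year = 2015), # gap 0.5
    make_pairs(60, 50, ref_year = 2013, field_year = 2015),   # gap 2
    make_pairs(60, 50, ref_year = 2011, field_year = 2015)    # gap 4
  )
  yb <- summarize_strata(pairs, "year_band")
  expect_equal(yb$n_pairs, c(1L, 1L, 1L))
  expect_equal(sum(yb$n_pairs), nrow(pairs))

  same_season <- make_pairs(c(60, 40), ref_season = "dry", field_season = "dry")
  ss <- summarize_strata(same_season, "season")
  expect_equal(ss$n_pairs[ss$stratum == "same"], 2L)
  expect_equal(ss$n_pairs[ss$stratum == "different"], 0L) # empty stratum kept
  expect_true(is.na(ss$mean[ss$stratum == "different"]))

  # nine pairs with n = 1..9: tertiles of 3/3/3 cut between 3|4 and 6|7
  nine <- make_pairs(rep(50, 9), rep(40, 9), field_n = 1:9)
  tt <- summarize_strata(nine, "size_tertile", member = "field")
  expect_equal(tt$n_pairs, c(3L, 3L, 3L))
  lv <- summarize_strata(nine, "level_band")
  expect_equal(sum(lv$n_pairs), 9L)
})

test_that("every exhaustive stratification scheme partitions the pair set", {
  set.seed(31)
  pairs <- make_pairs(
    runif(30, 0, 100), runif(30, 0, 100),
    ref_year = sample(c(2010, 2013.5, 2015), 30, TRUE),
    field_year = 2016,
    ref_level = sample(3:5, 30, TRUE), field_level = 2L,
    ref_season = sample(c("dry", "wet", "unknown"), 30, TRUE),
    field_season = "wet",
    field_n = sample(20:2000, 30)
  )
  for (scheme in c("year_band", "season", "level_band", "geo_level",
                   "size_tertile")) {
    s <- summarize_strata(pairs, scheme)
    expect_equal(sum(s$n_pairs), nrow(pairs))
  }
})

test_that("boxplot_summary follows linear-interpolation quantiles and Tukey whiskers", {
  const <- boxplot_summary(rep(7, 12))
  expect_equal(const$q1, 7)
  expect_equal(const$median, 7)
  expect_equal(const$q3, 7)
  expect_equal(const$lower_whisker, 7)
  expect_equal(const$upper_whisker, 7)
  expect_equal(const$n_outliers, 0L)

  b <- boxplot_summary(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q1, 25.75)
  expect_equal(b$q3, 75.25)

  # {0,0,0,100}: q3 = 25, fence = 62.5, so 100 is an outlier
  o <- boxplot_summary(c(0, 0, 0, 100))
  expect_equal(o$q3, 25)
  expect_equal(o$n_outliers, 1L)
  expect_equal(o$upper_whisker, 0)

  expect_error(boxplot_summary(numeric(0)), "non-empty")
})

test_that("reference-value binning uses half-open bands with a closed top", {
  p <- make_pairs(c(0, 100, 35, 9.99, 90))
  binned <- bin_by_reference_value(p, 10)
  expect_equal(as.character(binned$ref_bin),
               c("[0,10)", "[90,100]", "[30,40)", "[0,10)", "[90,100]"))
  expect_equal(nlevels(binned$ref_bin), 10L)
  expect_error(bin_by_reference_value(p, 30), "divide")
})

test_that("mean absolute difference bounds the absolute mean difference", {
  set.seed(41)
  for (i in 1:10) {
    p <- make_pairs(runif(25, 0, 100), runif(25, 0, 100))
    expect_gte(mean(p$abs_difference), abs(mean(p$difference)))
  }
})
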