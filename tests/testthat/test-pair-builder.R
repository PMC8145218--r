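test_that("select_reference_survey takes the most recent prior cycle, with posterior fallback", {
  expect_equal(select_reference_survey(2016, c(2010, 2014)),
               list(year = 2014, posterior = FALSE))
  expect_equal(select_reference_survey(2010, 2007),
               list(year = 2007, posterior = FALSE))
  # no prior cycle: earliest posterior cycle, flagged
  expect_equal(select_reference_survey(2012, 2013),
               list(year = 2013, posterior = TRUE))
  # a cycle in the field year itself counts as prior
  expect_equal(select_reference_survey(2015, c(2010, 2015))$year, 2015)
  expect_error(select_reference_survey(2015, numeric(0)), "no candidate")
})

test_that("resolve_geography climbs the hierarchy one level at a time", {
  refs <- tibble::tibble(
    geo_path = c("Mozambique", "Mozambique>Inhambane"),
    geo_level = c(5L, 3L)
  )
  # district absent, province present: one level up
  hit <- resolve_geography("Mozambique>Inhambane>Homoine", 2L, refs)
  expect_equal(hit$geo_path, "Mozambique>Inhambane")
  expect_equal(hit$levels_climbed, 1L)

  # exact unit present: itself
  self_hit <- resolve_geography("Mozambique>Inhambane", 3L, refs)
  expect_equal(self_hit$geo_path, "Mozambique>Inhambane")
  expect_equal(self_hit$levels_climbed, 0L)

  # village and district absent, province present: two levels up
  v <- resolve_geography("Mozambique>Inhambane>Homoine>Vilanculos", 1L, refs)
  expect_equal(v$geo_path, "Mozambique>Inhambane")
  expect_equal(v$levels_climbed, 2L)

  # the match is never below the query level
  expect_gte(v$geo_level, 1L)

  expect_error(
    resolve_geography("Mozambique>Inhambane>Homoine", 2L, refs, max_climb = 0),
    "no containing"
  )
  expect_error(
    resolve_geography("Kenya>Rift Valley", 3L, refs),
    "no containing"
  )
})

test_that("derive_pair_metrics fills every metric with the reference-minus-field convention", {
  # field at district, reference one level up at province
  p <- make_pairs(ref_estimate = 40, field_estimate = 55,
                  ref_level = 3L, field_level = 2L,
                  ref_year = 2011, field_year = 2017,
                  ref_season = "dry", field_season = "wet")
  expect_equal(p$difference, -15)
  expect_equal(p$abs_difference, 15)
  expect_equal(p$level_difference, 1L)
  expect_equal(as.character(p$level_diff_band), "1")
  expect_equal(p$year_difference, -6)
  expect_equal(p$season_concordance, "different")

  # a 6.5-year gap lands in the widest year band downstream
  q <- make_pairs(35.9, 29.3, ref_year = 2005.5, field_year = 2012)
  expect_equal(q$year_difference, -6.5)
  expect_equal(q$abs_year_difference, 6.5)

  # self-pair: all gaps zero, band 0
  s <- make_pairs(50, 50)
  expect_equal(s$year_difference, 0)
  expect_equal(s$level_difference, 0L)
  expect_equal(as.character(s$level_diff_band), "0")

  # unknown season on either side makes concordance unknown
  u <- make_pairs(50, 50, ref_season = "dry", field_season = "unknown")
  expect_equal(u$season_concordance, "unknown")

  expect_error(
    derive_pair_metrics(make_records(50, indicator_id = "a"),
                        make_records(50, indicator_id = "b")),
    "different indicators"
  )
  expect_error(
    derive_pair_metrics(make_records(50, country = "X"),
                        make_records(50, country = "Y", geo_path = "Y")),
    "different countries"
  )
})

test_that("difference is antisymmetric and abs_difference swap-invariant", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0, 100)
    b <- runif(1, 0, 100)
    fwd <- make_pairs(a, b)
    rev <- make_pairs(b, a)
    expect_equal(fwd$difference, -rev$difference)
    expect_equal(fwd$abs_difference, rev$abs_difference)
  }
})

test_that("the cross-source worked example reproduces all fifteen matches", {
  field <- read_fixture("anc3_field_estimates.csv")
  refs <- read_fixture("anc3_reference_estimates.csv")
  res <- build_cross_source_pairs(field, refs)

  expect_equal(nrow(res$pairs), 15L)
  expect_equal(nrow(res$no_match), 0L)
  expect_lte(nrow(res$pairs), nrow(field))
  # posterior fallback only for the two Pakistan rows
  expect_equal(sum(res$pairs$posterior_match), 2L)
  expect_equal(unique(res$pairs$country[res$pairs$posterior_match]), "Pakistan")
  # population-matched reference extractions pair with the right field survey
  jhark <- res$pairs[res$pairs$field_geo_path == "India>Jharkhand>Jharkhand", ]
  expect_equal(jhark$ref_n, 320L)
  expect_equal(jhark$ref_estimate, 36.6)
})

test_that("unmatched field records are reported, not dropped", {
  field <- make_records(50, country = "Nowhere", geo_path = "Nowhere")
  refs <- make_records(40, source_kind = "reference", country = "Elsewhere",
                       geo_path = "Elsewhere")
  res <- build_cross_source_pairs(field, refs)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(nrow(res$no_match), 1L)
  expect_match(res$no_match$reason, "no reference estimates")

  empty <- build_cross_source_pairs(field[0, ], refs)
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(nrow(empty$no_match), 0L)
})

test_that("posterior matches can be disallowed by policy", {
  field <- make_records(50, year = 2012, geo_path = "X", geo_level = 5L)
  refs <- make_records(40, source_kind = "reference", year = 2013,
                       geo_path = "X", geo_level = 5L)
  allowed <- build_cross_source_pairs(field, refs, allow_posterior = TRUE)
  expect_equal(nrow(allowed$pairs), 1L)
  expect_true(allowed$pairs$posterior_match)

  denied <- build_cross_source_pairs(field, refs, allow_posterior = FALSE)
  expect_equal(nrow(denied$pairs), 0L)
  expect_match(denied$no_match$reason, "posterior")
})

test_that("same-source scenarios split by year-only, level-only and both", {
  z <- read_fixture("zambia_anc3_cycles.csv")
  scen <- build_same_source_scenarios(z)

  s1 <- scen[scen$scenario == "S1", ]
  s2 <- scen[scen$scenario == "S2", ]
  s3 <- scen[scen$scenario == "S3", ]

  # S1: same unit and level, different years
  expect_true(all(s1$level_difference == 0))
  expect_true(all(s1$year_difference != 0))
  # S2: same year, reference strictly above the field unit
  expect_true(all(s2$year_difference == 0))
  expect_true(all(s2$level_difference > 0))
  # S3: both differ
  expect_true(all(s3$year_difference != 0 & s3$level_difference > 0))
  # no same-year-same-level pairs anywhere
  expect_false(any(scen$year_difference == 0 & scen$level_difference == 0))

  # spot-check two printed pairs
  central_s1 <- s1[s1$ref_geo_path == "Zambia>Central", ]
  expect_equal(central_s1$difference, 89.2 - 89.0)
  central_s2 <- s2[s2$field_geo_path == "Zambia>Central", ]
  expect_equal(central_s2$ref_estimate, 88.5)
  expect_equal(central_s2$ref_geo_level, 5L)

  # the S2 cycle can be switched to the later one
  scen_late <- build_same_source_scenarios(z, s2_cycle = "later")
  s2_late <- scen_late[scen_late$scenario == "S2", ]
  expect_true(all(s2_late$ref_year == 2018))
  expect_equal(nrow(s2_late), 10L)
})
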