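# Shared builders for in-code fixtures.

fixture_path <- function(name) {
  system.file("extdata", name, package = "svyconcord")
}

read_fixture <- function(name) {
  read_estimates(fixture_path(name))
}

# Minimal estimate records; vectors recycle against the longest input.
make_records <- function(estimate, n = 100L, source_kind = "field",
                         source_name = "SRC", country = "X", geo_path = "X",
                         geo_level = 5L, year = 2015, season = "unknown",
                         indicator_id = "ind", population = NA_character_) {
  tibble::tibble(
    source_kind = source_kind, source_name = source_name, country = country,
    geo_path = geo_path, geo_level_type = geo_level_label(geo_level),
    year_raw = ifelse(year %% 1 == 0, sprintf("%d", as.integer(year)),
                      sprintf("%.1f", year)),
    season = season, indicator_id = indicator_id, n = as.integer(n),
    estimate = estimate, sd = NA_real_, population = population,
    year = year, geo_level = as.integer(geo_level)
  )
}

# Matched pairs with prescribed per-side attributes.
make_pairs <- function(ref_estimate, field_estimate = ref_estimate,
                       indicator_id = "ind", ref_year = 2015,
                       field_year = 2015, ref_level = 3L, field_level = 3L,
                       ref_season = "unknown", field_season = "unknown",
                       ref_n = 100L, field_n = 100L) {
  ref <- make_records(ref_estimate,
    n = ref_n, source_kind = "reference",
    source_name = "REF", geo_path = "X>A", geo_level = ref_level,
    year = ref_year, season = ref_season, indicator_id = indicator_id
  )
  field <- make_records(field_estimate,
    n = field_n, source_name = "FLD",
    geo_path = "X>A", geo_level = field_level, year = field_year,
    season = field_season, indicator_id = indicator_id
  )
  derive_pair_metrics(ref, field)
}

# All-zero data-generating model: both sources survey the same provinces in
# the same year and season with no structural effects, so pair differences
# are pure binomial sampling noise.
dgm_all_zero <- function(seed, ...) {
  base <- list(
    n_regions = 4, n_provinces = 6, n_districts = 1, n_indicators = 12,
    sd_region = 0, sd_province = 0, sd_district = 0, sd_village = 0,
    drift_mean = 0, drift_sd = 0, season_sd = 0, method_bias_sd = 0,
    deff = 1,
    ref_cycles = 2015, field_cycles = 2015,
    ref_levels = 3, field_levels = 3,
    ref_season = "dry", field_season = "dry",
    seed = seed
  )
  do.call(dgm_config, utils::modifyList(base, list(...)))
}

landscape_pairs <- function(config) {
  land <- generate_landscape(config)
  match <- suppressMessages(
    build_cross_source_pairs(land$field, land$reference)
  )
  list(land = land, pairs = match$pairs, no_match = match$no_match)
}
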