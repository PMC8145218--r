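# Matched-pair construction: reference (DHS/MICS-style) vs field (NGO-style).

#' Choose the reference survey cycle for a field survey year
#'
#' The reference estimate comes from the most recent reference cycle carried
#' out no later than the field survey. When no prior cycle exists the earliest
#' posterior cycle is returned with `posterior = TRUE`, so callers can keep or
#' drop such matches explicitly.
#'
#' @param field_year Decimal year of the field survey.
#' @param candidate_years Numeric vector of available reference cycle years.
#'
#' @return A list with `year` (the chosen cycle) and `posterior` (logical).
#' @export
#' @examples
#' select_reference_survey(2016, c(2010, 2014)) # 2014, prior
#' select_reference_survey(2012, 2013)          # 2013, posterior fallback
select_reference_survey <- function(field_year, candidate_years) {
  candidate_years <- unique(candidate_years)
  if (length(candidate_years) == 0) {
    stop("no candidate reference survey years", call. = FALSE)
  }
  prior <- candidate_years[candidate_years <= field_year]
  if (length(prior) > 0) {
    list(year = max(prior), posterior = FALSE)
  } else {
    list(year = min(candidate_years), posterior = TRUE)
  }
}

#' Resolve a field geography against available reference geographies
#'
#' Looks for a reference unit covering the field unit: the unit itself if the
#' reference set contains it, otherwise the nearest ancestor in the
#' administrative hierarchy, climbing one level at a time. The match is never
#' at a lower level than the query.
#'
#' @param geo_path Field unit path (">"-joined, rooted at the country).
#' @param geo_level Field unit level (1-5).
#' @param available_ref_geos Data frame with columns `geo_path`, `geo_level`
#'   listing reference units.
#' @param max_climb Maximum number of levels the match may sit above the field
#'   unit (default unlimited).
#'
#' @return A list with `geo_path`, `geo_level` and `levels_climbed` (0 for an
#'   exact match). Errors when no containing unit exists within `max_climb`.
#' @export
resolve_geography <- function(geo_path, geo_level, available_ref_geos,
                              max_climb = Inf) {
  g <- dplyr::distinct(
    tibble::as_tibble(available_ref_geos)[, c("geo_path", "geo_level")]
  )
  covering <- g$geo_level >= geo_level &
    vapply(g$geo_path, is_path_prefix, logical(1), path = geo_path)
  cand <- g[covering, , drop = FALSE]
  if (nrow(cand) > 0) {
    best <- cand[which.min(cand$geo_level), ]
    climbed <- best$geo_level - geo_level
    if (climbed <= max_climb) {
      return(list(
        geo_path = best$geo_path,
        geo_level = best$geo_level,
        levels_climbed = climbed
      ))
    }
  }
  stop("no containing reference geography for ", sQuote(geo_path),
       " within ", max_climb, " level(s)", call. = FALSE)
}

# Band geographic level differences as 0 / 1 / 2+ on the absolute difference.
level_diff_band <- function(level_difference) {
  factor(
    ifelse(abs(level_difference) >= 2, "2+", as.character(abs(level_difference))),
    levels = c("0", "1", "2+")
  )
}

# Zero-row pair tibble with the full column set, so empty results keep shape.
empty_pairs <- function() {
  tibble::tibble(
    country = character(0), indicator_id = character(0),
    ref_source = character(0), ref_geo_path = character(0),
    ref_geo_level = integer(0), ref_year = numeric(0),
    ref_season = character(0), ref_n = integer(0), ref_estimate = numeric(0),
    field_source = character(0), field_geo_path = character(0),
    field_geo_level = integer(0), field_year = numeric(0),
    field_season = character(0), field_n = integer(0),
    field_estimate = numeric(0),
    difference = numeric(0), abs_difference = numeric(0),
    year_difference = numeric(0), abs_year_difference = numeric(0),
    level_difference = integer(0),
    level_diff_band = factor(character(0), levels = c("0", "1", "2+")),
    season_concordance = character(0), scenario = character(0),
    posterior_match = logical(0), levels_climbed = integer(0)
  )
}

#' Derive all pair metrics for matched reference/field estimates
#'
#' Computes, for each reference-field pair of estimates of the same indicator
#' in the same country: the difference (reference minus field, in percentage
#' points), absolute difference, year difference (reference minus field) and
#' its absolute value, geographic level difference (reference minus field)
#' with its 0/1/2+ band on the absolute value, and season concordance
#' (`"same"`, `"different"`, or `"unknown"` when either side's season is
#' unknown).
#'
#' @param ref,field Estimate records (equal-height tibbles; matched row-wise).
#' @param scenario Pair scenario tag: `"cross_source"` for reference-vs-field
#'   pairs, or `"S1"`/`"S2"`/`"S3"` for same-source scenario pairs.
#' @param posterior_match Logical, whether the reference cycle postdates the
#'   field survey.
#' @param levels_climbed Integer, levels climbed during geography resolution.
#'
#' @return A tibble of matched pairs, one row per input row.
#' @export
derive_pair_metrics <- function(ref, field, scenario = "cross_source",
                                posterior_match = FALSE,
                                levels_climbed = NA_integer_) {
  ref <- tibble::as_tibble(ref)
  field <- tibble::as_tibble(field)
  if (nrow(ref) != nrow(field)) {
    stop("`ref` and `field` must have the same number of rows", call. = FALSE)
  }
  if (nrow(ref) == 0) return(empty_pairs())
  if (any(ref$indicator_id != field$indicator_id)) {
    stop("cannot pair estimates of different indicators", call. = FALSE)
  }
  if (any(ref$country != field$country)) {
    stop("cannot pair estimates from different countries", call. = FALSE)
  }

  difference <- ref$estimate - field$estimate
  year_difference <- ref$year - field$year
  level_difference <- as.integer(ref$geo_level - field$geo_level)
  unknown <- is.na(ref$season) | is.na(field$season) |
    ref$season == "unknown" | field$season == "unknown"
  season_concordance <- dplyr::case_when(
    unknown ~ "unknown",
    ref$season == field$season ~ "same",
    TRUE ~ "different"
  )

  tibble::tibble(
    country = ref$country,
    indicator_id = ref$indicator_id,
    ref_source = ref$source_name,
    ref_geo_path = ref$geo_path,
    ref_geo_level = as.integer(ref$geo_level),
    ref_year = ref$year,
    ref_season = ref$season,
    ref_n = as.integer(ref$n),
    ref_estimate = ref$estimate,
    field_source = field$source_name,
    field_geo_path = field$geo_path,
    field_geo_level = as.integer(field$geo_level),
    field_year = field$year,
    field_season = field$season,
    field_n = as.integer(field$n),
    field_estimate = field$estimate,
    difference = difference,
    abs_difference = abs(difference),
    year_difference = year_difference,
    abs_year_difference = abs(year_difference),
    level_difference = level_difference,
    level_diff_band = level_diff_band(level_difference),
    season_concordance = season_concordance,
    scenario = scenario,
    posterior_match = posterior_match,
    levels_climbed = as.integer(levels_climbed)
  )
}

#' Build reference-vs-field matched pairs
#'
#' For every field estimate, finds the reference estimate of the same indicator
#' in the same country by (1) choosing the reference cycle with
#' [select_reference_survey()] and (2) resolving the geography within that
#' cycle with [resolve_geography()]. When both sides carry a `population` tag,
#' candidate reference estimates are restricted to those with a matching (or
#' missing) tag, so population-matched reference extractions pair with the
#' right field survey. Field records without a match are reported, not
#' silently dropped.
#'
#' @param field_records,ref_records Validated, n-filtered estimate tables.
#' @param allow_posterior Keep matches whose reference cycle postdates the
#'   field survey (flagged in `posterior_match`; default `TRUE`).
#' @param max_climb Maximum levels of geographic fallback (default unlimited).
#'
#' @return A list with `pairs` (tibble of matched pairs) and `no_match`
#'   (tibble of unmatched field records with a `reason` column).
#' @export
build_cross_source_pairs <- function(field_records, ref_records,
                                     allow_posterior = TRUE, max_climb = Inf) {
  field_records <- tibble::as_tibble(field_records)
  ref_records <- tibble::as_tibble(ref_records)
  if (!"population" %in% names(field_records)) field_records$population <- NA_character_
  if (!"population" %in% names(ref_records)) ref_records$population <- NA_character_

  pairs <- vector("list", nrow(field_records))
  misses <- list()
  miss <- function(i, f, reason) {
    misses[[length(misses) + 1L]] <<- tibble::tibble(
      field_row = i, country = f$country, indicator_id = f$indicator_id,
      geo_path = f$geo_path, year = f$year, reason = reason
    )
  }

  for (i in seq_len(nrow(field_records))) {
    f <- field_records[i, ]
    cand <- ref_records[
      ref_records$country == f$country &
        ref_records$indicator_id == f$indicator_id, ,
      drop = FALSE
    ]
    compatible <- is.na(cand$population) | is.na(f$population) |
      cand$population == f$population
    cand <- cand[compatible, , drop = FALSE]
    if (nrow(cand) == 0) {
      miss(i, f, "no reference estimates for this country and indicator")
      next
    }
    sel <- select_reference_survey(f$year, unique(cand$year))
    if (sel$posterior && !allow_posterior) {
      miss(i, f, "only posterior reference cycles available")
      next
    }
    cyc <- cand[cand$year == sel$year, , drop = FALSE]
    geo <- tryCatch(
      resolve_geography(f$geo_path, f$geo_level, cyc, max_climb),
      error = function(e) NULL
    )
    if (is.null(geo)) {
      miss(i, f, "no containing reference geography")
      next
    }
    hit <- cyc[cyc$geo_path == geo$geo_path & cyc$geo_level == geo$geo_level, ,
               drop = FALSE]
    if (nrow(hit) > 1) {
      stop("ambiguous reference match for field row ", i, " (",
           f$country, ", ", f$indicator_id, "): ", nrow(hit),
           " reference estimates at ", sQuote(geo$geo_path),
           "; disambiguate with the population column", call. = FALSE)
    }
    pairs[[i]] <- derive_pair_metrics(
      hit, f,
      scenario = "cross_source",
      posterior_match = sel$posterior,
      levels_climbed = geo$levels_climbed
    )
  }

  list(
    pairs = dplyr::bind_rows(empty_pairs(), pairs),
    no_match = dplyr::bind_rows(
      tibble::tibble(
        field_row = integer(0), country = character(0),
        indicator_id = character(0), geo_path = character(0),
        year = numeric(0), reason = character(0)
      ),
      misses
    )
  )
}

#' Build same-source scenario pairs (reference source against itself)
#'
#' Pairs estimates from a single survey source across its own cycles and
#' levels, mimicking the conditions of cross-source matching while holding the
#' survey methodology fixed:
#'
#' * **S1** — same geographic unit and level, earlier cycle as reference and
#'   later cycle as the field-mimicking side;
#' * **S2** — same cycle, a higher-level unit as reference and each strictly
#'   contained lower-level unit as the field side;
#' * **S3** — earlier cycle at the higher level as reference, later cycle at
#'   the contained lower level as the field side.
#'
#' No same-year-same-level pairs are emitted. Containment means the lower
#' unit's path is strictly prefixed by the higher unit's path, so national
#' estimates pair with any subunit.
#'
#' @param records Estimate table from one source (same `source_kind`).
#' @param ref_cycle,field_cycle Decimal years of the two cycles compared;
#'   default the two most recent cycles present, earlier as reference.
#' @param s2_cycle Which cycle the same-year (S2) pairs are drawn from:
#'   `"earlier"` (default) or `"later"`.
#'
#' @return A tibble of pairs with `scenario` in `"S1"`, `"S2"`, `"S3"`.
#' @export
build_same_source_scenarios <- function(records, ref_cycle = NULL,
                                        field_cycle = NULL,
                                        s2_cycle = c("earlier", "later")) {
  s2_cycle <- match.arg(s2_cycle)
  records <- tibble::as_tibble(records)
  if (length(unique(records$source_kind)) > 1) {
    stop("same-source scenarios need records from a single source kind",
         call. = FALSE)
  }
  years <- sort(unique(records$year))
  if (is.null(ref_cycle) || is.null(field_cycle)) {
    if (length(years) < 2) {
      stop("need at least two survey cycles for same-source scenarios",
           call. = FALSE)
    }
    ref_cycle <- years[length(years) - 1L]
    field_cycle <- years[length(years)]
  }
  if (!(ref_cycle < field_cycle)) {
    stop("`ref_cycle` must precede `field_cycle`", call. = FALSE)
  }

  older <- records[records$year == ref_cycle, , drop = FALSE]
  newer <- records[records$year == field_cycle, , drop = FALSE]

  # S1: same unit, same level, across cycles
  key <- function(d) paste(d$country, d$geo_path, d$geo_level, d$indicator_id,
                           sep = "\r")
  m <- match(key(older), key(newer))
  hit <- !is.na(m)
  s1 <- derive_pair_metrics(older[hit, ], newer[m[hit], ], scenario = "S1")

  # Higher-level unit (reference side) against strictly contained lower units.
  containment_pairs <- function(hi, lo, scenario) {
    out <- list()
    for (j in seq_len(nrow(hi))) {
      h <- hi[j, ]
      contained <- lo$country == h$country &
        lo$indicator_id == h$indicator_id &
        lo$geo_level < h$geo_level &
        vapply(lo$geo_path, function(p) {
          is_path_prefix(h$geo_path, p, strict = TRUE)
        }, logical(1))
      sub <- lo[contained, , drop = FALSE]
      if (nrow(sub) > 0) {
        out[[length(out) + 1L]] <- derive_pair_metrics(
          h[rep(1L, nrow(sub)), ], sub, scenario = scenario
        )
      }
    }
    dplyr::bind_rows(empty_pairs(), out)
  }

  s2_recs <- if (s2_cycle == "earlier") older else newer
  s2 <- containment_pairs(s2_recs, s2_recs, "S2")
  s3 <- containment_pairs(older, newer, "S3")

  dplyr::bind_rows(s1, s2, s3)
}
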