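# Record model and CSV I/O for survey estimate tables.
#
# One row = one prevalence estimate from one source at one place and time:
#   source_kind    "reference" (DHS/MICS-style) or "field" (NGO-style)
#   source_name    free text, e.g. "DHS", "CARE"
#   country        country name; also the root of geo_path
#   geo_path       ">"-joined place names from the country downward; composite
#                  units are declared with "+" inside a single path component
#   geo_level_type administrative word resolved to a level via the synonym map
#   year_raw       "YYYY", a consecutive span "YYYY/YY" or "YYYY/YYYY", or a
#                  decimal "YYYY.5"
#   season         free label ("dry", "wet", ...) or "unknown"
#   indicator_id   indicator identifier; pairing requires exact equality
#   n              number of observations behind the estimate
#   estimate       prevalence in percent, 0-100
#   sd             optional standard deviation in percent
#   population     optional study-population tag; reference estimates that were
#                  recomputed to match a specific field survey's sample carry
#                  the same tag as that field survey

.estimate_columns <- c(
  "source_kind", "source_name", "country", "geo_path", "geo_level_type",
  "year_raw", "season", "indicator_id", "n", "estimate", "sd", "population"
)

#' Parse survey years, including two-year spans
#'
#' A survey whose fieldwork spans two calendar years is dated at the midpoint:
#' the first year plus 0.5, so `"2013/14"` becomes 2013.5. Single years pass
#' through, and already-coded decimals (`"2013.5"`) are accepted so that a
#' parsed year rendered back to text re-parses to itself.
#'
#' @param raw Character vector: `"YYYY"`, `"YYYY/YY"`, `"YYYY/YYYY"` (the two
#'   years must be consecutive) or `"YYYY.0"` / `"YYYY.5"`.
#' @param rows Optional row identifiers used in error messages.
#'
#' @return Numeric vector of decimal years.
#' @export
#' @examples
#' parse_year(c("2013/14", "2016", "2016/17"))
parse_year <- function(raw, rows = NULL) {
  raw_chr <- trimws(as.character(raw))
  rows <- rows %||% seq_along(raw_chr)
  out <- rep(NA_real_, length(raw_chr))

  single <- !is.na(raw_chr) & grepl("^\\d{4}(\\.[05])?$", raw_chr)
  out[single] <- as.numeric(raw_chr[single])

  span <- !is.na(raw_chr) & grepl("^\\d{4}/(\\d{2}|\\d{4})$", raw_chr)
  for (i in which(span)) {
    parts <- strsplit(raw_chr[i], "/", fixed = TRUE)[[1L]]
    y1 <- as.numeric(parts[1L])
    y2 <- as.numeric(parts[2L])
    if (nchar(parts[2L]) == 2L) {
      y2 <- y1 - (y1 %% 100) + y2
      if (y2 < y1) y2 <- y2 + 100 # century wrap, e.g. "1999/00"
    }
    if (y2 != y1 + 1) {
      stop("non-consecutive year span ", sQuote(raw_chr[i]), " (row ", rows[i], ")",
        call. = FALSE
      )
    }
    out[i] <- y1 + 0.5
  }

  bad <- is.na(out)
  if (any(bad)) {
    stop(
      "unparseable year value(s): ",
      paste0(sQuote(raw_chr[bad]), " (row ", rows[bad], ")", collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Validate a table of survey estimates
#'
#' Checks every record invariant: estimates within 0-100, positive integer
#' sample sizes, plausible years (1990-2035), geographic paths rooted at the
#' record's country with a depth consistent with the declared level, and
#' uniqueness of the (source_kind, source_name, country, geo_path, year,
#' indicator_id, population) key. All violations are reported together with
#' their row numbers.
#'
#' @param records Tibble of estimates as returned by [read_estimates()].
#' @return The validated records, invisibly.
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- setdiff(.estimate_columns, c("sd", "population"))
  missing_cols <- setdiff(c(required, "year", "geo_level"), names(records))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems, paste0(msg, " (row ", which(bad), ")"))
    }
  }

  flag(!records$source_kind %in% c("reference", "field"),
       "source_kind must be 'reference' or 'field'")
  flag(is.na(records$estimate) | records$estimate < 0 | records$estimate > 100,
       "estimate outside [0, 100]")
  flag(is.na(records$n) | records$n < 1 | records$n %% 1 != 0,
       "n must be a positive integer")
  flag(is.na(records$year) | records$year < 1990 | records$year > 2035,
       "year outside the plausible window [1990, 2035]")
  flag(!records$geo_level %in% 1:5, "geo_level must be in 1..5")
  if ("sd" %in% names(records)) {
    flag(!is.na(records$sd) & records$sd < 0, "sd must be non-negative")
  }

  parts <- split_geo_path(records$geo_path)
  root <- vapply(parts, function(p) p[[1L]], character(1))
  depth <- lengths(parts)
  flag(root != records$country, "geo_path must be rooted at the record's country")
  depth_ok <- ifelse(records$geo_level == 5L,
    depth == 1L,
    depth >= 2L & depth <= 6L - records$geo_level
  )
  flag(records$geo_level %in% 1:5 & !depth_ok,
       "geo_path depth inconsistent with geo_level")

  pop <- if ("population" %in% names(records)) records$population else NA_character_
  key <- paste(records$source_kind, records$source_name, records$country,
               records$geo_path, records$year, records$indicator_id, pop,
               sep = "\r")
  flag(duplicated(key) | duplicated(key, fromLast = TRUE),
       "duplicate (source, geography, year, indicator) key")

  if (length(problems) > 0) {
    stop("invalid estimate record(s):\n  ", paste(problems, collapse = "\n  "),
      call. = FALSE
    )
  }
  invisible(records)
}

#' Read a CSV table of survey estimates
#'
#' Expects the columns `source_kind, source_name, country, geo_path,
#' geo_level_type, year_raw, season, indicator_id, n, estimate` plus optional
#' `sd` and `population`. Two derived columns are added: `year` (via
#' [parse_year()]) and `geo_level` (via [assign_geo_level()]). Missing or empty
#' seasons become `"unknown"`.
#'
#' @param path Path to the CSV file.
#' @param synonyms Unit-type synonym map, see [geo_level_synonyms()].
#' @param validate Run [validate_records()] on the result (default `TRUE`).
#'
#' @return A tibble of estimate records.
#' @export
read_estimates <- function(path, synonyms = geo_level_synonyms(), validate = TRUE) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- setdiff(.estimate_columns, c("sd", "population"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(
      "estimate table ", sQuote(path), " lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"sd" %in% names(df)) df$sd <- NA_character_
  if (!"population" %in% names(df)) df$population <- NA_character_

  df <- dplyr::mutate(df,
    n = as.integer(.data$n),
    estimate = as.numeric(.data$estimate),
    sd = as.numeric(.data$sd),
    season = dplyr::if_else(
      is.na(.data$season) | .data$season == "", "unknown", .data$season
    )
  )
  df$year <- parse_year(df$year_raw, rows = seq_len(nrow(df)))
  df$geo_level <- if (nrow(df) > 0) {
    assign_geo_level(df$geo_level_type, synonyms)
  } else {
    integer(0)
  }
  df <- df[, c(.estimate_columns, "year", "geo_level")]
  if (validate && nrow(df) > 0) validate_records(df)
  df
}

#' Write a table of survey estimates to CSV
#'
#' Writes the canonical input columns (raw year and unit type, not the derived
#' `year`/`geo_level`), so that a written table read back with
#' [read_estimates()] reproduces the records field for field.
#'
#' @param records Tibble of estimate records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (!"sd" %in% names(records)) records$sd <- NA_real_
  if (!"population" %in% names(records)) records$population <- NA_character_
  readr::write_csv(records[, .estimate_columns], path, na = "")
  invisible(path)
}

#' Exclude estimates based on too few observations
#'
#' Estimates based on fewer than `threshold` observations are set aside (the
#' default reproduces the rule of excluding estimates with fewer than ten
#' observations; n = 10 itself is kept).
#'
#' @param records Tibble of estimate records.
#' @param threshold Minimum retained sample size (default 10).
#'
#' @return A list with `retained`, `excluded` (both tibbles partitioning the
#'   input), `threshold` and `n_excluded`.
#' @export
filter_min_n <- function(records, threshold = 10) {
  stopifnot(threshold >= 1)
  records <- tibble::as_tibble(records)
  keep <- records$n >= threshold
  res <- list(
    retained = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE],
    threshold = threshold,
    n_excluded = sum(!keep)
  )
  message(sum(!keep), " estimate(s) excluded with n < ", threshold,
          "; ", sum(keep), " retained")
  res
}
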