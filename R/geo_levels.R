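#' Administrative geographic levels
#'
#' Survey estimates are tagged with the level of the administrative unit they
#' describe, coded 1 (the smallest subdivision: village, town, locality or
#' traditional authority) through 5 (the whole country):
#'
#' * 1 — village, town, locality, traditional authority
#' * 2 — district or equivalent (e.g. upazila, local government area)
#' * 3 — province, state, department, county, zone or division
#' * 4 — region (a grouping of level-3 units)
#' * 5 — country
#'
#' Because the same administrative word maps to different levels in different
#' countries (a "county" is a level-3 unit in Liberia but a level-2 unit in
#' Kenya), the word-to-level map is an editable synonym table rather than a
#' fixed rule.
#'
#' @param overrides Named integer vector of synonym replacements or additions,
#'   e.g. `c(county = 2)`.
#'
#' @return `geo_level_synonyms()` returns a named integer vector mapping
#'   lower-case unit-type words to levels 1-5.
#' @export
#' @examples
#' geo_level_synonyms()[["county"]]             # 3, Liberia-style default
#' geo_level_synonyms(c(county = 2))[["county"]] # Kenya-style override
geo_level_synonyms <- function(overrides = NULL) {
  syn <- c(
    "village" = 1L, "town" = 1L, "locality" = 1L, "traditional authority" = 1L,
    "commune" = 1L, "ward" = 1L,
    "district" = 2L, "district council" = 2L, "upazila" = 2L,
    "local government area" = 2L, "municipality" = 2L, "city" = 2L,
    "province" = 3L, "state" = 3L, "department" = 3L, "county" = 3L,
    "zone" = 3L, "division" = 3L,
    "region" = 4L,
    "country" = 5L, "national" = 5L
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("`overrides` must be a named vector of unit-type words", call. = FALSE)
    }
    if (!all(overrides %in% 1:5)) {
      stop("geographic levels must be integers in 1..5", call. = FALSE)
    }
    syn[tolower(names(overrides))] <- as.integer(overrides)
  }
  syn
}

#' Assign a geographic level to an administrative unit type
#'
#' @param unit_type Character vector of unit-type words (e.g. `"district"`).
#'   Matching is case-insensitive and ignores surrounding whitespace.
#' @param synonyms Word-to-level map, see [geo_level_synonyms()].
#'
#' @return Integer vector of levels in 1..5.
#' @export
#' @examples
#' assign_geo_level(c("village", "Province", "country"))
assign_geo_level <- function(unit_type, synonyms = geo_level_synonyms()) {
  key <- trimws(tolower(unit_type))
  level <- unname(synonyms[key])
  if (anyNA(level)) {
    bad <- unique(key[is.na(level)])
    stop(
      "unknown geographic unit type(s): ", paste(sQuote(bad), collapse = ", "),
      "\naccepted types: ", paste(sort(names(synonyms)), collapse = ", "),
      call. = FALSE
    )
  }
  level
}

#' Canonical label for a geographic level
#'
#' @param level Integer vector of levels in 1..5.
#' @return Character vector: `"village"`, `"district"`, `"province"`,
#'   `"region"` or `"country"`.
#' @export
geo_level_label <- function(level) {
  if (!all(level %in% 1:5)) stop("`level` must be in 1..5", call. = FALSE)
  c("village", "district", "province", "region", "country")[level]
}
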