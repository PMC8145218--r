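#' Indicator catalog: indicator -> subgroup -> group
#'
#' Indicators with similar definitions are pooled into subgroups (e.g. stunting
#' prevalence at different ages), and subgroups into broad groups (child
#' anthropometry, child diet, ...). Every indicator maps to exactly one
#' subgroup and every subgroup to exactly one group. Regrouping refinements —
#' splitting an indicator out of its subgroup after inspecting the data, as was
#' done for early-infancy diarrhoea and car ownership — are expressed as
#' overrides so the original grouping stays visible.
#'
#' @param entries Data frame with columns `indicator_id`, `subgroup_id`,
#'   `group_id`.
#' @param overrides Optional data frame with columns `indicator_id`,
#'   `subgroup_id` and optionally `group_id`; each row moves one indicator to a
#'   new (possibly fresh) subgroup. When `group_id` is absent or `NA` the
#'   indicator keeps its current group.
#'
#' @return An object of class `indicator_catalog`.
#' @export
#' @examples
#' cat <- indicator_catalog(
#'   data.frame(
#'     indicator_id = c("stunting", "wasting"),
#'     subgroup_id = c("Stunting", "Wasting"),
#'     group_id = "Child anthropometry"
#'   )
#' )
#' catalog_lookup(cat, "stunting")
indicator_catalog <- function(entries, overrides = NULL) {
  entries <- tibble::as_tibble(entries)
  need <- c("indicator_id", "subgroup_id", "group_id")
  if (!all(need %in% names(entries))) {
    stop("catalog entries need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  entries <- entries[, need]
  if (anyDuplicated(entries$indicator_id)) {
    stop("duplicate indicator_id in catalog entries", call. = FALSE)
  }

  if (!is.null(overrides) && nrow(tibble::as_tibble(overrides)) > 0) {
    overrides <- tibble::as_tibble(overrides)
    if (!all(c("indicator_id", "subgroup_id") %in% names(overrides))) {
      stop("overrides need columns indicator_id and subgroup_id", call. = FALSE)
    }
    for (i in seq_len(nrow(overrides))) {
      id <- overrides$indicator_id[i]
      j <- match(id, entries$indicator_id)
      new_group <- if ("group_id" %in% names(overrides)) overrides$group_id[i] else NA_character_
      if (is.na(j)) {
        if (is.na(new_group)) {
          stop("override for unknown indicator ", sQuote(id),
               " must supply a group_id", call. = FALSE)
        }
        entries <- dplyr::bind_rows(entries, tibble::tibble(
          indicator_id = id,
          subgroup_id = overrides$subgroup_id[i],
          group_id = new_group
        ))
      } else {
        entries$subgroup_id[j] <- overrides$subgroup_id[i]
        if (!is.na(new_group)) entries$group_id[j] <- new_group
      }
    }
  }

  sub2grp <- unique(entries[, c("subgroup_id", "group_id")])
  if (anyDuplicated(sub2grp$subgroup_id)) {
    bad <- sub2grp$subgroup_id[duplicated(sub2grp$subgroup_id)]
    stop("subgroup(s) mapped to more than one group: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }

  structure(list(entries = entries), class = "indicator_catalog")
}

#' @export
print.indicator_catalog <- function(x, ...) {
  cat("<indicator_catalog> ", nrow(x$entries), " indicators, ",
      length(unique(x$entries$subgroup_id)), " subgroups, ",
      length(unique(x$entries$group_id)), " groups\n", sep = "")
  invisible(x)
}

#' Look up subgroup and group for indicator ids
#'
#' @param catalog An [indicator_catalog()].
#' @param indicator_id Character vector of indicator ids.
#' @return Tibble with columns `indicator_id`, `subgroup_id`, `group_id`,
#'   one row per input id. Unknown ids raise an error listing all offenders.
#' @export
catalog_lookup <- function(catalog, indicator_id) {
  stopifnot(inherits(catalog, "indicator_catalog"))
  j <- match(indicator_id, catalog$entries$indicator_id)
  if (anyNA(j)) {
    stop("indicator(s) not in catalog: ",
         paste(sQuote(unique(indicator_id[is.na(j)])), collapse = ", "),
         call. = FALSE)
  }
  catalog$entries[j, ]
}

#' Default indicator catalog shipped with the package
#'
#' The 37 indicator subgroups across 8 groups (child anthropometry, child
#' diet, child health, household characteristics, household wealth, maternal
#' characteristics, maternal health, WASH), each with a representative
#' indicator id. Early-infancy diarrhoea and household car ownership already
#' appear as their own subgroups, reflecting the standard regrouping
#' refinement.
#'
#' @return An [indicator_catalog()].
#' @export
default_indicator_catalog <- function() {
  path <- system.file("extdata", "indicator_catalog.csv", package = "svyconcord")
  entries <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  indicator_catalog(entries)
}
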