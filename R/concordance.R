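# Descriptive concordance summaries over matched pairs.

#' Proportion of pairs within k percentage points
#'
#' @param pairs Tibble of matched pairs (needs `abs_difference`).
#' @param k Concordance band half-width in percentage points; a pair counts as
#'   concordant when its absolute difference is at most `k` (inclusive).
#'
#' @return Percentage of pairs within the band, in 0-100.
#' @export
#' @examples
#' p <- derive_pair_metrics(
#'   tibble::tibble(country = "X", indicator_id = "i", source_name = "A",
#'                  geo_path = "X", geo_level = 5, year = 2015,
#'                  season = "unknown", n = 100, estimate = c(50, 40, 71)),
#'   tibble::tibble(country = "X", indicator_id = "i", source_name = "B",
#'                  geo_path = "X", geo_level = 5, year = 2015,
#'                  season = "unknown", n = 100, estimate = c(47, 47, 50))
#' )
#' within_band_proportion(p, 5)
within_band_proportion <- function(pairs, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("`k` must be a single positive number of percentage points", call. = FALSE)
  }
  if (nrow(pairs) == 0) {
    stop("within-band proportion is undefined for an empty pair set", call. = FALSE)
  }
  100 * mean(pairs$abs_difference <= k)
}

#' Per-subgroup concordance summary
#'
#' One row per indicator subgroup present in the pair set: number of pairs,
#' mean/SD of the reference and field estimates, mean/SD/min/max of the
#' difference (reference minus field, percentage points), and the percentage
#' of pairs within each band in `k`. Sample SDs (n - 1 denominator) are used
#' throughout; single-pair subgroups report `NA` SDs.
#'
#' @param pairs Tibble of matched pairs.
#' @param catalog An [indicator_catalog()] covering every indicator present.
#' @param k Numeric vector of concordance bands (default 5 and 20 pp).
#'
#' @return A tibble, one row per subgroup.
#' @export
summarize_subgroups <- function(pairs, catalog, k = c(5, 20)) {
  pairs <- tibble::as_tibble(pairs)
  look <- catalog_lookup(catalog, unique(pairs$indicator_id))
  d <- dplyr::left_join(pairs, look, by = "indicator_id")

  d |>
    dplyr::group_by(.data$group_id, .data$subgroup_id) |>
    dplyr::group_modify(function(g, key) {
      row <- tibble::tibble(
        n_pairs = nrow(g),
        ref_mean = mean(g$ref_estimate),
        ref_sd = stats::sd(g$ref_estimate),
        field_mean = mean(g$field_estimate),
        field_sd = stats::sd(g$field_estimate),
        diff_mean = mean(g$difference),
        diff_sd = stats::sd(g$difference),
        diff_min = min(g$difference),
        diff_max = max(g$difference)
      )
      for (kk in k) {
        row[[paste0("pct_within_", kk)]] <- 100 * mean(g$abs_difference <= kk)
      }
      row
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group_id, .data$subgroup_id)
}

# Rank-based tertiles of sample size; ties broken by stable input order,
# remainders go to the lower tertiles.
size_tertile <- function(n) {
  N <- length(n)
  sizes <- rep(N %/% 3L, 3L)
  extra <- N %% 3L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  g <- integer(N)
  g[order(n)] <- rep(1:3, times = sizes)
  factor(paste("Tertile", g), levels = paste("Tertile", 1:3))
}

#' Stratified summary of absolute differences
#'
#' Summarizes `abs_difference` (mean, sample SD, median, IQR; quantiles by
#' linear interpolation, R type 7) within strata defined by one of:
#'
#' * `"year_band"` — absolute year difference bands: at most 1 year, 1.5-3
#'   years, 3.5 years or more;
#' * `"season"` — season concordance (same / different / unknown);
#' * `"level_band"` — geographic level difference band (0 / 1 / 2+);
#' * `"geo_level"` — the geographic level of one member of the pair;
#' * `"size_tertile"` — rank-based tertiles of one member's sample size
#'   (Tertile 1 = smallest third).
#'
#' Strata that exist in the scheme but contain no pairs are reported with
#' `n_pairs = 0` and `NA` statistics.
#'
#' @param pairs Tibble of matched pairs.
#' @param scheme Stratification scheme, see above.
#' @param member Which member of the pair supplies the level or sample size for
#'   the `"geo_level"` and `"size_tertile"` schemes: `"ref"` or `"field"`.
#'
#' @return A tibble with columns `scheme`, `stratum`, `n_pairs`, `mean`, `sd`,
#'   `median`, `iqr`.
#' @export
summarize_strata <- function(pairs,
                             scheme = c("year_band", "season", "level_band",
                                        "geo_level", "size_tertile"),
                             member = c("ref", "field")) {
  scheme <- match.arg(scheme)
  member <- match.arg(member)
  pairs <- tibble::as_tibble(pairs)

  stratum <- switch(scheme,
    year_band = cut(pairs$abs_year_difference,
      breaks = c(-Inf, 1, 3, Inf),
      labels = c("<=1 year", "1.5-3 years", ">=3.5 years")
    ),
    season = factor(pairs$season_concordance,
      levels = c("same", "different", "unknown")
    ),
    level_band = pairs$level_diff_band,
    geo_level = factor(
      geo_level_label(pairs[[paste0(member, "_geo_level")]]),
      levels = c("country", "region", "province", "district", "village")
    ),
    size_tertile = size_tertile(pairs[[paste0(member, "_n")]])
  )

  tibble::tibble(stratum = stratum, x = pairs$abs_difference) |>
    dplyr::group_by(.data$stratum, .drop = FALSE) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean = if (dplyr::n() > 0) mean(.data$x) else NA_real_,
      sd = stats::sd(.data$x),
      median = if (dplyr::n() > 0) stats::median(.data$x) else NA_real_,
      iqr = if (dplyr::n() > 0) stats::IQR(.data$x, type = 7) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(scheme = scheme, .before = 1)
}

#' Five-number boxplot summary with Tukey whiskers
#'
#' Quartiles use linear interpolation (R quantile type 7). Whiskers extend to
#' the furthest observation within 1.5 x IQR of the quartiles; observations
#' beyond the whisker fences are counted as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `n`, `q1`, `median`, `q3`, `iqr`, `lower_whisker`,
#'   `upper_whisker`, `n_outliers`.
#' @export
#' @examples
#' boxplot_summary(1:100)
boxplot_summary <- function(values) {
  if (length(values) == 0 || !all(is.finite(values))) {
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  tibble::tibble(
    n = length(values),
    q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
    lower_whisker = min(values[values >= lo_fence]),
    upper_whisker = max(values[values <= hi_fence]),
    n_outliers = sum(values < lo_fence | values > hi_fence)
  )
}

# Half-open bands [lo, hi) over 0-100; the top band is closed so 100 belongs
# to it.
ref_value_band <- function(x, bin_width) {
  if (100 %% bin_width != 0) {
    stop("`bin_width` must divide 100", call. = FALSE)
  }
  lo <- pmin(floor(x / bin_width) * bin_width, 100 - bin_width)
  starts <- seq(0, 100 - bin_width, by = bin_width)
  labs <- sprintf("[%g,%g)", starts, starts + bin_width)
  labs[length(labs)] <- sprintf("[%g,%g]", 100 - bin_width, 100)
  factor(labs[lo / bin_width + 1], levels = labs)
}

#' Bin pairs by the reference estimate's value
#'
#' Assigns each pair to the half-open band `[lo, hi)` containing its reference
#' estimate (the top band is closed, so an estimate of exactly 100 falls in
#' it). Used to examine how agreement varies across the prevalence range.
#'
#' @param pairs Tibble of matched pairs.
#' @param bin_width Band width in percentage points; must divide 100.
#' @return `pairs` with an added `ref_bin` factor whose levels span all bands.
#' @export
bin_by_reference_value <- function(pairs, bin_width = 10) {
  pairs <- tibble::as_tibble(pairs)
  pairs$ref_bin <- ref_value_band(pairs$ref_estimate, bin_width)
  pairs
}
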