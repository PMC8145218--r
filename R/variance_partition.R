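# Sequential (Type I) partition of difference variance across pair factors.

#' Partition the variance of pair differences across factors
#'
#' Decomposes the total corrected sum of squares of the chosen response
#' (difference or absolute difference between paired estimates) into shares
#' attributable to each factor plus an unattributed residual ("Other"), using
#' sequential (Type I) sums of squares: factors enter a least-squares fit in
#' the stated order and each factor's share is the increase in explained sum
#' of squares when it is added, as a percentage of the total. Shares are
#' non-negative and sum with the residual to 100.
#'
#' The default factor order is indicator, geographic level difference band,
#' year difference (a single linear continuous term), and season concordance.
#' For same-source scenario pairs drop `"season_concordance"` from `factors`,
#' since a single source usually collects within one season per country.
#' Character/factor columns enter as categorical factors (full-rank contrasts;
#' the shares do not depend on the contrast coding), numeric columns as one
#' continuous column. A factor that is constant over the pair set contributes
#' exactly 0.
#'
#' @param pairs Tibble of matched pairs (at least 2 rows).
#' @param response `"difference"` or `"abs_difference"`.
#' @param factors Character vector of pair columns, in entry order.
#'
#' @return An object of class `variance_partition` with a `table` of terms
#'   (`term`, `kind`, `df`, `ss`, `share`), the response name, `n` and
#'   `total_ss`. The last table row is the residual, labelled `"Other"`.
#' @export
#' @examples
#' ref <- tibble::tibble(country = "X", indicator_id = rep(c("a", "b"), 2),
#'                       source_name = "R", geo_path = "X", geo_level = 5,
#'                       year = 2015, season = "unknown", n = 100,
#'                       estimate = c(10, 40, 12, 38))
#' fld <- dplyr::mutate(ref, source_name = "F", estimate = c(10, 10, 12, 12))
#' vp <- partition_variance(derive_pair_metrics(ref, fld),
#'                          factors = "indicator_id")
#' variance_shares(vp)
partition_variance <- function(pairs,
                               response = c("difference", "abs_difference"),
                               factors = c("indicator_id", "level_diff_band",
                                           "year_difference",
                                           "season_concordance")) {
  response <- match.arg(response)
  pairs <- tibble::as_tibble(pairs)
  missing_cols <- setdiff(factors, names(pairs))
  if (length(missing_cols) > 0) {
    stop("factor column(s) not in pairs: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  y <- pairs[[response]]
  n <- length(y)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  total_ss <- sum((y - mean(y))^2)
  if (total_ss == 0) {
    stop("response is constant across pairs: total sum of squares is zero",
      call. = FALSE
    )
  }

  cols <- lapply(factors, function(f) {
    v <- pairs[[f]]
    if (is.numeric(v)) v else droplevels(factor(v))
  })
  kinds <- vapply(cols, function(v) {
    if (is.factor(v)) "categorical" else "continuous"
  }, character(1))
  degenerate <- vapply(cols, function(v) {
    if (is.factor(v)) nlevels(v) < 2 else stats::var(v) == 0
  }, logical(1))

  # syntactic internal names so anova() row labels are predictable
  internal <- paste0(".f", seq_along(factors))
  ss <- stats::setNames(rep(0, length(factors)), internal)
  dfree <- stats::setNames(rep(0L, length(factors)), internal)

  active <- internal[!degenerate]
  if (length(active) > 0) {
    dat <- stats::setNames(cols, internal)[!degenerate]
    dat$..y <- y
    fit <- stats::lm(stats::reformulate(active, response = "..y"),
      data = as.data.frame(dat, check.names = FALSE)
    )
    # only the sequential SS are used; silence anova's F-test warnings on
    # saturated (perfect) fits
    an <- suppressWarnings(stats::anova(fit))
    ss[active] <- an[active, "Sum Sq"]
    dfree[active] <- an[active, "Df"]
  }

  resid_ss <- total_ss - sum(ss)
  all_ss <- c(unname(ss), resid_ss)
  tab <- tibble::tibble(
    term = c(factors, "Other"),
    kind = c(kinds, "residual"),
    df = c(unname(dfree), n - 1L - sum(dfree)),
    ss = all_ss,
    share = 100 * all_ss / total_ss
  )
  structure(
    list(table = tab, response = response, n = n, total_ss = total_ss),
    class = "variance_partition"
  )
}

#' Extract variance shares
#'
#' @param x A `variance_partition` object.
#' @return Named numeric vector of percent shares (factors plus `"Other"`),
#'   summing to 100.
#' @export
variance_shares <- function(x) {
  stopifnot(inherits(x, "variance_partition"))
  stats::setNames(x$table$share, x$table$term)
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition of ", x$response, " (sequential SS, n = ", x$n,
    ")\n",
    sep = ""
  )
  tab <- x$table
  cat(sprintf("  %-22s %-12s %5s %10s %8s\n", "term", "kind", "df", "SS", "share%"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-22s %-12s %5d %10.3f %8.2f\n",
      tab$term[i], tab$kind[i], tab$df[i], tab$ss[i], tab$share[i]
    ))
  }
  invisible(x)
}

#' Brute-force one-way variance share
#'
#' Direct computation of the percent of total corrected sum of squares
#' explained by a single grouping: `100 * SS_between / SS_total` from group
#' means. Serves as an independent check of [partition_variance()] with one
#' categorical factor.
#'
#' @param values Numeric response (length at least 2, non-constant).
#' @param labels Group labels, same length as `values`.
#' @return Percent between-group share in 0-100.
#' @export
#' @examples
#' one_way_oracle(c(0, 0, 10, 10), c("a", "a", "b", "b")) # 100
#' one_way_oracle(c(0, 10, 0, 10), c("a", "a", "b", "b")) # 0
one_way_oracle <- function(values, labels) {
  if (length(values) < 2 || length(labels) != length(values)) {
    stop("need >= 2 values with matching labels", call. = FALSE)
  }
  total_ss <- sum((values - mean(values))^2)
  if (total_ss == 0) {
    stop("values are constant: total sum of squares is zero", call. = FALSE)
  }
  group_mean <- tapply(values, labels, mean)
  group_n <- tapply(values, labels, length)
  100 * sum(group_n * (group_mean - mean(values))^2) / total_ss
}
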