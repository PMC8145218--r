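# Pure sampling-error model: the difference between two independent binomial
# prevalence estimates of the same true prevalence.

#' Configuration for the sampling-error simulation
#'
#' Defaults reflect the study conditions: true prevalences of 1%, 10%, 20%,
#' ..., 90% and 99%, a sample size of 500 per estimate (a typical survey
#' sample size for a single indicator), and 1,000 iterations per prevalence.
#'
#' @param p_grid True prevalences as proportions in `[0, 1]`.
#' @param n Observations per estimate (positive integer).
#' @param iterations Monte Carlo iterations per prevalence.
#' @param seed Integer root seed; per-prevalence streams are derived from it.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(p_grid = c(0.01, seq(0.1, 0.9, by = 0.1), 0.99),
                              n = 500, iterations = 1000, seed = 1L) {
  stopifnot(
    all(p_grid >= 0 & p_grid <= 1),
    length(p_grid) >= 1,
    n >= 1, n %% 1 == 0,
    iterations >= 1, iterations %% 1 == 0,
    length(seed) == 1
  )
  structure(
    list(
      p_grid = as.numeric(p_grid), n = as.integer(n),
      iterations = as.integer(iterations), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate differences between two independent prevalence estimates
#'
#' For each true prevalence p in the grid, draws two independent
#' binomial(n, p) counts per iteration, converts each to a percent estimate,
#' and records the signed difference (estimate 1 minus estimate 2) in
#' percentage points. This isolates pure sampling error: any spread wider than
#' these distributions in real paired data must come from something other than
#' sampling.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_differences`: the config plus a
#'   tibble `draws` with columns `p` and list-column `differences`
#'   (one numeric vector of length `iterations` per prevalence).
#' @export
#' @examples
#' sim <- simulate_difference_distribution(simulation_config(seed = 7))
#' simulation_summary(sim)
simulate_difference_distribution <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  stream_seeds <- sample.int(2147483647L, length(config$p_grid))
  differences <- purrr::map2(config$p_grid, stream_seeds, function(p, s) {
    set.seed(s)
    b1 <- stats::rbinom(config$iterations, config$n, p)
    b2 <- stats::rbinom(config$iterations, config$n, p)
    100 * (b1 - b2) / config$n
  })
  structure(
    list(
      config = config,
      draws = tibble::tibble(p = config$p_grid, differences = differences)
    ),
    class = "simulated_differences"
  )
}

#' @export
print.simulated_differences <- function(x, ...) {
  cat("<simulated_differences> ", nrow(x$draws), " prevalences x ",
      x$config$iterations, " iterations (n = ", x$config$n, ")\n", sep = "")
  invisible(x)
}

#' Summarize a sampling-error simulation
#'
#' @param sim A `simulated_differences` object.
#' @return A tibble with one row per true prevalence: mean and SD of the
#'   signed differences, the closed-form SD from [analytic_sd()], and the
#'   [boxplot_summary()] of the absolute differences (columns prefixed
#'   `abs_`).
#' @export
simulation_summary <- function(sim) {
  stopifnot(inherits(sim, "simulated_differences"))
  purrr::map2(sim$draws$p, sim$draws$differences, function(p, d) {
    box <- boxplot_summary(abs(d))
    names(box) <- paste0("abs_", names(box))
    dplyr::bind_cols(
      tibble::tibble(
        p = p,
        mean_difference = mean(d),
        sd_difference = stats::sd(d),
        analytic_sd = analytic_sd(p, sim$config$n)
      ),
      box
    )
  }) |>
    dplyr::bind_rows()
}

#' Closed-form SD of the difference of two independent prevalence estimates
#'
#' The variance of one binomial proportion estimate is p(1 - p)/n; two
#' independent estimates of the same p differ with variance 2 p (1 - p) / n,
#' so the SD of their difference in percentage points is
#' `100 * sqrt(2 p (1 - p) / n)`.
#'
#' @param p True prevalence as a proportion in `[0, 1]`.
#' @param n Observations per estimate.
#' @return SD in percentage points.
#' @export
#' @examples
#' analytic_sd(0.5, 500) # 3.1623 pp
analytic_sd <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  100 * sqrt(2 * p * (1 - p) / n)
}

#' Half-width of a normal-approximation confidence interval
#'
#' @param se Standard error of the estimate, in percentage points.
#' @param level Confidence level (default 0.95).
#' @return Half-width in percentage points (1.96 x se at 95%).
#' @export
#' @examples
#' normal_ci_half_width(5) # ~9.8 pp
normal_ci_half_width <- function(se, level = 0.95) {
  stopifnot(level > 0, level < 1, all(se >= 0))
  stats::qnorm((1 + level) / 2) * se
}

#' Align boxplot summaries of simulated and observed absolute differences
#'
#' Produces one boxplot summary row per reference-value band for the
#' simulation (each simulated prevalence is keyed by the band containing
#' 100 x p) and for each observed pair set (binned by reference estimate via
#' [bin_by_reference_value()]), aligned so the series can be compared band by
#' band.
#'
#' @param sim A `simulated_differences` object.
#' @param ... Named tibbles of matched pairs (e.g. `cross_source = pairs`).
#' @param bin_width Reference-value band width in percentage points.
#' @return A tibble with columns `series`, `band`, and the
#'   [boxplot_summary()] columns.
#' @export
compare_distributions <- function(sim, ..., bin_width = 10) {
  stopifnot(inherits(sim, "simulated_differences"))
  observed <- list(...)
  if (length(observed) > 0 && is.null(names(observed))) {
    names(observed) <- paste0("observed_", seq_along(observed))
  }

  sim_rows <- purrr::map2(sim$draws$p, sim$draws$differences, function(p, d) {
    dplyr::bind_cols(
      tibble::tibble(
        series = "simulation",
        band = ref_value_band(100 * p, bin_width)
      ),
      boxplot_summary(abs(d))
    )
  }) |>
    dplyr::bind_rows()

  obs_rows <- purrr::imap(observed, function(pairs, nm) {
    binned <- bin_by_reference_value(pairs, bin_width)
    split(binned$abs_difference, binned$ref_bin) |>
      purrr::imap(function(v, band) {
        if (length(v) == 0) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(series = nm,
                         band = factor(band, levels = levels(binned$ref_bin))),
          boxplot_summary(v)
        )
      }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()

  dplyr::bind_rows(sim_rows, obs_rows) |>
    dplyr::arrange(.data$series, .data$band)
}
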