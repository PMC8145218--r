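# Synthetic two-source survey landscapes with known ground truth.
#
# The data-generating model is additive on the logit scale so that geographic
# heterogeneity, temporal drift, seasonality and per-source method bias
# compose without leaving (0, 1):
#
#   logit p(i, g, t, s) = mu_i + sum(level effects along g's path)
#                          + beta_i * (t - base_year) + gamma_i * 1[s == "wet"]
#
# An emitted estimate for source k draws a count from
# binomial(n_eff, invlogit(logit p + delta_{k,i})) with n_eff = round(n/DEFF):
# the design effect of cluster sampling is modelled as effective-sample-size
# deflation rather than explicit cluster simulation.

#' Configuration of the synthetic survey data-generating model
#'
#' Defaults describe a realistic small-country landscape: a 4-level geography
#' under one country, a dozen prevalence indicators with baselines spread
#' logit-uniformly over 5-95%, modest geographic heterogeneity (0.2-0.3 on the
#' logit scale), slow secular drift, a mild seasonal effect, per-source
#' method bias of SD 0.25 logit, and estimates of n = 500 with a design
#' effect of 1.5. The reference source reports provinces and the national
#' level over two cycles; the field source reports districts in a single later
#' year.
#'
#' @param country Country name (root of every geographic path).
#' @param n_regions,n_provinces,n_districts,n_villages Units per parent
#'   (villages default 0, i.e. level 1 is not populated).
#' @param n_indicators Number of indicators.
#' @param prevalence_range Baseline prevalences are drawn uniformly on the
#'   logit of this range.
#' @param sd_region,sd_province,sd_district,sd_village SDs of the additive
#'   unit effects per level, logit scale.
#' @param drift_mean,drift_sd Per-indicator linear time trend (logit/year).
#' @param season_sd SD of the per-indicator wet-season effect (logit).
#' @param method_bias_sd SD of the per-(source, indicator) bias delta (logit).
#' @param n_per_estimate Nominal observations behind each estimate.
#' @param deff Design effect (>= 1); the effective sample size is
#'   `round(n_per_estimate / deff)`.
#' @param ref_cycles,field_cycles Decimal years of each source's survey
#'   cycles.
#' @param ref_levels,field_levels Geographic levels each source reports.
#' @param ref_season,field_season Season label of each source's fieldwork.
#' @param season_unknown_frac Fraction of emitted records whose season label
#'   is masked to `"unknown"`.
#' @param field_site_quantile Optional field-source site-selection bias: the
#'   field source surveys only the fraction of units (per level) with the
#'   lowest combined geographic effect, emulating NGO targeting of worse-off
#'   areas. 1 (the default) surveys every unit.
#' @param base_year Year at which the drift term is zero.
#' @param seed Integer seed; the whole landscape is reproducible from it.
#'
#' @return An object of class `dgm_config`.
#' @export
dgm_config <- function(country = "Atlantis",
                       n_regions = 3, n_provinces = 4, n_districts = 3,
                       n_villages = 0,
                       n_indicators = 12, prevalence_range = c(0.05, 0.95),
                       sd_region = 0.3, sd_province = 0.25, sd_district = 0.2,
                       sd_village = 0.2,
                       drift_mean = 0, drift_sd = 0.05, season_sd = 0.1,
                       method_bias_sd = 0.25,
                       n_per_estimate = 500, deff = 1.5,
                       ref_cycles = c(2010, 2014), field_cycles = 2016,
                       ref_levels = c(3, 5), field_levels = 2,
                       ref_season = "dry", field_season = "wet",
                       season_unknown_frac = 0, field_site_quantile = 1,
                       base_year = 2015, seed = 1L) {
  cfg <- list(
    country = country,
    n_regions = n_regions, n_provinces = n_provinces,
    n_districts = n_districts, n_villages = n_villages,
    n_indicators = n_indicators, prevalence_range = prevalence_range,
    sd_region = sd_region, sd_province = sd_province,
    sd_district = sd_district, sd_village = sd_village,
    drift_mean = drift_mean, drift_sd = drift_sd, season_sd = season_sd,
    method_bias_sd = method_bias_sd,
    n_per_estimate = n_per_estimate, deff = deff,
    ref_cycles = sort(ref_cycles), field_cycles = sort(field_cycles),
    ref_levels = sort(ref_levels), field_levels = sort(field_levels),
    ref_season = ref_season, field_season = field_season,
    season_unknown_frac = season_unknown_frac,
    field_site_quantile = field_site_quantile,
    base_year = base_year, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_regions >= 1, cfg$n_provinces >= 1, cfg$n_districts >= 1,
    cfg$n_villages >= 0, cfg$n_indicators >= 1,
    length(cfg$prevalence_range) == 2,
    all(cfg$prevalence_range > 0 & cfg$prevalence_range < 1),
    cfg$sd_region >= 0, cfg$sd_province >= 0, cfg$sd_district >= 0,
    cfg$sd_village >= 0, cfg$drift_sd >= 0, cfg$season_sd >= 0,
    cfg$method_bias_sd >= 0,
    cfg$n_per_estimate >= 1, cfg$deff >= 1,
    length(cfg$ref_cycles) >= 1, length(cfg$field_cycles) >= 1,
    all(cfg$ref_levels %in% 1:5), all(cfg$field_levels %in% 1:5),
    cfg$season_unknown_frac >= 0, cfg$season_unknown_frac <= 1,
    cfg$field_site_quantile > 0, cfg$field_site_quantile <= 1
  )
  structure(cfg, class = "dgm_config")
}

# Build the unit hierarchy with per-unit logit effects; parents precede
# children so cumulative effects can be accumulated in one pass.
build_units <- function(cfg) {
  units <- tibble::tibble(
    geo_path = cfg$country, geo_level = 5L, parent = NA_character_
  )
  add_level <- function(units, parent_level, child_level, count, prefix) {
    parents <- units$geo_path[units$geo_level == parent_level]
    if (count == 0 || length(parents) == 0) return(units)
    kids <- tidyr::expand_grid(parent = parents, k = seq_len(count))
    kids$geo_path <- paste0(kids$parent, ">", prefix,
                            match(kids$parent, parents), ".", kids$k)
    dplyr::bind_rows(units, tibble::tibble(
      geo_path = kids$geo_path, geo_level = child_level, parent = kids$parent
    ))
  }
  units <- add_level(units, 5L, 4L, cfg$n_regions, "R")
  units <- add_level(units, 4L, 3L, cfg$n_provinces, "P")
  units <- add_level(units, 3L, 2L, cfg$n_districts, "D")
  units <- add_level(units, 2L, 1L, cfg$n_villages, "V")

  level_sd <- c(cfg$sd_village, cfg$sd_district, cfg$sd_province,
                cfg$sd_region, 0)
  units$effect <- stats::rnorm(nrow(units), 0, level_sd[units$geo_level])
  units$cum_effect <- units$effect
  for (i in seq_len(nrow(units))) {
    if (!is.na(units$parent[i])) {
      j <- match(units$parent[i], units$geo_path)
      units$cum_effect[i] <- units$cum_effect[j] + units$effect[i]
    }
  }
  units
}

#' Generate a synthetic two-source survey landscape
#'
#' Draws all latent parameters (baseline prevalences, geographic unit effects,
#' drift, seasonal and method-bias terms), then emits one estimate record per
#' (source, cycle, reporting unit, indicator) with binomial sampling noise at
#' the effective sample size. Both record tables pass [validate_records()] and
#' round-trip through [write_estimates()] / [read_estimates()] unchanged.
#'
#' @param config A [dgm_config()].
#' @return A list with `field` and `reference` (estimate tibbles) and `truth`
#'   (class `synthetic_truth`: the config, per-indicator parameters, per-unit
#'   effects, realized per-source biases, and every true prevalence used).
#' @export
#' @examples
#' land <- generate_landscape(dgm_config(n_indicators = 3, seed = 42))
#' nrow(land$field)
generate_landscape <- function(config) {
  stopifnot(inherits(config, "dgm_config"))
  cfg <- config
  set.seed(cfg$seed)

  units <- build_units(cfg)
  indicators <- tibble::tibble(
    indicator_id = sprintf("ind%02d", seq_len(cfg$n_indicators)),
    mu = stats::runif(
      cfg$n_indicators,
      stats::qlogis(cfg$prevalence_range[1]),
      stats::qlogis(cfg$prevalence_range[2])
    ),
    drift = stats::rnorm(cfg$n_indicators, cfg$drift_mean, cfg$drift_sd),
    season_effect = stats::rnorm(cfg$n_indicators, 0, cfg$season_sd)
  )
  indicators$baseline_prevalence <- stats::plogis(indicators$mu)
  bias <- tibble::tibble(
    source_kind = rep(c("reference", "field"), each = cfg$n_indicators),
    indicator_id = rep(indicators$indicator_id, 2),
    delta = stats::rnorm(2 * cfg$n_indicators, 0, cfg$method_bias_sd)
  )
  n_eff <- max(1L, as.integer(round(cfg$n_per_estimate / cfg$deff)))

  emit <- function(kind, source_name, levels, cycles, season) {
    u <- units[units$geo_level %in% levels, , drop = FALSE]
    if (kind == "field" && cfg$field_site_quantile < 1) {
      u <- u |>
        dplyr::group_by(.data$geo_level) |>
        dplyr::filter(.data$cum_effect <= stats::quantile(
          .data$cum_effect, cfg$field_site_quantile, type = 7
        )) |>
        dplyr::ungroup()
    }
    grid <- tidyr::expand_grid(
      u[, c("geo_path", "geo_level", "cum_effect")],
      indicators[, c("indicator_id", "mu", "drift", "season_effect")],
      year = cycles
    )
    logit_p <- grid$mu + grid$cum_effect +
      grid$drift * (grid$year - cfg$base_year) +
      grid$season_effect * (season == "wet")
    p_true <- stats::plogis(logit_p)
    d <- bias$delta[match(
      paste(kind, grid$indicator_id),
      paste(bias$source_kind, bias$indicator_id)
    )]
    p_obs <- stats::plogis(logit_p + d)
    count <- stats::rbinom(nrow(grid), n_eff, p_obs)
    season_label <- rep(season, nrow(grid))
    if (cfg$season_unknown_frac > 0) {
      season_label[stats::runif(nrow(grid)) < cfg$season_unknown_frac] <- "unknown"
    }
    list(
      records = tibble::tibble(
        source_kind = kind,
        source_name = source_name,
        country = cfg$country,
        geo_path = grid$geo_path,
        geo_level_type = geo_level_label(grid$geo_level),
        year_raw = format_year(grid$year),
        season = season_label,
        indicator_id = grid$indicator_id,
        n = n_eff,
        estimate = 100 * count / n_eff,
        sd = NA_real_,
        population = NA_character_,
        year = grid$year,
        geo_level = grid$geo_level
      ),
      prevalence = tibble::tibble(
        indicator_id = grid$indicator_id,
        geo_path = grid$geo_path,
        geo_level = grid$geo_level,
        year = grid$year,
        season = season,
        p_true = p_true
      )
    )
  }

  ref <- emit("reference", "PUBSURV", cfg$ref_levels, cfg$ref_cycles,
              cfg$ref_season)
  fld <- emit("field", "NGO", cfg$field_levels, cfg$field_cycles,
              cfg$field_season)

  validate_records(ref$records)
  validate_records(fld$records)

  truth <- structure(
    list(
      config = cfg,
      indicators = indicators,
      units = units,
      bias = bias,
      n_eff = n_eff,
      prevalence = dplyr::distinct(
        dplyr::bind_rows(ref$prevalence, fld$prevalence)
      )
    ),
    class = "synthetic_truth"
  )
  list(field = fld$records, reference = ref$records, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$indicators), " indicators, ",
      nrow(x$units), " geographic units, n_eff = ", x$n_eff, "\n", sep = "")
  invisible(x)
}

#' Aggregate estimates up to a containing unit
#'
#' Combines estimates for units under a common parent into one estimate for
#' the parent: the sample-size-weighted mean, with the summed n. All records
#' must share the same source, indicator and year, and lie within the parent
#' unit.
#'
#' @param records Estimate records for the child units.
#' @param parent_path Geographic path of the parent unit.
#' @param parent_level Geographic level of the parent unit.
#' @return A one-row estimate tibble at the parent level.
#' @export
#' @examples
#' kids <- tibble::tibble(
#'   source_kind = "reference", source_name = "S", country = "X",
#'   geo_path = c("X>A", "X>B"), geo_level_type = "region",
#'   year_raw = "2015", season = "dry", indicator_id = "i",
#'   n = c(100L, 300L), estimate = c(40, 80), sd = NA_real_,
#'   population = NA_character_, year = 2015, geo_level = 4L
#' )
#' aggregate_up(kids, "X", 5)$estimate # 70
aggregate_up <- function(records, parent_path, parent_level) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no records to aggregate", call. = FALSE)
  single <- function(col) {
    v <- unique(records[[col]])
    if (length(v) != 1) {
      stop("cannot aggregate mixed ", col, " values", call. = FALSE)
    }
    v
  }
  indicator_id <- single("indicator_id")
  year <- single("year")
  source_kind <- single("source_kind")
  source_name <- single("source_name")
  country <- single("country")
  contained <- vapply(records$geo_path, is_path_prefix, logical(1),
                      prefix = parent_path)
  if (!all(contained)) {
    stop("record(s) not contained in parent unit ", sQuote(parent_path),
         call. = FALSE)
  }
  if (any(records$geo_level > parent_level)) {
    stop("record(s) at a higher level than the parent", call. = FALSE)
  }
  seasons <- unique(records$season)
  tibble::tibble(
    source_kind = source_kind,
    source_name = source_name,
    country = country,
    geo_path = parent_path,
    geo_level_type = geo_level_label(parent_level),
    year_raw = format_year(year),
    season = if (length(seasons) == 1) seasons else "unknown",
    indicator_id = indicator_id,
    n = as.integer(sum(records$n)),
    estimate = stats::weighted.mean(records$estimate, records$n),
    sd = NA_real_,
    population = NA_character_,
    year = year,
    geo_level = as.integer(parent_level)
  )
}

#' Compare injected mechanisms against recovered variance shares
#'
#' Lines up each mechanism the generator injected (per-indicator method bias,
#' geographic-level heterogeneity, temporal drift, seasonality) with the
#' variance share its matching factor received in a [partition_variance()] of
#' pairs built from the generated records, and flags the factor with the
#' largest share.
#'
#' @param truth The `synthetic_truth` from [generate_landscape()].
#' @param partition A `variance_partition` fitted on pairs built from the
#'   generated records.
#' @return A tibble with columns `term`, `mechanism`, `injected_sd` (the
#'   realized logit-scale magnitude of the injected effect; `NA` for the
#'   residual) and `share`, plus `largest_factor`.
#' @export
recovery_report <- function(truth, partition) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(partition, "variance_partition"))
  shares <- variance_shares(partition)
  cfg <- truth$config

  delta_gap <- tidyr::pivot_wider(truth$bias,
    names_from = "source_kind", values_from = "delta"
  )
  bias_sd <- stats::sd(delta_gap$reference - delta_gap$field)
  geo_sd <- sqrt(cfg$sd_region^2 + cfg$sd_province^2 +
                 cfg$sd_district^2 + cfg$sd_village^2)
  injected <- c(
    indicator_id = bias_sd,
    level_diff_band = geo_sd,
    year_difference = stats::sd(truth$indicators$drift),
    season_concordance = stats::sd(truth$indicators$season_effect)
  )
  mechanism <- c(
    indicator_id = "per-indicator method bias",
    level_diff_band = "geographic heterogeneity",
    year_difference = "temporal drift",
    season_concordance = "seasonality",
    Other = "residual (sampling noise + unattributed)"
  )

  terms <- names(shares)
  factor_terms <- setdiff(terms, "Other")
  largest <- factor_terms[which.max(shares[factor_terms])]
  tibble::tibble(
    term = terms,
    mechanism = unname(mechanism[terms]),
    injected_sd = unname(injected[terms]),
    share = unname(shares[terms]),
    largest_factor = terms == largest
  )
}
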