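# End-to-end pipeline: read, validate, filter, match, summarize, partition,
# simulate; write CSV outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' @param field_path,ref_path CSV paths of the field and reference estimate
#'   tables.
#' @param out_dir Output directory (created if absent).
#' @param catalog An [indicator_catalog()], or `NULL` to skip the subgroup
#'   summary.
#' @param allow_posterior,max_climb Matching policy, see
#'   [build_cross_source_pairs()].
#' @param within_k Concordance bands in percentage points.
#' @param partition_factors Factor entry order for [partition_variance()].
#' @param responses Responses to partition.
#' @param same_source Also build S1/S2/S3 scenario pairs from the reference
#'   table (requires two reference cycles).
#' @param simulation A [simulation_config()], or `NULL` to skip the
#'   sampling-error simulation. Its seed is overridden by `seed`.
#' @param min_n Minimum retained sample size.
#' @param seed Root seed governing every stochastic stage.
#' @param synonyms Unit-type synonym map.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(field_path, ref_path, out_dir,
                            catalog = NULL,
                            allow_posterior = TRUE, max_climb = Inf,
                            within_k = c(5, 20),
                            partition_factors = c("indicator_id",
                                                  "level_diff_band",
                                                  "year_difference",
                                                  "season_concordance"),
                            responses = c("difference", "abs_difference"),
                            same_source = FALSE,
                            simulation = simulation_config(),
                            min_n = 10, seed = 1L,
                            synonyms = geo_level_synonyms()) {
  stopifnot(length(within_k) >= 1, all(within_k > 0))
  structure(
    list(
      field_path = field_path, ref_path = ref_path, out_dir = out_dir,
      catalog = catalog, allow_posterior = allow_posterior,
      max_climb = max_climb, within_k = within_k,
      partition_factors = partition_factors, responses = responses,
      same_source = same_source, simulation = simulation,
      min_n = min_n, seed = as.integer(seed), synonyms = synonyms
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()] (paths,
#' policy flags, `within_k`, `partition_factors`, `responses`, `same_source`,
#' `min_n`, `seed`, plus an optional `catalog_path` and a `simulation` block
#' with `p_grid`, `n`, `iterations`).
#'
#' @param path YAML file path.
#' @return An object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), c(
    "field_path", "ref_path", "out_dir", "allow_posterior", "max_climb",
    "within_k", "partition_factors", "responses", "same_source", "min_n",
    "seed"
  ))]
  if (!is.null(raw$catalog_path)) {
    entries <- readr::read_csv(raw$catalog_path, col_types = "ccc",
                               progress = FALSE)
    args$catalog <- indicator_catalog(entries)
  }
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    # YAML 1.1 reads a bare `n` key as the boolean FALSE; undo that
    names(sim)[names(sim) %in% c("FALSE", "false")] <- "n"
    args$simulation <- do.call(simulation_config, sim)
  }
  do.call(pipeline_config, args)
}

write_display <- function(df, path) {
  # companion table rounded to the 1-decimal style of printed reports
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 1)
  readr::write_csv(df, path, na = "")
}

#' Run the full concordance pipeline
#'
#' Reads and validates both estimate tables, applies the minimum-n exclusion,
#' builds cross-source matched pairs (and optionally same-source scenario
#' pairs), writes concordance summaries, variance partitions and the
#' sampling-error simulation summary to `out_dir`, along with a JSON manifest
#' recording the seed, package version and the record/pair counts at every
#' stage. Outputs are reproducible: rerunning with the same inputs, config and
#' seed writes byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  field <- read_estimates(config$field_path, synonyms = config$synonyms)
  ref <- read_estimates(config$ref_path, synonyms = config$synonyms)
  ffilt <- filter_min_n(field, config$min_n)
  rfilt <- filter_min_n(ref, config$min_n)

  match <- build_cross_source_pairs(
    ffilt$retained, rfilt$retained,
    allow_posterior = config$allow_posterior, max_climb = config$max_climb
  )
  pairs <- match$pairs
  readr::write_csv(pairs, out("pairs.csv"), na = "")
  readr::write_csv(match$no_match, out("no_match.csv"), na = "")

  outputs <- c("pairs.csv", "no_match.csv")
  notes <- character(0)

  if (nrow(pairs) > 0) {
    if (!is.null(config$catalog)) {
      sub <- summarize_subgroups(pairs, config$catalog, k = config$within_k)
      readr::write_csv(sub, out("subgroup_summary.csv"), na = "")
      write_display(sub, out("subgroup_summary_display.csv"))
      outputs <- c(outputs, "subgroup_summary.csv", "subgroup_summary_display.csv")
    }
    strata <- dplyr::bind_rows(lapply(
      c("year_band", "season", "level_band", "geo_level", "size_tertile"),
      function(s) summarize_strata(pairs, s)
    ))
    readr::write_csv(strata, out("strata_summary.csv"), na = "")
    write_display(strata, out("strata_summary_display.csv"))
    outputs <- c(outputs, "strata_summary.csv", "strata_summary_display.csv")

    parts <- list()
    for (resp in config$responses) {
      vp <- tryCatch(
        partition_variance(pairs, resp, config$partition_factors),
        error = function(e) NULL
      )
      if (is.null(vp)) {
        notes <- c(notes, paste0("variance partition skipped for ", resp))
      } else {
        parts[[resp]] <- dplyr::mutate(vp$table, response = resp, .before = 1)
      }
    }
    if (length(parts) > 0) {
      readr::write_csv(dplyr::bind_rows(parts), out("variance_partition.csv"),
                       na = "")
      outputs <- c(outputs, "variance_partition.csv")
    }
  } else {
    notes <- c(notes, "no pairs built; summaries skipped")
  }

  scenario_n <- NA_integer_
  if (isTRUE(config$same_source)) {
    scen <- build_same_source_scenarios(rfilt$retained)
    readr::write_csv(scen, out("scenario_pairs.csv"), na = "")
    outputs <- c(outputs, "scenario_pairs.csv")
    scenario_n <- nrow(scen)
  }

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    sim <- simulate_difference_distribution(sim_cfg)
    readr::write_csv(simulation_summary(sim), out("simulation_summary.csv"),
                     na = "")
    outputs <- c(outputs, "simulation_summary.csv")
  }

  manifest <- list(
    package = "svyconcord",
    version = as.character(utils::packageVersion("svyconcord")),
    seed = config$seed,
    min_n = config$min_n,
    counts = list(
      field_read = nrow(field),
      field_excluded = ffilt$n_excluded,
      field_retained = nrow(ffilt$retained),
      ref_read = nrow(ref),
      ref_excluded = rfilt$n_excluded,
      ref_retained = nrow(rfilt$retained),
      pairs = nrow(pairs),
      no_match = nrow(match$no_match),
      scenario_pairs = scenario_n
    ),
    outputs = outputs,
    notes = notes
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(manifest)
}
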