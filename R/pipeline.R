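#' Pipeline orchestration
#'
#' Each `run_*()` step reads the flat-file inputs, executes one analysis
#' stage and writes stable, documented CSV outputs plus a YAML run
#' manifest (configuration echo and warning counts). `run_report()`
#' chains indicators, correction, rates and trends into one output
#' directory. All thresholds of the method — the 30/50/70% window
#' breakpoints, the tier bounds, the 0.05 significance level, the
#' 2005/2015 comparison years and the 5-year trend minimum — are
#' arguments with the method's values as defaults, so sensitivity
#' analyses need no code change.
#'
#' @name pipeline
NULL

#' Assemble a run configuration
#'
#' @param deaths,population,income input CSV paths (income optional).
#' @param age_floor 65 (default) or 0.
#' @param ages indicator restriction, `"65plus"` or `"all"`.
#' @param policy window policy from [window_policy()].
#' @param comparison_years two years for the before/after change, default
#'   `c(2005, 2015)`.
#' @param min_trend_years minimum data years for a trend fit, default 5.
#' @param alpha two-sided significance level, default 0.05.
#' @param population_units `"persons"` or `"thousands"`.
#' @return a `run_config` list.
#' @export
run_config <- function(deaths, population = NULL, income = NULL,
                       age_floor = 65, ages = "65plus",
                       policy = window_policy(),
                       comparison_years = c(2005L, 2015L),
                       min_trend_years = 5L, alpha = 0.05,
                       population_units = "persons") {
  structure(
    list(deaths = deaths, population = population, income = income,
         age_floor = age_floor, ages = ages, policy = policy,
         comparison_years = comparison_years,
         min_trend_years = min_trend_years, alpha = alpha,
         population_units = population_units),
    class = "run_config"
  )
}

.check_inputs <- function(paths) {
  for (p in paths) {
    if (!is.null(p) && !file.exists(p)) {
      rlang::abort(paste0("input file not found: ", p),
                   class = "fallcoding_missing_input")
    }
  }
}

.write_manifest <- function(outdir, step, config, n_warnings = 0) {
  manifest <- list(
    step = step,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = Filter(Negate(is.null),
                    config[c("deaths", "population", "income")]),
    parameters = list(
      age_floor = config$age_floor, ages = config$ages,
      window_breaks = config$policy$breaks,
      window_lengths = config$policy$lengths,
      comparison_years = config$comparison_years,
      min_trend_years = config$min_trend_years,
      alpha = config$alpha
    ),
    n_warnings = n_warnings
  )
  yaml::write_yaml(manifest, file.path(outdir, paste0(step, "_manifest.yaml")))
}

#' Run the availability summary
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param member_states optional country list for the unavailable bin.
#' @return paths of the written CSVs, invisibly.
#' @export
run_availability <- function(config, outdir, member_states = NULL) {
  .check_inputs(config$deaths)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deaths <- read_death_file(config$deaths, config$age_floor)
  av <- availability(deaths, member_states)
  readr::write_csv(av$bins, file.path(outdir, "availability_bins.csv"),
                   progress = FALSE)
  readr::write_csv(av$revisions, file.path(outdir, "icd_revisions.csv"),
                   progress = FALSE)
  .write_manifest(outdir, "availability", config)
  invisible(file.path(outdir, c("availability_bins.csv", "icd_revisions.csv")))
}

#' Run the five quality indicators (and income comparison if possible)
#'
#' @inheritParams run_availability
#' @return path of the indicators CSV, invisibly.
#' @export
run_indicators <- function(config, outdir) {
  .check_inputs(c(config$deaths, config$income))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deaths <- read_death_file(config$deaths, config$age_floor)
  profiles <- quality_indicators(deaths, ages = config$ages)
  readr::write_csv(profiles, file.path(outdir, "quality_indicators.csv"),
                   progress = FALSE)
  if (!is.null(config$income)) {
    income <- read_income_lookup(config$income)
    rows <- list()
    for (k in 1:5) {
      cmp <- tryCatch(income_group_comparison(profiles, income, k),
                      fallcoding_insufficient_groups = function(e) NULL)
      if (is.null(cmp)) next
      rows[[k]] <- dplyr::mutate(cmp$summary, indicator = k,
                                 H = cmp$statistic, p_value = cmp$p_value)
    }
    if (length(rows) > 0) {
      readr::write_csv(dplyr::bind_rows(rows),
                       file.path(outdir, "income_comparison.csv"),
                       progress = FALSE)
    }
  }
  .write_manifest(outdir, "indicators", config)
  invisible(file.path(outdir, "quality_indicators.csv"))
}

#' Run the garbage-code correction
#'
#' @inheritParams run_availability
#' @return path of the correction CSV, invisibly.
#' @export
run_correction <- function(config, outdir) {
  .check_inputs(config$deaths)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deaths <- read_death_file(config$deaths, config$age_floor)
  corrected <- correct_all(deaths, policy = config$policy)
  readr::write_csv(corrected, file.path(outdir, "corrected_falls.csv"),
                   progress = FALSE)
  .write_manifest(outdir, "correct", config,
                  n_warnings = sum(corrected$fallback))
  invisible(file.path(outdir, "corrected_falls.csv"))
}

#' Run direct standardisation and the impact classification
#'
#' @inheritParams run_availability
#' @return paths of the rates and classification CSVs, invisibly.
#' @export
run_rates <- function(config, outdir) {
  .check_inputs(c(config$deaths, config$population))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deaths <- read_death_file(config$deaths, config$age_floor)
  population <- read_population_file(config$population,
                                     units = config$population_units)
  corrected <- correct_all(deaths, policy = config$policy)
  series <- rate_series(corrected, population)
  readr::write_csv(series, file.path(outdir, "rates.csv"), progress = FALSE)
  readr::write_csv(impact_ratio(series),
                   file.path(outdir, "impact_classification.csv"),
                   progress = FALSE)
  .write_manifest(outdir, "rates", config)
  invisible(file.path(outdir, c("rates.csv", "impact_classification.csv")))
}

#' Run the trend-impact analysis
#'
#' @inheritParams run_availability
#' @return paths of the written CSVs, invisibly.
#' @export
run_trends <- function(config, outdir) {
  .check_inputs(c(config$deaths, config$population))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  deaths <- read_death_file(config$deaths, config$age_floor)
  population <- read_population_file(config$population,
                                     units = config$population_units)
  corrected <- correct_all(deaths, policy = config$policy)
  series <- rate_series(corrected, population)
  changes <- change_between_years(series, config$comparison_years)
  fits <- trend_table(series, config$min_trend_years, config$alpha)
  readr::write_csv(changes, file.path(outdir, "change_comparison.csv"),
                   progress = FALSE)
  readr::write_csv(fits, file.path(outdir, "trend_fits.csv"),
                   progress = FALSE)
  readr::write_csv(reversal_summary(fits),
                   file.path(outdir, "reversal_summary.csv"),
                   progress = FALSE)
  .write_manifest(outdir, "trends", config)
  invisible(file.path(outdir, c("change_comparison.csv", "trend_fits.csv",
                                "reversal_summary.csv")))
}

#' Generate a scenario's flat files
#'
#' @param scenario a [scenario_config()], a name from
#'   [scenario_library()], or a YAML path.
#' @param outdir output directory.
#' @param seed optional seed override.
#' @return named list of file paths (deaths, population, truth).
#' @export
run_simulate <- function(scenario, outdir, seed = NULL) {
  if (is.character(scenario)) {
    scenario <- if (file.exists(scenario)) {
      scenario_from_yaml(scenario)
    } else if (scenario %in% names(scenario_library())) {
      scenario_library()[[scenario]]
    } else {
      rlang::abort(paste0("unknown scenario: ", scenario),
                   class = "fallcoding_missing_input")
    }
  }
  sc <- generate_scenario(scenario, seed = seed)
  write_scenario(sc, outdir)
}

#' Run the full report: indicators, correction, rates, trends
#'
#' @inheritParams run_availability
#' @return character vector of all written files, invisibly.
#' @export
run_report <- function(config, outdir) {
  out <- c(
    run_indicators(config, outdir),
    run_correction(config, outdir),
    run_rates(config, outdir),
    run_trends(config, outdir)
  )
  .write_manifest(outdir, "report", config)
  invisible(out)
}
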