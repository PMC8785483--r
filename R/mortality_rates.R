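#' Direct age standardisation and impact classification
#'
#' Age-adjusted 65+ fall mortality is computed by the direct method: the
#' age-specific rates are weighted by the WHO World Standard Population
#' age structure, renormalised over ages 65 and older. The ratio of
#' corrected to uncorrected age-adjusted rates quantifies how much
#' problematic coding distorted a country's fall mortality, and countries
#' are placed in six quality tiers by their maximum ratio across years.
#'
#' @name mortality_rates
NULL

#' WHO World Standard Population weights for ages 65+
#'
#' The published world standard age distribution (5-year groups, 0-4
#' through 100+) ships with the package as
#' `extdata/who_world_standard.csv`. For elderly standardisation its 65+
#' share is renormalised to sum to one over the five analysis groups,
#' with 85-89/90-94/95-99/100+ merged into 85+.
#'
#' @param file optional path to an alternative standard-population CSV
#'   with columns `age_group, weight_percent`.
#' @return named numeric vector of five weights over [age_groups()],
#'   summing to 1.
#' @examples
#' who_standard_weights()
#' @export
who_standard_weights <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "who_world_standard.csv",
                        package = "fallcoding", mustWork = TRUE)
  }
  std <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  elderly <- std[std$age_group %in% c("65-69", "70-74", "75-79", "80-84",
                                      "85-89", "90-94", "95-99", "95+",
                                      "100+", "85+"), , drop = FALSE]
  elderly$age_group <- ifelse(
    elderly$age_group %in% c("85-89", "90-94", "95-99", "95+", "100+", "85+"),
    "85+", elderly$age_group
  )
  w <- tapply(elderly$weight_percent, elderly$age_group, sum)
  w <- w[age_groups()]
  if (any(is.na(w)) || any(w <= 0)) {
    rlang::abort("standard population must cover all five 65+ age groups",
                 class = "fallcoding_validation_error")
  }
  w / sum(w)
}

#' Direct age-standardised mortality rate per 100,000
#'
#' @param deaths numeric vector of deaths by age group, named by or
#'   ordered as [age_groups()]; fractional counts (post-correction) are
#'   fine.
#' @param population tibble with `age_group, population` covering all five
#'   groups (e.g. one country-year of [read_population_file()] output).
#' @param standard named weight vector from [who_standard_weights()].
#' @return the age-standardised rate per 100,000 person-years:
#'   `1e5 * sum(w_a * d_a / p_a)`.
#' @export
age_adjusted_rate <- function(deaths, population,
                              standard = who_standard_weights()) {
  grp <- age_groups()
  if (!is.null(names(deaths))) deaths <- deaths[grp]
  if (length(deaths) != length(grp) || any(is.na(deaths))) {
    rlang::abort("deaths must cover all five 65+ age groups",
                 class = "fallcoding_validation_error")
  }
  p <- population$population[match(grp, population$age_group)]
  if (any(is.na(p))) {
    rlang::abort(
      paste0("missing population stratum: ",
             paste(grp[is.na(p)], collapse = ", ")),
      class = "fallcoding_missing_population"
    )
  }
  if (any(p <= 0)) {
    rlang::abort("population must be positive in every stratum",
                 class = "fallcoding_validation_error")
  }
  1e5 * sum(standard[grp] * deaths / p)
}

#' Uncorrected and corrected rate series for each country
#'
#' @param corrected tidy correction output from [correct_all()].
#' @param population population tibble from [read_population_file()].
#' @param standard weights from [who_standard_weights()].
#' @return tibble `country, year, rate_uncorrected, rate_corrected,
#'   ratio`; country-years lacking population data are dropped with a
#'   message naming the pairs.
#' @export
rate_series <- function(corrected, population,
                        standard = who_standard_weights()) {
  keys <- dplyr::distinct(corrected[c("country", "year")])
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(keys))) {
    ct <- keys$country[i]
    y <- keys$year[i]
    sub <- corrected[corrected$country == ct & corrected$year == y, ,
                     drop = FALSE]
    pop <- population[population$country == ct & population$year == y, ,
                      drop = FALSE]
    if (nrow(pop) < length(age_groups())) {
      skipped <- c(skipped, paste0(ct, "/", y))
      next
    }
    d_obs <- stats::setNames(sub$observed_falls, sub$age_group)
    d_cor <- stats::setNames(sub$corrected_falls, sub$age_group)
    r <- age_adjusted_rate(d_obs, pop, standard)
    r_star <- age_adjusted_rate(d_cor, pop, standard)
    rows[[i]] <- tibble::tibble(
      country = ct, year = y,
      rate_uncorrected = r, rate_corrected = r_star,
      ratio = ifelse(r > 0, r_star / r, NA_real_)
    )
  }
  if (length(skipped) > 0) {
    rlang::inform(paste0("no population data, skipped: ",
                         paste(skipped, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

#' Six-tier quality classification from the maximum impact ratio
#'
#' @param max_ratio numeric vector of maximum corrected/uncorrected rate
#'   ratios (unrounded values; display rounding is separate).
#' @return factor over `highest, higher, high, low, lower, lowest` with
#'   bins \[1.0,1.1), \[1.1,1.2), \[1.2,1.3), \[1.3,1.4), \[1.4,1.5),
#'   \[1.5,Inf).
#' @examples
#' classify_tier(c(1.05, 1.34, 1.50))
#' @export
classify_tier <- function(max_ratio) {
  tiers <- c("highest", "higher", "high", "low", "lower", "lowest")
  idx <- findInterval(pmax(max_ratio, 1), c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5))
  factor(tiers[idx], levels = tiers)
}

#' Per-country impact of problematic coding on rate levels
#'
#' Summarises each country's yearly corrected/uncorrected ratios and
#' assigns the six-tier quality class by the (unrounded) maximum ratio.
#' Years with an uncorrected rate of zero but a positive corrected rate
#' carry no defined ratio and are excluded, counted in `n_excluded`.
#'
#' @param series output of [rate_series()].
#' @return tibble `country, n_years, median_ratio, min_ratio, max_ratio,
#'   tier, n_excluded`.
#' @export
impact_ratio <- function(series) {
  dat <- dplyr::group_by(series, .data$country)
  out <- dplyr::summarise(
    dat,
    n_years = sum(!is.na(.data$ratio)),
    median_ratio = stats::median(.data$ratio, na.rm = TRUE),
    min_ratio = suppressWarnings(min(.data$ratio, na.rm = TRUE)),
    max_ratio = suppressWarnings(max(.data$ratio, na.rm = TRUE)),
    n_excluded = sum(is.na(.data$ratio)),
    .groups = "drop"
  )
  out <- out[out$n_years > 0, , drop = FALSE]
  out$tier <- classify_tier(out$max_ratio)
  out[c("country", "n_years", "median_ratio", "min_ratio", "max_ratio",
        "tier", "n_excluded")]
}
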