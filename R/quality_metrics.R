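#' Coding-quality indicators for fall mortality
#'
#' Five proportions measure how much of the cause-of-death signal is lost
#' to problematic ICD-10 codes, per country and year:
#' \enumerate{
#'   \item unspecified deaths (R96/R98/R99) / total deaths
#'   \item injury deaths with undetermined intent / injury deaths
#'   \item unspecified unintentional injuries (X59) / unintentional injuries
#'   \item falls with unspecified mechanism (W19) / fall deaths
#'   \item falls with unknown occurrence place (4th digit 9) / fall deaths
#' }
#' Internally all proportions live in \[0,1\]; multiply by 100 only for
#' display. A proportion is `NA` when its denominator is zero.
#'
#' @name quality_metrics
NULL

#' Tally the category counts for one country-year
#'
#' Sums deaths over the rows of one country-year into the numerator and
#' denominator universes of the five quality proportions.
#'
#' @param deaths internal death table rows (see [read_death_file()]) all
#'   sharing one (country, year); an error is raised otherwise.
#' @param ages `"65plus"` (default) restricts counts to ages 65 and older
#'   (deaths of unknown age excluded); `"all"` adds the under-65 bands.
#' @return a one-row tibble: `country, year, n_total, n_unspecified,
#'   n_injury, n_undetermined, n_unintentional, n_x59, n_fall, n_w19,
#'   n_fall_place_unknown`.
#' @examples
#' rows <- tibble::tibble(
#'   country = "AAA", year = 2010L, list = "104",
#'   cause = c("W19", "W009", "X59", "R99", "C509"),
#'   d_under65 = 0, d65_69 = c(10, 5, 3, 2, 80),
#'   d70_74 = 0, d75_79 = 0, d80_84 = 0, d85p = 0, d_unknown_age = 0,
#'   total65 = c(10, 5, 3, 2, 80)
#' )
#' tally_categories(rows)
#' @export
tally_categories <- function(deaths, ages = c("65plus", "all")) {
  ages <- match.arg(ages)
  if (nrow(deaths) == 0) {
    return(tibble::tibble(
      country = NA_character_, year = NA_integer_,
      n_total = 0, n_unspecified = 0, n_injury = 0, n_undetermined = 0,
      n_unintentional = 0, n_x59 = 0, n_fall = 0, n_w19 = 0,
      n_fall_place_unknown = 0
    ))
  }
  if (dplyr::n_distinct(deaths$country) > 1 ||
      dplyr::n_distinct(deaths$year) > 1) {
    rlang::abort("tally_categories() expects rows from a single country-year",
                 class = "fallcoding_contract_violation")
  }
  w <- deaths$total65
  if (ages == "all") w <- w + deaths$d_under65
  cls <- classify_cause(deaths$cause)
  place <- place_of_occurrence(deaths$cause)
  tibble::tibble(
    country = deaths$country[1],
    year = deaths$year[1],
    n_total = sum(w),
    n_unspecified = sum(w[cls$unspecified_death]),
    n_injury = sum(w[cls$injury]),
    n_undetermined = sum(w[cls$undetermined_intent]),
    n_unintentional = sum(w[cls$unintentional]),
    n_x59 = sum(w[cls$unspecified_unintentional]),
    n_fall = sum(w[cls$fall]),
    n_w19 = sum(w[cls$fall_unspecified_mechanism]),
    n_fall_place_unknown = sum(w[place == "unknown"])
  )
}

#' The five quality proportions from category counts
#'
#' @param counts tibble of category counts as returned by
#'   [tally_categories()]; may hold many country-years.
#' @return `counts` with columns `proportion_one..proportion_five`
#'   appended, each in \[0,1\] or `NA` where the denominator is zero.
#' @export
quality_profile <- function(counts) {
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(
    counts,
    proportion_one = ratio(.data$n_unspecified, .data$n_total),
    proportion_two = ratio(.data$n_undetermined, .data$n_injury),
    proportion_three = ratio(.data$n_x59, .data$n_unintentional),
    proportion_four = ratio(.data$n_w19, .data$n_fall),
    proportion_five = ratio(.data$n_fall_place_unknown, .data$n_fall)
  )
}

#' Quality indicators for every country-year in a dataset
#'
#' Convenience wrapper: tallies and profiles each country-year of an
#' ICD-10 death table.
#'
#' @param deaths internal death table (any number of country-years);
#'   non-ICD-10 rows (by `list` tag) are excluded.
#' @inheritParams tally_categories
#' @return tibble with one row per country-year: counts plus the five
#'   proportions.
#' @export
quality_indicators <- function(deaths, ages = c("65plus", "all")) {
  ages <- match.arg(ages)
  deaths <- deaths[is_icd10_list(deaths$list), , drop = FALSE]
  groups <- dplyr::group_split(dplyr::group_by(deaths, .data$country, .data$year))
  tallies <- dplyr::bind_rows(lapply(groups, tally_categories, ages = ages))
  quality_profile(tallies)
}

#' Data-availability bins over a study period
#'
#' Counts, per country, the distinct years with any death record in the
#' period and bins them: 0 (unavailable), 1-5, 6-10, 11-15, 16-20, 21-25,
#' 26-30 years. Also reports the ICD revision used per country-year.
#'
#' @param deaths internal death table.
#' @param member_states optional character vector of country codes that
#'   should appear even when absent from the data (binned `"0"`).
#' @param period two-element integer vector, default `c(1990, 2019)`.
#' @return a list with `bins` (tibble `country, n_years, bin`) and
#'   `revisions` (tibble `country, year, revision`).
#' @export
availability <- function(deaths, member_states = NULL,
                         period = c(1990L, 2019L)) {
  deaths <- deaths[deaths$year >= period[1] & deaths$year <= period[2], ,
                   drop = FALSE]
  counts <- dplyr::summarise(
    dplyr::group_by(deaths, .data$country),
    n_years = dplyr::n_distinct(.data$year), .groups = "drop"
  )
  if (!is.null(member_states)) {
    absent <- setdiff(member_states, counts$country)
    counts <- dplyr::bind_rows(
      counts, tibble::tibble(country = absent, n_years = 0L)
    )
  }
  breaks <- c(-1, 0, 5, 10, 15, 20, 25, 30)
  labels <- c("0", "1-5", "6-10", "11-15", "16-20", "21-25", "26-30")
  counts$bin <- cut(counts$n_years, breaks = breaks, labels = labels)
  revisions <- dplyr::distinct(
    tibble::tibble(
      country = deaths$country,
      year = deaths$year,
      revision = icd_revision(deaths$list)
    )
  )
  list(bins = dplyr::arrange(counts, .data$country), revisions = revisions)
}

#' Compare a quality indicator across income groups
#'
#' Kruskal-Wallis rank sum test of one of the five proportions across the
#' four World Bank income classes, with country-years as the analysis
#' units. Per-group medians and quartiles use the linear-interpolation
#' quantile convention (type 7).
#'
#' @param profiles output of [quality_indicators()].
#' @param income income lookup tibble from [read_income_lookup()].
#' @param indicator integer 1..5 selecting the proportion.
#' @return a list: `statistic` (Kruskal-Wallis H), `df`, `p_value`, and
#'   `summary` (tibble `income_group, n, median, q25, q75`).
#' @export
income_group_comparison <- function(profiles, income, indicator = 1L) {
  stopifnot(indicator %in% 1:5)
  col <- paste0("proportion_",
                c("one", "two", "three", "four", "five")[indicator])
  dat <- dplyr::inner_join(profiles, income, by = "country")
  dat <- dat[!is.na(dat[[col]]), , drop = FALSE]
  dat$income_group <- droplevels(dat$income_group)
  if (dplyr::n_distinct(dat$income_group) < 2) {
    rlang::abort("need at least 2 non-empty income groups",
                 class = "fallcoding_insufficient_groups")
  }
  if (dplyr::n_distinct(dat[[col]]) == 1) {
    # no variation at all: H is 0 by definition (kruskal.test returns NaN)
    kw <- list(statistic = 0,
               parameter = dplyr::n_distinct(dat$income_group) - 1,
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(dat[[col]], dat$income_group)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(dat, .data$income_group),
    n = dplyr::n(),
    median = stats::median(.data[[col]]),
    q25 = stats::quantile(.data[[col]], 0.25, type = 7, names = FALSE),
    q75 = stats::quantile(.data[[col]], 0.75, type = 7, names = FALSE),
    .groups = "drop"
  )
  list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    summary = summary
  )
}
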