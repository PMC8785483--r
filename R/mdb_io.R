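#' Reading WHO Mortality Database style inputs
#'
#' The death flat file has one row per country/year/ICD-list/cause/sex with
#' 26 age-banded count columns `Deaths1..Deaths26`: band 1 is all ages,
#' bands 2..25 are ascending age bands in the full-detail age format
#' (`Frmat` 0: single years 0–4, then 5-year groups up to 95+), and band 26
#' is deaths of unspecified age. Only the full-detail format is supported;
#' rows in any other format are rejected with a diagnostic, mirroring the
#' restriction of the quality analysis to countries reporting 4-digit
#' ICD-10 detail.
#'
#' @name mdb_io
NULL

# Deaths2..Deaths18 cover ages 0-64; Deaths19..22 are 65-69..80-84;
# Deaths23..25 are 85-89/90-94/95+, merged into 85+; Deaths26 is unknown age.
.deaths_cols <- paste0("Deaths", 1:26)
.under65_cols <- paste0("Deaths", 2:18)
.supported_frmat <- 0L

#' Age-group labels used throughout the package
#'
#' The elderly population is analysed in five age groups; the terminal
#' 85-89/90-94/95+ detail of the source files is merged into 85+, the
#' lowest common resolution with the standard-population weights.
#'
#' @return character vector `c("65-69","70-74","75-79","80-84","85+")`.
#' @export
age_groups <- function() c("65-69", "70-74", "75-79", "80-84", "85+")

# internal column names for the five collapsed age groups
.age_cols <- c("d65_69", "d70_74", "d75_79", "d80_84", "d85p")

age_cols <- function() .age_cols

#' Read a WHO-MDB-style death flat file
#'
#' Reads, validates and normalises the CSV into the package's internal
#' death table: one row per (country, year, list, cause) with the sexes
#' summed, ages collapsed to the five elderly groups plus an under-65 and
#' an unknown-age column, and the all-ages total recomputed as the sum of
#' the retained bands (rows whose stored `Deaths1` disagrees with the band
#' sum are counted in the diagnostics).
#'
#' @param path CSV file with header columns `Country, Year, List, Cause,
#'   Sex, Frmat, Deaths1..Deaths26` (extra columns such as `Admin1`,
#'   `SubDiv`, `IM_Frmat` are ignored).
#' @param age_floor 0 or 65. With 65 (default) bands below age 65 are
#'   zeroed out; with 0 they are retained in the `d_under65` column.
#' @return a tibble with columns `country, year, list, cause, d_under65,
#'   d65_69, d70_74, d75_79, d80_84, d85p, d_unknown_age, total65`, and a
#'   `diagnostics` attribute (list: `n_frmat_rejected`, `n_cause_dropped`,
#'   `n_total_mismatch`, `unknown_age_deaths`).
#' @export
read_death_file <- function(path, age_floor = 65) {
  if (!age_floor %in% c(0, 65)) {
    rlang::abort("age_floor must be 0 or 65", class = "fallcoding_bad_arg")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("Country", "Year", "List", "Cause", "Sex", "Frmat", .deaths_cols)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("death file is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "fallcoding_format_error"
    )
  }
  raw[.deaths_cols] <- lapply(raw[.deaths_cols], function(x) {
    x <- suppressWarnings(as.numeric(x))
    x[is.na(x)] <- 0
    x
  })
  neg <- which(rowSums(as.matrix(raw[.deaths_cols]) < 0) > 0)
  if (length(neg) > 0) {
    rlang::abort(
      paste0("negative death count in row(s): ",
             paste(utils::head(neg, 10), collapse = ", ")),
      class = "fallcoding_validation_error"
    )
  }

  ok_frmat <- raw$Frmat %in% .supported_frmat
  n_frmat_rejected <- sum(!ok_frmat)
  if (n_frmat_rejected > 0) {
    bad <- unique(raw$Frmat[!ok_frmat])
    rlang::inform(paste0(
      n_frmat_rejected, " row(s) rejected: unsupported age format (Frmat ",
      paste(bad, collapse = ", "), "); only the full-detail format ",
      .supported_frmat, " is supported"
    ))
  }
  raw <- raw[ok_frmat, , drop = FALSE]

  raw$Cause <- toupper(trimws(as.character(raw$Cause)))
  ok_cause <- valid_cause(raw$Cause)
  n_cause_dropped <- sum(!ok_cause)
  if (n_cause_dropped > 0) {
    rlang::warn(paste0(
      n_cause_dropped, " row(s) dropped: unparseable cause code(s) ",
      paste(unique(utils::head(raw$Cause[!ok_cause], 10)), collapse = ", ")
    ))
  }
  raw <- raw[ok_cause, , drop = FALSE]

  band_sum <- rowSums(as.matrix(raw[paste0("Deaths", 2:26)]))
  n_total_mismatch <- sum(abs(raw$Deaths1 - band_sum) > 0)

  # combine sexes: the analysis is for both sexes together
  dat <- dplyr::summarise(
    dplyr::group_by(
      raw,
      country = as.character(.data$Country),
      year = as.integer(.data$Year),
      list = as.character(.data$List),
      cause = .data$Cause
    ),
    dplyr::across(dplyr::all_of(paste0("Deaths", 2:26)), sum),
    .groups = "drop"
  )

  if (age_floor == 65) {
    dat[.under65_cols] <- 0
  }
  out <- tibble::tibble(
    country = dat$country,
    year = dat$year,
    list = dat$list,
    cause = dat$cause,
    d_under65 = rowSums(as.matrix(dat[.under65_cols])),
    d65_69 = dat$Deaths19,
    d70_74 = dat$Deaths20,
    d75_79 = dat$Deaths21,
    d80_84 = dat$Deaths22,
    d85p = dat$Deaths23 + dat$Deaths24 + dat$Deaths25,
    d_unknown_age = dat$Deaths26
  )
  out$total65 <- rowSums(as.matrix(out[.age_cols]))
  attr(out, "diagnostics") <- list(
    n_frmat_rejected = n_frmat_rejected,
    n_cause_dropped = n_cause_dropped,
    n_total_mismatch = n_total_mismatch,
    unknown_age_deaths = sum(out$d_unknown_age)
  )
  out
}

#' Write a death table back to the WHO-MDB flat-file dialect
#'
#' The inverse of [read_death_file()] for tables in the internal layout
#' (optionally carrying a `sex` column, which is written out as given;
#' otherwise a single combined row per cause is written with `Sex = 9`).
#' The five elderly age-group columns map to `Deaths19..Deaths23`
#' (85+ written into the 85-89 band, 90-94/95+ zero), under-65 deaths to
#' `Deaths18` (60-64 band) and unknown age to `Deaths26`.
#'
#' @param deaths tibble with columns `country, year, list, cause`, the five
#'   age-group count columns, and optionally `sex`, `d_under65`,
#'   `d_unknown_age`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_death_file <- function(deaths, path) {
  n <- nrow(deaths)
  zero <- function() rep(0, n)
  col <- function(nm) if (nm %in% names(deaths)) deaths[[nm]] else zero()
  out <- tibble::tibble(
    Country = deaths$country,
    Admin1 = "",
    SubDiv = "",
    Year = deaths$year,
    List = if ("list" %in% names(deaths)) deaths$list else "104",
    Cause = deaths$cause,
    Sex = if ("sex" %in% names(deaths)) deaths$sex else 9L,
    Frmat = 0L,
    IM_Frmat = 0L
  )
  for (k in 1:26) out[[paste0("Deaths", k)]] <- zero()
  out$Deaths18 <- col("d_under65")
  out$Deaths19 <- col("d65_69")
  out$Deaths20 <- col("d70_74")
  out$Deaths21 <- col("d75_79")
  out$Deaths22 <- col("d80_84")
  out$Deaths23 <- col("d85p")
  out$Deaths26 <- col("d_unknown_age")
  out$Deaths1 <- rowSums(as.matrix(out[paste0("Deaths", 2:26)]))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a simplified UN-WPP-style population table
#'
#' @param path CSV with columns `location, year, age_group, population`.
#'   Age groups at 5-year resolution; `85-89`, `90-94` and `95+` are
#'   collapsed into `85+` (an `85+` row is also accepted as is).
#' @param units `"persons"` (default) or `"thousands"`; with
#'   `"thousands"` counts are multiplied by 1000.
#' @return a tibble `country, year, age_group, population` with
#'   `age_group` over [age_groups()].
#' @export
read_population_file <- function(path, units = c("persons", "thousands")) {
  units <- match.arg(units)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("location", "year", "age_group", "population")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("population file is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "fallcoding_format_error"
    )
  }
  if (any(!is.finite(raw$population) | raw$population <= 0)) {
    rlang::abort("population counts must be positive",
                 class = "fallcoding_validation_error")
  }
  scale <- if (units == "thousands") 1000 else 1
  raw$age_group <- ifelse(raw$age_group %in% c("85-89", "90-94", "95+", "85+"),
                          "85+", raw$age_group)
  keep <- raw$age_group %in% age_groups()
  out <- dplyr::summarise(
    dplyr::group_by(
      raw[keep, , drop = FALSE],
      country = as.character(.data$location),
      year = as.integer(.data$year),
      age_group = .data$age_group
    ),
    population = sum(.data$population) * scale,
    .groups = "drop"
  )
  dup <- duplicated(out[c("country", "year", "age_group")])
  if (any(dup)) {
    rlang::abort("duplicate (country, year, age_group) in population file",
                 class = "fallcoding_validation_error")
  }
  out
}

#' Write a population table in the simplified UN-WPP dialect
#'
#' @param population tibble `country, year, age_group, population`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_file <- function(population, path) {
  out <- tibble::tibble(
    location = population$country,
    year = population$year,
    age_group = population$age_group,
    population = population$population
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a country-to-income-group lookup
#'
#' World Bank Analytical Classifications 2019 groups: `LICT` (low income),
#' `LMICT` (lower middle), `UMICT` (upper middle), `HICT` (high income
#' countries/territories).
#'
#' @param path 2-column CSV `country_code, income_group`.
#' @return a tibble `country, income_group` with `income_group` a factor
#'   over the four classes.
#' @export
read_income_lookup <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("country_code", "income_group")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("income lookup is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "fallcoding_format_error"
    )
  }
  bad <- !raw$income_group %in% income_groups()
  if (any(bad)) {
    rlang::abort(
      paste0("unknown income group label(s): ",
             paste(unique(raw$income_group[bad]), collapse = ", ")),
      class = "fallcoding_validation_error"
    )
  }
  conflicts <- dplyr::summarise(
    dplyr::group_by(raw, .data$country_code),
    n = dplyr::n_distinct(.data$income_group), .groups = "drop"
  )
  if (any(conflicts$n > 1)) {
    rlang::abort(
      paste0("conflicting income class for country: ",
             paste(conflicts$country_code[conflicts$n > 1], collapse = ", ")),
      class = "fallcoding_validation_error"
    )
  }
  out <- dplyr::distinct(
    tibble::tibble(
      country = as.character(raw$country_code),
      income_group = factor(raw$income_group, levels = income_groups())
    )
  )
  out
}

#' @rdname read_income_lookup
#' @return `income_groups()` returns the four class labels, poorest first.
#' @export
income_groups <- function() c("LICT", "LMICT", "UMICT", "HICT")
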