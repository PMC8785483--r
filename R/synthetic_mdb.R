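#' Synthetic WHO-MDB-style data with known ground truth
#'
#' The generator draws true deaths per country, year, 65+ age group and
#' cause group from binomial models (population times rate), then injects
#' the five problematic-code types by relabelling: each death is
#' relabelled to R99 with probability q1; surviving injury deaths to Y34
#' with probability q2; surviving unintentional-injury deaths to X59 with
#' probability q3. Because garbage arises by relabelling true causes, the
#' proportionate method's assumption — problematic codes follow the same
#' cause distribution as specific codes — holds by construction, so
#' parameter recovery tests the implementation, not the assumption.
#' Surviving falls are coded W19 with probability q4 (else a random
#' mechanism W00–W18) and get occurrence-place digit 9 with probability
#' q5 (else a random digit 0–8). Total mortality is preserved exactly:
#' relabelled plus retained equals generated per stratum.
#'
#' @name synthetic_mdb
NULL

.noninjury_causes <- c("C509", "I219", "J189", "E149")
.other_injury_causes <- c("X709", "Y049")
.nonfall_unintentional_causes <- c("V892", "W742", "X099")

#' Build a synthetic-data scenario configuration
#'
#' Injection rates `q1..q3` may be a single value, a length-2 vector
#' (linear start-to-end over the years, modelling changing coding
#' practice), a per-year vector, or a named list keyed by country of any
#' of those.
#'
#' @param countries tibble `country, income_group`.
#' @param years integer years within 1990–2019.
#' @param population named numeric vector of persons per age group
#'   ([age_groups()]).
#' @param fall_rate named per-age true fall death rates (per person-year).
#' @param fall_trend relative change of the fall rate per year (0 = flat).
#' @param nonfall_unintentional_rate,other_injury_rate,noninjury_rate
#'   per-person-year death rates of the other cause groups (uniform over
#'   ages).
#' @param q1,q2,q3 relabelling probabilities to R99 / Y34 / X59.
#' @param q4 probability a surviving fall is coded W19.
#' @param q5 probability a fall code gets occurrence-place digit 9.
#' @param seed integer; fixes all randomness of [generate_scenario()].
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(countries,
                            years,
                            population = c(`65-69` = 30000, `70-74` = 25000,
                                           `75-79` = 20000, `80-84` = 15000,
                                           `85+` = 10000),
                            fall_rate = c(`65-69` = 0.001, `70-74` = 0.002,
                                          `75-79` = 0.004, `80-84` = 0.008,
                                          `85+` = 0.020),
                            fall_trend = 0,
                            nonfall_unintentional_rate = 0.001,
                            other_injury_rate = 0.0005,
                            noninjury_rate = 0.05,
                            q1 = 0, q2 = 0, q3 = 0, q4 = 0.3, q5 = 0.3,
                            seed = 1L) {
  stopifnot(
    all(c("country", "income_group") %in% names(countries)),
    all(years >= 1990 & years <= 2019),
    all(age_groups() %in% names(population)), all(population > 0),
    all(age_groups() %in% names(fall_rate)), all(fall_rate >= 0),
    q4 >= 0, q4 <= 1, q5 >= 0, q5 <= 1
  )
  structure(
    list(
      countries = countries, years = sort(unique(as.integer(years))),
      population = population[age_groups()],
      fall_rate = fall_rate[age_groups()], fall_trend = fall_trend,
      nonfall_unintentional_rate = nonfall_unintentional_rate,
      other_injury_rate = other_injury_rate,
      noninjury_rate = noninjury_rate,
      q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

# resolve an injection-rate spec into one value per year (and country)
.resolve_q <- function(q, country, years, name) {
  if (is.list(q)) {
    if (!country %in% names(q)) {
      rlang::abort(paste0(name, " has no entry for country ", country),
                   class = "fallcoding_generation_error")
    }
    q <- q[[country]]
  }
  n <- length(years)
  out <- if (length(q) == 1) {
    rep(q, n)
  } else if (length(q) == 2) {
    seq(q[1], q[2], length.out = n)
  } else if (length(q) == n) {
    q
  } else {
    rlang::abort(paste0(name, " must have length 1, 2 or length(years)"),
                 class = "fallcoding_generation_error")
  }
  if (any(out < 0 | out > 1)) {
    rlang::abort(paste0(name, " resolves outside [0, 1]"),
                 class = "fallcoding_generation_error")
  }
  out
}

# sequential relabelling of one cause-group count
.relabel <- function(n, q1, q2 = 0, q3 = 0) {
  r1 <- stats::rbinom(1, n, q1)
  rem <- n - r1
  r2 <- stats::rbinom(1, rem, q2)
  rem <- rem - r2
  r3 <- stats::rbinom(1, rem, q3)
  c(r99 = r1, y34 = r2, x59 = r3, keep = rem - r3)
}

# distribute surviving falls over W00-W19 x place digits
.fall_codes <- function(n, q4, q5) {
  if (n == 0) return(integer(0))
  w19 <- stats::rbinom(1, n, q4)
  mech <- drop(stats::rmultinom(1, n - w19, rep(1, 19)))
  counts <- c(mech, w19) # W00..W18, W19
  out <- integer(0)
  for (k in 0:19) {
    nk <- counts[k + 1]
    if (nk == 0) next
    unk <- stats::rbinom(1, nk, q5)
    digits <- drop(stats::rmultinom(1, nk - unk, rep(1, 9))) # digits 0-8
    codes <- c(stats::setNames(unk, sprintf("W%02d9", k)),
               stats::setNames(digits, sprintf("W%02d%d", k, 0:8)))
    out <- c(out, codes[codes > 0])
  }
  out
}

#' Generate a synthetic scenario
#'
#' @param config a [scenario_config()].
#' @param seed optional override of `config$seed`.
#' @return a list of class `scenario_data`: `deaths` (internal death
#'   table, as from [read_death_file()]), `population` (tibble
#'   `country, year, age_group, population`), `truth` (list: `strata`
#'   with true fall deaths per country-year-age, `rates` with the true
#'   age-adjusted rate per country-year, `slopes` with the true OLS trend
#'   per country), and `config`.
#' @export
generate_scenario <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  grp <- age_groups()
  years <- config$years
  y0 <- years[1]
  death_rows <- list()
  pop_rows <- list()
  truth_rows <- list()

  for (ci in seq_len(nrow(config$countries))) {
    ct <- config$countries$country[ci]
    q1y <- .resolve_q(config$q1, ct, years, "q1")
    q2y <- .resolve_q(config$q2, ct, years, "q2")
    q3y <- .resolve_q(config$q3, ct, years, "q3")
    for (yi in seq_along(years)) {
      y <- years[yi]
      fall_rate_y <- config$fall_rate * (1 + config$fall_trend * (y - y0))
      if (any(fall_rate_y < 0) || any(fall_rate_y > 1)) {
        rlang::abort(
          paste0("fall_trend drives the fall rate outside [0, 1] in ", y),
          class = "fallcoding_generation_error"
        )
      }
      counts <- new.env(parent = emptyenv())
      add <- function(cause, a, n) {
        if (n == 0) return(invisible())
        cur <- if (!is.null(counts[[cause]])) counts[[cause]] else numeric(5)
        cur[a] <- cur[a] + n
        counts[[cause]] <- cur
      }
      for (a in seq_along(grp)) {
        pop <- config$population[a]
        falls <- stats::rbinom(1, pop, fall_rate_y[a])
        nfu <- stats::rbinom(1, pop, config$nonfall_unintentional_rate)
        oi <- stats::rbinom(1, pop, config$other_injury_rate)
        ni <- stats::rbinom(1, pop, config$noninjury_rate)

        rf <- .relabel(falls, q1y[yi], q2y[yi], q3y[yi])
        ru <- .relabel(nfu, q1y[yi], q2y[yi], q3y[yi])
        ro <- .relabel(oi, q1y[yi], q2y[yi], 0)
        rn <- .relabel(ni, q1y[yi], 0, 0)

        add("R99", a, rf["r99"] + ru["r99"] + ro["r99"] + rn["r99"])
        add("Y34", a, rf["y34"] + ru["y34"] + ro["y34"])
        add("X59", a, rf["x59"] + ru["x59"])

        fc <- .fall_codes(rf[["keep"]], config$q4, config$q5)
        for (code in names(fc)) add(code, a, fc[[code]])
        if (ru[["keep"]] > 0) {
          split <- drop(stats::rmultinom(1, ru[["keep"]],
                                         rep(1, length(.nonfall_unintentional_causes))))
          for (j in seq_along(split)) add(.nonfall_unintentional_causes[j], a, split[j])
        }
        if (ro[["keep"]] > 0) {
          split <- drop(stats::rmultinom(1, ro[["keep"]],
                                         rep(1, length(.other_injury_causes))))
          for (j in seq_along(split)) add(.other_injury_causes[j], a, split[j])
        }
        if (rn[["keep"]] > 0) {
          split <- drop(stats::rmultinom(1, rn[["keep"]],
                                         rep(1, length(.noninjury_causes))))
          for (j in seq_along(split)) add(.noninjury_causes[j], a, split[j])
        }

        pop_rows[[length(pop_rows) + 1]] <- tibble::tibble(
          country = ct, year = y, age_group = grp[a],
          population = unname(pop)
        )
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          country = ct, year = y, age_group = grp[a],
          true_falls = unname(falls)
        )
      }
      causes <- sort(ls(counts))
      if (length(causes) > 0) {
        mat <- t(vapply(causes, function(cz) counts[[cz]], numeric(5)))
        dimnames(mat) <- NULL
        death_rows[[length(death_rows) + 1]] <- tibble::tibble(
          country = ct, year = y, list = "104", cause = causes,
          d_under65 = 0,
          d65_69 = mat[, 1], d70_74 = mat[, 2], d75_79 = mat[, 3],
          d80_84 = mat[, 4], d85p = mat[, 5],
          d_unknown_age = 0,
          total65 = rowSums(mat)
        )
      }
    }
  }

  deaths <- dplyr::bind_rows(death_rows)
  population <- dplyr::bind_rows(pop_rows)
  strata <- dplyr::bind_rows(truth_rows)

  std <- who_standard_weights()
  rates <- dplyr::bind_rows(lapply(
    split(strata, paste(strata$country, strata$year)),
    function(sl) tibble::tibble(
      country = sl$country[1], year = sl$year[1],
      true_rate = age_adjusted_rate(
        stats::setNames(sl$true_falls, sl$age_group),
        population[population$country == sl$country[1] &
                     population$year == sl$year[1], ],
        std
      )
    )
  ))
  slopes <- dplyr::bind_rows(lapply(split(rates, rates$country), function(rl) {
    f <- if (nrow(rl) >= 3) fit_trend(rl$year, rl$true_rate, min_years = 3L) else NULL
    tibble::tibble(country = rl$country[1],
                   true_slope = if (is.null(f)) NA_real_ else f$b)
  }))

  structure(
    list(deaths = deaths, population = population,
         truth = list(strata = strata, rates = rates, slopes = slopes),
         config = config),
    class = "scenario_data"
  )
}

#' Write a generated scenario to flat files
#'
#' Deaths are written in the WHO-MDB dialect with a deterministic
#' male/female split (so write-then-read round-trips exactly), and the
#' population in the simplified UN-WPP dialect with the 85+ group split
#' into 85-89/90-94/95+ rows to exercise the reader's collapsing.
#'
#' @param scenario a `scenario_data` object from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return named list of file paths: `deaths`, `population`, `truth`.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- scenario$deaths
  half <- function(x) floor(x / 2)
  males <- dplyr::mutate(
    d, sex = 1L,
    dplyr::across(dplyr::all_of(c(.age_cols, "d_under65", "d_unknown_age")), half)
  )
  females <- d
  for (colnm in c(.age_cols, "d_under65", "d_unknown_age")) {
    females[[colnm]] <- d[[colnm]] - males[[colnm]]
  }
  females$sex <- 2L
  both <- dplyr::bind_rows(males, females)
  both$total65 <- rowSums(as.matrix(both[.age_cols]))
  deaths_path <- file.path(dir, "deaths.csv")
  write_death_file(both, deaths_path)

  pop <- scenario$population
  open_grp <- pop[pop$age_group == "85+", , drop = FALSE]
  closed <- pop[pop$age_group != "85+", , drop = FALSE]
  a <- floor(open_grp$population * 0.6)
  b <- floor(open_grp$population * 0.3)
  split85 <- dplyr::bind_rows(
    dplyr::mutate(open_grp, age_group = "85-89", population = a),
    dplyr::mutate(open_grp, age_group = "90-94", population = b),
    dplyr::mutate(open_grp, age_group = "95+",
                  population = open_grp$population - a - b)
  )
  pop_path <- file.path(dir, "population.csv")
  write_population_file(dplyr::bind_rows(closed, split85), pop_path)

  truth_path <- file.path(dir, "ground_truth.csv")
  readr::write_csv(scenario$truth$strata, truth_path, progress = FALSE)
  list(deaths = deaths_path, population = pop_path, truth = truth_path)
}

#' Library of named study scenarios
#'
#' \describe{
#'   \item{clean}{no garbage codes; the correction must be an identity.}
#'   \item{tiered}{four countries with stage-1 injection rates 20, 40, 60
#'     and 75%, one per adaptive-window regime (1/3/5/7 years), one per
#'     income class; used for parameter recovery.}
#'   \item{indicators}{one large country with all five injection rates
#'     set; used for indicator recovery against binomial error.}
#'   \item{improving_coding}{unspecified-death coding improves linearly
#'     (q1 50% to 10%) over 2000–2015 while the true fall rate is flat,
#'     inducing a spurious upward uncorrected trend.}
#'   \item{sparse}{tiny populations and few years, exercising
#'     zero-denominator fallbacks and truncated windows.}
#' }
#'
#' @return named list of [scenario_config()] objects.
#' @export
scenario_library <- function() {
  big_fall <- c(`65-69` = 0.001, `70-74` = 0.002, `75-79` = 0.004,
                `80-84` = 0.008, `85+` = 0.020)
  list(
    clean = scenario_config(
      countries = tibble::tibble(country = c("CLNA", "CLNB"),
                                 income_group = c("HICT", "UMICT")),
      years = 2006:2012, fall_rate = big_fall,
      q1 = 0, q2 = 0, q3 = 0, q4 = 0.3, q5 = 0.3, seed = 101L
    ),
    tiered = scenario_config(
      countries = tibble::tibble(
        country = c("TIER20", "TIER40", "TIER60", "TIER75"),
        income_group = c("HICT", "UMICT", "LMICT", "LICT")
      ),
      years = 2004:2012, fall_rate = big_fall,
      q1 = list(TIER20 = 0.20, TIER40 = 0.40, TIER60 = 0.60,
                TIER75 = 0.75),
      q2 = 0, q3 = 0, q4 = 0.4, q5 = 0.5, seed = 202L
    ),
    indicators = scenario_config(
      countries = tibble::tibble(country = "INDIC", income_group = "HICT"),
      years = 2008:2010,
      population = c(`65-69` = 60000, `70-74` = 50000, `75-79` = 40000,
                     `80-84` = 30000, `85+` = 20000),
      fall_rate = big_fall,
      q1 = 0.10, q2 = 0.15, q3 = 0.20, q4 = 0.50, q5 = 0.60, seed = 303L
    ),
    improving_coding = scenario_config(
      countries = tibble::tibble(country = "IMPRV", income_group = "UMICT"),
      years = 2000:2015, fall_rate = big_fall, fall_trend = 0,
      q1 = c(0.50, 0.10), q2 = 0, q3 = 0, q4 = 0.4, q5 = 0.4, seed = 404L
    ),
    sparse = scenario_config(
      countries = tibble::tibble(country = "SPRS", income_group = "LMICT"),
      years = 2008:2010,
      population = c(`65-69` = 300, `70-74` = 250, `75-79` = 200,
                     `80-84` = 150, `85+` = 100),
      fall_rate = big_fall,
      q1 = 0.40, q2 = 0.10, q3 = 0.90, q4 = 0.4, q5 = 0.4, seed = 505L
    )
  )
}

#' Read a scenario configuration from YAML
#'
#' The YAML mirrors the arguments of [scenario_config()]; named maps
#' become named vectors (`population`, `fall_rate`) or per-country lists
#' (`q1..q3`), and `countries` is a list of `{country, income_group}`
#' records.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  to_vec <- function(x) if (is.list(x)) unlist(x) else x
  countries <- dplyr::bind_rows(lapply(y$countries, tibble::as_tibble))
  args <- list(
    countries = countries,
    years = y$years[1]:y$years[length(y$years)]
  )
  for (nm in c("population", "fall_rate")) {
    if (!is.null(y[[nm]])) args[[nm]] <- to_vec(y[[nm]])
  }
  for (nm in c("fall_trend", "nonfall_unintentional_rate",
               "other_injury_rate", "noninjury_rate", "q4", "q5", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  for (nm in c("q1", "q2", "q3")) {
    if (!is.null(y[[nm]])) {
      args[[nm]] <- if (is.list(y[[nm]]) && !is.null(names(y[[nm]])) &&
                        any(names(y[[nm]]) %in% countries$country)) {
        y[[nm]]
      } else {
        to_vec(y[[nm]])
      }
    }
  }
  do.call(scenario_config, args)
}
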