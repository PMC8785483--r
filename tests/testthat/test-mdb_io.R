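# writes a minimal MDB-dialect CSV (list of one_row() records)
write_mdb_csv <- function(rows, path) {
  base <- data.frame(
    Country = vapply(rows, `[[`, "", "country"), Admin1 = "", SubDiv = "",
    Year = vapply(rows, `[[`, 0, "year"),
    List = vapply(rows, `[[`, "", "list"),
    Cause = vapply(rows, `[[`, "", "cause"),
    Sex = vapply(rows, `[[`, 0, "sex"),
    Frmat = vapply(rows, `[[`, 0, "frmat"), IM_Frmat = 0
  )
  m <- matrix(0, nrow = nrow(base), ncol = 26,
              dimnames = list(NULL, paste0("Deaths", 1:26)))
  for (i in seq_along(rows)) m[i, rows[[i]]$bands] <- rows[[i]]$counts
  m[, 1] <- rowSums(m[, 2:26, drop = FALSE])
  readr::write_csv(cbind(base, as.data.frame(m)), path, progress = FALSE)
  path
}

one_row <- function(cause = "W19", bands = 19:25, counts = rep(1, 7),
                    frmat = 0, sex = 1, year = 2010, country = "AAA") {
  list(country = country, year = year, list = "104", cause = cause,
       sex = sex, frmat = frmat, bands = bands, counts = counts)
}

test_that("a single fall row sums to its 65+ total", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row()), f)
  d <- read_death_file(f, age_floor = 65)
  expect_equal(nrow(d), 1)
  expect_equal(d$total65, 7)
  expect_equal(d$d85p, 3) # 85-89 + 90-94 + 95+ merged
})

test_that("unsupported age formats are rejected with a diagnostic", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row("W19"), one_row("W05", frmat = 2)), f)
  expect_message(d <- read_death_file(f), regexp = "Frmat")
  expect_equal(d$cause, "W19")
  expect_equal(attr(d, "diagnostics")$n_frmat_rejected, 1)
})

test_that("missing mandatory columns and negative counts are fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row()), f)
  raw <- readr::read_csv(f, show_col_types = FALSE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw[setdiff(names(raw), "Sex")], f2)
  expect_error(read_death_file(f2), class = "fallcoding_format_error")
  expect_error(read_death_file(f2), regexp = "Sex")

  raw$Deaths19 <- -1
  f3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, f3)
  expect_error(read_death_file(f3), class = "fallcoding_validation_error")
})

test_that("unparseable cause codes are dropped with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row("W19"), one_row("BAD1")), f)
  expect_warning(d <- read_death_file(f), regexp = "BAD1")
  expect_equal(d$cause, "W19")
  expect_equal(attr(d, "diagnostics")$n_cause_dropped, 1)
})

test_that("sexes are combined and stored totals are cross-checked", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row("W19", sex = 1, counts = rep(2, 7)),
                     one_row("W19", sex = 2, counts = rep(3, 7))), f)
  d <- read_death_file(f)
  expect_equal(nrow(d), 1)
  expect_equal(d$total65, 35)
  expect_equal(attr(d, "diagnostics")$n_total_mismatch, 0)
})

test_that("age bands below the floor are zeroed, or kept with floor 0", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_mdb_csv(list(one_row(bands = c(10, 19), counts = c(5, 2))), f)
  d65 <- read_death_file(f, age_floor = 65)
  expect_equal(d65$d_under65, 0)
  expect_equal(d65$total65, 2)
  d0 <- read_death_file(f, age_floor = 0)
  expect_equal(d0$d_under65, 5)
  expect_equal(d0$total65, 2)
  expect_error(read_death_file(f, age_floor = 50),
               class = "fallcoding_bad_arg")
})

test_that("population age groups above 85 collapse into 85+", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(
    location = "AAA", year = 2010,
    age_group = c("65-69", "70-74", "75-79", "80-84", "85-89", "90-94", "95+"),
    population = c(500, 400, 300, 200, 100, 50, 10)
  ), f)
  p <- read_population_file(f)
  expect_equal(nrow(p), 5)
  expect_equal(p$population[p$age_group == "85+"], 160)
  pk <- read_population_file(f, units = "thousands")
  expect_equal(pk$population[pk$age_group == "85+"], 160000)
})

test_that("non-positive populations are fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(location = "AAA", year = 2010,
                              age_group = "65-69", population = 0), f)
  expect_error(read_population_file(f), class = "fallcoding_validation_error")
})

test_that("income lookup validates labels and conflicts", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(
    country_code = c("USA", "VNM", "BRA", "MWI"),
    income_group = c("HICT", "LMICT", "UMICT", "LICT")
  ), f)
  inc <- read_income_lookup(f)
  expect_equal(nrow(inc), 4)
  expect_equal(as.character(inc$income_group[inc$country == "USA"]), "HICT")

  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(country_code = "USA", income_group = "MIDDLE"), f2)
  expect_error(read_income_lookup(f2), regexp = "MIDDLE")

  f3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(country_code = c("USA", "USA"),
                              income_group = c("HICT", "UMICT")), f3)
  expect_error(read_income_lookup(f3), class = "fallcoding_validation_error")
})

test_that("synthetic files round-trip through write and read exactly", {
  sc <- generate_scenario(scenario_library()$sparse)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  back <- read_death_file(paths$deaths)
  orig <- dplyr::arrange(sc$deaths, country, year, cause)
  got <- dplyr::arrange(back, country, year, cause)
  expect_equal(got$cause, orig$cause)
  for (colnm in c("d65_69", "d70_74", "d75_79", "d80_84", "d85p", "total65")) {
    expect_equal(got[[colnm]], orig[[colnm]])
  }
  pop <- read_population_file(paths$population)
  orig_pop <- dplyr::arrange(sc$population, country, year, age_group)
  got_pop <- dplyr::arrange(pop, country, year, age_group)
  expect_equal(got_pop$population, orig_pop$population)
})
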