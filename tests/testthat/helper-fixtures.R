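# Builders for small in-memory death tables in the internal layout.

# counts: named list cause -> either a single 65-69 count or a length-5
# vector over the age groups
fake_rows <- function(country, year, counts, list_id = "104") {
  causes <- names(counts)
  mat <- t(vapply(counts, function(x) {
    if (length(x) == 1) c(x, 0, 0, 0, 0) else as.numeric(x)
  }, numeric(5)))
  tibble::tibble(
    country = country, year = as.integer(year), list = list_id,
    cause = causes,
    d_under65 = 0,
    d65_69 = mat[, 1], d70_74 = mat[, 2], d75_79 = mat[, 3],
    d80_84 = mat[, 4], d85p = mat[, 5],
    d_unknown_age = 0,
    total65 = rowSums(mat)
  )
}

# flat population table for one country over years, same count everywhere
fake_population <- function(country, years, per_group = 10000) {
  tidyr::crossing(
    country = country, year = as.integer(years),
    age_group = age_groups()
  ) |>
    dplyr::mutate(population = per_group)
}

# random cause table guaranteed to have positive target counts in every
# age group and stage universe
random_instance <- function(years = 2010L) {
  counts <- list(
    C509 = sample(50:200, 5, replace = TRUE),   # non-injury
    I219 = sample(50:200, 5, replace = TRUE),
    X709 = sample(5:40, 5, replace = TRUE),     # injury, not unintentional
    V892 = sample(5:40, 5, replace = TRUE),     # unintentional, not fall
    W009 = sample(5:60, 5, replace = TRUE),     # falls
    W180 = sample(5:60, 5, replace = TRUE),
    W19 = sample(5:60, 5, replace = TRUE),
    R99 = sample(0:80, 5, replace = TRUE),      # stage-1 garbage
    Y34 = sample(0:30, 5, replace = TRUE),      # stage-2 garbage
    X59 = sample(0:30, 5, replace = TRUE)       # stage-3 garbage
  )
  dplyr::bind_rows(lapply(years, function(y) fake_rows("RND", y, counts)))
}
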