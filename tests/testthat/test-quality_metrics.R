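# independent per-death counter: expands rows to unit records and decides
# every flag by fresh string comparisons, bypassing classify_cause()
brute_tally <- function(rows) {
  stems <- rep(substr(rows$cause, 1, 3), rows$total65)
  codes <- rep(rows$cause, rows$total65)
  injury <- stems >= "V01" & stems <= "Y89"
  unint <- stems >= "V01" & stems <= "X59"
  fall <- stems >= "W00" & stems <= "W19"
  d4 <- substr(codes, 4, 4)
  c(
    n_total = length(codes),
    n_unspecified = sum(stems %in% c("R96", "R98", "R99")),
    n_injury = sum(injury),
    n_undetermined = sum(stems %in% c("Y30", "Y31", "Y34") |
                           codes %in% c("Y872", "Y899")),
    n_unintentional = sum(unint),
    n_x59 = sum(stems == "X59"),
    n_fall = sum(fall),
    n_w19 = sum(stems == "W19"),
    n_fall_place_unknown = sum(fall & (d4 == "9" | d4 == ""))
  )
}

test_that("category tallies match a hand count and a brute-force recount", {
  rows <- fake_rows("AAA", 2010, list(
    W19 = 10, W009 = 5, X59 = 3, R99 = 2, C509 = 80
  ))
  tl <- tally_categories(rows)
  expect_equal(tl$n_total, 100)
  expect_equal(tl$n_unspecified, 2)
  expect_equal(tl$n_injury, 18)
  expect_equal(tl$n_undetermined, 0)
  expect_equal(tl$n_unintentional, 18)
  expect_equal(tl$n_x59, 3)
  expect_equal(tl$n_fall, 15)
  expect_equal(tl$n_w19, 10)
  # W19 lacks a 4th digit (unknown place) and W009 has digit 9
  expect_equal(tl$n_fall_place_unknown, 15)

  bt <- brute_tally(rows)
  got <- unlist(tl[names(bt)])
  expect_equal(unname(got), unname(bt))
})

test_that("tallies on random instances equal the brute-force counter", {
  set.seed(42)
  for (i in 1:20) {
    rows <- random_instance()
    tl <- tally_categories(rows)
    bt <- brute_tally(rows)
    expect_equal(unname(unlist(tl[names(bt)])), unname(bt))
  }
})

test_that("degenerate tallies: empty input and single-category input", {
  empty <- tally_categories(fake_rows("AAA", 2010, list(C509 = 1))[0, ])
  expect_equal(empty$n_total, 0)
  expect_equal(empty$n_fall, 0)

  only_r99 <- tally_categories(fake_rows("AAA", 2010, list(R99 = 7)))
  expect_equal(only_r99$n_total, 7)
  expect_equal(only_r99$n_unspecified, 7)
  expect_equal(only_r99$n_injury, 0)

  mixed <- dplyr::bind_rows(fake_rows("AAA", 2010, list(R99 = 1)),
                            fake_rows("BBB", 2010, list(R99 = 1)))
  expect_error(tally_categories(mixed),
               class = "fallcoding_contract_violation")
})

test_that("the five proportions are the printed ratios, undefined at zero denominators", {
  counts <- tibble::tibble(
    country = "AAA", year = 2010L,
    n_total = 200, n_unspecified = 20, n_injury = 50, n_undetermined = 5,
    n_unintentional = 40, n_x59 = 4, n_fall = 40, n_w19 = 40,
    n_fall_place_unknown = 10
  )
  qp <- quality_profile(counts)
  expect_equal(qp$proportion_one, 0.10)
  expect_equal(qp$proportion_two, 0.10)
  expect_equal(qp$proportion_three, 0.10)
  expect_equal(qp$proportion_four, 1.00)
  expect_equal(qp$proportion_five, 0.25)

  none <- quality_profile(dplyr::mutate(counts, n_fall = 0, n_w19 = 0,
                                        n_fall_place_unknown = 0))
  expect_true(is.na(none$proportion_four))
  expect_true(is.na(none$proportion_five))

  # derived example: all falls have unknown place
  derived <- quality_profile(tally_categories(fake_rows("AAA", 2010, list(
    W19 = 10, W009 = 5, X59 = 3, R99 = 2, C509 = 80
  ))))
  expect_equal(derived$proportion_five, 1.00)
  expect_equal(derived$proportion_four, 10 / 15)
})

test_that("availability bins count distinct data years within 1990-2019", {
  deaths <- dplyr::bind_rows(
    lapply(2000:2002, function(y) fake_rows("AAA", y, list(W19 = 1))),
    lapply(1990:2016, function(y) fake_rows("BBB", y, list(C509 = 1))),
    fake_rows("CCC", 1985, list(C509 = 1)) # outside the period
  )
  av <- availability(deaths, member_states = c("AAA", "BBB", "CCC", "DDD"))
  bin <- function(ct) as.character(av$bins$bin[av$bins$country == ct])
  expect_equal(bin("AAA"), "1-5")
  expect_equal(bin("BBB"), "26-30")
  expect_equal(bin("CCC"), "0")
  expect_equal(bin("DDD"), "0")
  expect_true(all(av$revisions$revision == "ICD-10"))
})

test_that("income comparison: Kruskal-Wallis with quartiles by linear interpolation", {
  profiles <- tibble::tibble(
    country = rep(c("A1", "B1", "C1", "D1"), each = 3),
    year = rep(2010:2012, 4),
    proportion_one = rep(0.5, 12)
  )
  income <- tibble::tibble(
    country = c("A1", "B1", "C1", "D1"),
    income_group = factor(income_groups(), levels = income_groups())
  )
  flat <- income_group_comparison(profiles, income, 1)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  sep <- profiles
  sep$proportion_one <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9, 0.1, 0.2, 0.3,
                          0.7, 0.8, 0.9)
  two <- income_group_comparison(sep[1:6, ], income[1:2, ], 1)
  expect_lt(two$p_value, 0.05)
  # H from the rank formula, no ties: 12/(N(N+1)) * sum n_g (rbar_g - rbar)^2
  h_manual <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(two$statistic, h_manual)

  # quartiles follow the type-7 interpolation convention
  grp <- two$summary[two$summary$income_group == "LICT", ]
  x <- sort(c(0.1, 0.2, 0.3))
  expect_equal(grp$q25, x[1] + 0.5 * (x[2] - x[1]))
  expect_equal(grp$median, 0.2)

  expect_error(income_group_comparison(profiles[1:3, ], income[1, ], 1),
               class = "fallcoding_insufficient_groups")
})
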