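test_that("window length follows the adaptive rule with half-open intervals", {
  expect_equal(window_length(c(0, 0.29, 0.299)), c(1L, 1L, 1L))
  expect_equal(window_length(c(0.30, 0.45, 0.499)), c(3L, 3L, 3L))
  expect_equal(window_length(c(0.50, 0.60, 0.699)), c(5L, 5L, 5L))
  expect_equal(window_length(c(0.70, 0.9, 1)), c(7L, 7L, 7L))
  expect_equal(window_length(NA_real_), 1L)
  expect_error(window_length(1.2), class = "fallcoding_contract_violation")
  expect_error(window_policy(breaks = c(0.5, 0.3, 0.7)))
  expect_error(window_policy(lengths = c(1, 2, 4, 6)))
})

test_that("pooled shares are windowed ratios of falls to target deaths", {
  # single year: 50 falls among 100 unintentional targets
  d1 <- fake_rows("AAA", 2010, list(W009 = 50, V892 = 50, X59 = 20))
  ps <- pooled_share(d1, "AAA", 2010, 1L, stage = 3, age_group = "65-69")
  expect_equal(ps$share, 0.5)
  expect_false(ps$fallback)

  # 3-year pooling: falls (10,20,30) over targets (100,100,100)
  d3 <- dplyr::bind_rows(
    fake_rows("AAA", 2009, list(W009 = 10, V892 = 90)),
    fake_rows("AAA", 2010, list(W009 = 20, V892 = 80)),
    fake_rows("AAA", 2011, list(W009 = 30, V892 = 70))
  )
  ps3 <- pooled_share(d3, "AAA", 2010, 3L, stage = 3, age_group = "65-69")
  expect_equal(ps3$share, 60 / 300)
  expect_equal(ps3$years_used, 2009:2011)

  # age stratum with zero denominator falls back to the pooled 65+ share
  d_fb <- fake_rows("AAA", 2010, list(
    W009 = c(25, 0, 0, 0, 0), V892 = c(75, 0, 0, 0, 0)
  ))
  fb <- pooled_share(d_fb, "AAA", 2010, 1L, stage = 3, age_group = "85+")
  expect_equal(fb$share, 0.25)
  expect_true(fb$fallback)

  # window truncation at the series boundary
  tr <- pooled_share(d3, "AAA", 2009, 3L, stage = 3, age_group = "65-69")
  expect_equal(tr$years_used, 2009:2010)
  expect_true(tr$truncated)
})

test_that("zero garbage means the correction is an exact identity", {
  d <- fake_rows("AAA", 2010, list(
    W009 = c(5, 10, 15, 20, 25), C509 = c(50, 50, 50, 50, 50),
    V892 = c(3, 3, 3, 3, 3)
  ))
  cr <- correct_year(d, "AAA", 2010)
  expect_identical(cr$by_age$corrected, cr$by_age$observed)
  expect_true(all(cr$stages$garbage_total == 0))
})

test_that("a single stage splits garbage proportionally", {
  # falls 50, other unintentional 50, X59 = 20: share 0.5, +10 falls
  d <- fake_rows("AAA", 2010, list(W009 = 50, V892 = 50, X59 = 20))
  cr <- correct_year(d, "AAA", 2010)
  expect_equal(cr$stages$window, c(1L, 1L, 1L))
  expect_equal(sum(cr$by_age$alloc_stage3), 10)
  expect_equal(sum(cr$by_age$corrected), 60)
})

test_that("stage allocations conserve the garbage totals over the target universe", {
  set.seed(7)
  for (i in 1:50) {
    d <- random_instance(years = 2009:2011)
    cr <- correct_year(d, "RND", 2010)
    cls <- classify_cause(d$cause)
    study <- d$year == 2010
    garbage_totals <- c(
      sum(d$total65[study & cls$unspecified_death]),
      sum(d$total65[study & cls$undetermined_intent]),
      sum(d$total65[study & cls$unspecified_unintentional])
    )
    for (s in 1:3) {
      al <- stage_allocations(d, "RND", 2010, s, cr$stages$window[s])
      expect_equal(sum(al$allocation), garbage_totals[s],
                   tolerance = 1e-9)
      # falls receive exactly what correct_year reports
      fall_alloc <- sum(al$allocation[classify_cause(al$cause)$fall])
      expect_equal(fall_alloc, sum(cr$by_age[[paste0("alloc_stage", s)]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("corrected counts are monotone in the garbage counts", {
  base <- list(W009 = 50, V892 = 50, C509 = 200, X709 = 10,
               R99 = 10, Y34 = 5, X59 = 8)
  more <- base
  more$X59 <- 16
  more$R99 <- 30
  c1 <- correct_year(fake_rows("AAA", 2010, base), "AAA", 2010)
  c2 <- correct_year(fake_rows("AAA", 2010, more), "AAA", 2010)
  expect_true(all(c2$by_age$corrected >= c1$by_age$corrected))
  expect_true(all(c1$by_age$corrected >= c1$by_age$observed))
})

# Independent oracle: full cause-level cascade. Each stage removes its
# garbage and scales every current target cause up proportionally; totals
# are recomputed from the running table between stages.
cascade_oracle <- function(counts) {
  cls <- classify_cause(names(counts))
  g <- list(cls$unspecified_death, cls$undetermined_intent,
            cls$unspecified_unintentional)
  any_g <- Reduce(`|`, g)
  targets <- list(!any_g, cls$injury & !any_g, cls$unintentional & !any_g)
  x <- counts
  for (s in 1:3) {
    G <- sum(x[g[[s]]])
    T_s <- sum(x[targets[[s]]])
    if (G > 0 && T_s > 0) {
      x[targets[[s]]] <- x[targets[[s]]] * (T_s + G) / T_s
      x[g[[s]]] <- 0
    }
  }
  sum(x[cls$fall])
}

test_that("correct_year matches the stage-wise cascade oracle for single-year windows", {
  set.seed(99)
  for (i in 1:25) {
    counts <- c(
      C509 = sample(100:400, 1), X709 = sample(10:50, 1),
      V892 = sample(10:80, 1), W009 = sample(20:100, 1),
      W19 = sample(10:60, 1),
      R99 = sample(1:150, 1), Y34 = sample(1:40, 1), X59 = sample(1:40, 1)
    )
    d <- fake_rows("AAA", 2010, as.list(counts))
    cr <- correct_year(d, "AAA", 2010)
    expect_equal(sum(cr$by_age$corrected), cascade_oracle(counts),
                 tolerance = 1e-9)
  }
})

test_that("a missing study year is a labelled error", {
  d <- fake_rows("AAA", 2010, list(W009 = 5))
  expect_error(correct_year(d, "AAA", 2011),
               class = "fallcoding_missing_year")
  expect_error(correct_year(d, "ZZZ", 2010),
               class = "fallcoding_missing_year")
})

test_that("correct_all is tidy and consistent with correct_year", {
  d <- dplyr::bind_rows(
    fake_rows("AAA", 2009, list(W009 = 40, V892 = 60, R99 = 20, C509 = 100)),
    fake_rows("AAA", 2010, list(W009 = 50, V892 = 50, R99 = 10, C509 = 100))
  )
  all_out <- correct_all(d)
  expect_equal(nrow(all_out), 2 * length(age_groups()))
  one <- correct_year(d, "AAA", 2010)
  sub <- all_out[all_out$year == 2010, ]
  expect_equal(sub$corrected_falls, one$by_age$corrected)
})
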