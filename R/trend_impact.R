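#' Impact of correction on temporal comparisons
#'
#' Two views of how garbage-code correction changes what the data say
#' about time: the 2005-versus-2015 rate change, and the ordinary
#' least-squares trend of the age-adjusted rate on calendar year (fitted
#' only for countries with at least 5 data years). For both, the
#' uncorrected and corrected series are compared and direction/significance
#' reversals flagged at the two-sided alpha = 0.05 level.
#'
#' @name trend_impact
NULL

#' Rate change between two reference years
#'
#' @param series rate series from [rate_series()] (any number of
#'   countries).
#' @param years two comparison years, default `c(2005, 2015)`.
#' @return tibble with one row per country having both years:
#'   `country, delta_uncorrected` (absolute difference per 100,000),
#'   `pct_uncorrected` (relative change, %), `delta_corrected`,
#'   `pct_corrected`, `reversal` (direction differs between the two
#'   series). Countries missing a year are listed in the `excluded`
#'   attribute with the reason.
#' @export
change_between_years <- function(series, years = c(2005L, 2015L)) {
  out <- list()
  excluded <- list()
  for (ct in unique(series$country)) {
    sub <- series[series$country == ct, , drop = FALSE]
    r1 <- sub[sub$year == years[1], , drop = FALSE]
    r2 <- sub[sub$year == years[2], , drop = FALSE]
    if (nrow(r1) != 1 || nrow(r2) != 1) {
      excluded[[ct]] <- tibble::tibble(
        country = ct,
        reason = paste0("missing year ",
                        paste(years[c(nrow(r1) != 1, nrow(r2) != 1)],
                              collapse = ", "))
      )
      next
    }
    du <- r2$rate_uncorrected - r1$rate_uncorrected
    dc <- r2$rate_corrected - r1$rate_corrected
    out[[ct]] <- tibble::tibble(
      country = ct,
      delta_uncorrected = du,
      pct_uncorrected = ifelse(r1$rate_uncorrected > 0,
                               100 * du / r1$rate_uncorrected, NA_real_),
      delta_corrected = dc,
      pct_corrected = ifelse(r1$rate_corrected > 0,
                             100 * dc / r1$rate_corrected, NA_real_),
      reversal = sign(du) * sign(dc) < 0
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded") <- dplyr::bind_rows(excluded)
  res
}

#' Ordinary least-squares year trend of a rate series
#'
#' Classical OLS of rate on calendar year with a two-sided t-test on the
#' slope. A series with zero residual variance gets p = 1 for a zero
#' slope (constant series) and p = 0 for a perfect non-constant line.
#'
#' @param years integer calendar years (at least `min_years` distinct).
#' @param rates rates aligned with `years`.
#' @param min_years inclusion rule, default 5 data years.
#' @return a one-row tibble `b, s_b, p` (slope per year, classical
#'   standard error, two-sided p-value), or `NULL` when the series is
#'   shorter than `min_years` (with a message).
#' @export
fit_trend <- function(years, rates, min_years = 5L) {
  keep <- !is.na(rates) & !is.na(years)
  years <- years[keep]
  rates <- rates[keep]
  if (length(years) < min_years) {
    return(NULL)
  }
  if (stats::var(years) == 0) {
    rlang::abort("years have zero variance; cannot fit a trend",
                 class = "fallcoding_contract_violation")
  }
  if (stats::var(rates) == 0) {
    # exactly constant series: zero slope, no evidence of trend
    return(tibble::tibble(b = 0, s_b = 0, p = 1))
  }
  fit <- stats::lm(rates ~ years)
  # summary() warns on an essentially perfect fit; that case is handled below
  co <- suppressWarnings(summary(fit))$coefficients
  b <- co["years", "Estimate"]
  s_b <- co["years", "Std. Error"]
  p <- co["years", "Pr(>|t|)"]
  if (!is.finite(p)) {
    # degenerate residual variance: summary() yields NaN
    sigma2 <- sum(stats::residuals(fit)^2)
    if (sigma2 < 1e-20) {
      p <- if (abs(b) < 1e-12) 1 else 0
      s_b <- 0
    }
  }
  tibble::tibble(b = b, s_b = s_b, p = p)
}

#' Trend fits for all countries, uncorrected and corrected
#'
#' @param series rate series from [rate_series()].
#' @param min_years minimum data years for inclusion (default 5).
#' @param alpha significance level for the two-sided slope test.
#' @return tibble `country, n_years, b, s_b, p, b_corrected,
#'   s_b_corrected, p_corrected, sign_reversal, sig_lost, sig_gained`.
#'   Countries below `min_years` are omitted and listed in the
#'   `excluded` attribute.
#' @export
trend_table <- function(series, min_years = 5L, alpha = 0.05) {
  out <- list()
  excluded <- list()
  for (ct in unique(series$country)) {
    sub <- series[series$country == ct, , drop = FALSE]
    fu <- fit_trend(sub$year, sub$rate_uncorrected, min_years)
    fc <- fit_trend(sub$year, sub$rate_corrected, min_years)
    if (is.null(fu) || is.null(fc)) {
      excluded[[ct]] <- tibble::tibble(
        country = ct,
        reason = paste0("fewer than ", min_years, " data years")
      )
      next
    }
    sig_u <- fu$p <= alpha
    sig_c <- fc$p <= alpha
    out[[ct]] <- tibble::tibble(
      country = ct,
      n_years = nrow(sub),
      b = fu$b, s_b = fu$s_b, p = fu$p,
      b_corrected = fc$b, s_b_corrected = fc$s_b, p_corrected = fc$p,
      sign_reversal = sign(fu$b) * sign(fc$b) < 0,
      sig_lost = sig_u & !sig_c,
      sig_gained = !sig_u & sig_c
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded") <- dplyr::bind_rows(excluded)
  res
}

#' Summary of trend reversals across countries
#'
#' @param fits output of [trend_table()].
#' @return tibble with one row per initial slope sign (`positive`,
#'   `negative`): `n_countries, n_sign_reversal, n_sig_lost,
#'   n_sig_gained, pct_sign_reversal`.
#' @export
reversal_summary <- function(fits) {
  if (nrow(fits) == 0) {
    return(tibble::tibble(
      initial_sign = c("positive", "negative"),
      n_countries = 0L, n_sign_reversal = 0L,
      n_sig_lost = 0L, n_sig_gained = 0L,
      pct_sign_reversal = NA_real_
    ))
  }
  fits$initial_sign <- ifelse(fits$b >= 0, "positive", "negative")
  out <- dplyr::summarise(
    dplyr::group_by(fits, .data$initial_sign),
    n_countries = dplyr::n(),
    n_sign_reversal = sum(.data$sign_reversal),
    n_sig_lost = sum(.data$sig_lost),
    n_sig_gained = sum(.data$sig_gained),
    .groups = "drop"
  )
  miss <- setdiff(c("positive", "negative"), out$initial_sign)
  if (length(miss) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      initial_sign = miss, n_countries = 0L, n_sign_reversal = 0L,
      n_sig_lost = 0L, n_sig_gained = 0L
    ))
  }
  out$pct_sign_reversal <- ifelse(
    out$n_countries > 0, 100 * out$n_sign_reversal / out$n_countries,
    NA_real_
  )
  out[match(c("positive", "negative"), out$initial_sign), ]
}
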