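#' Adaptive-window proportionate redistribution of problematic codes
#'
#' The first three problematic-code types distort the overall fall
#' mortality level and are corrected by proportionate redistribution:
#' garbage-coded deaths are assumed to follow the same cause distribution
#' as specifically coded deaths and are allocated accordingly. The three
#' stages, applied in order, are
#' \enumerate{
#'   \item unspecified deaths (R96/R98/R99) over all specified causes,
#'   \item undetermined-intent deaths (Y30/Y31/Y34/Y87.2/Y89.9) over
#'     injury causes,
#'   \item unspecified unintentional injuries (X59) over unintentional
#'     injury causes,
#' }
#' in each case excluding the garbage codes themselves from the target
#' universe. The cause distribution is estimated from a window of years
#' centred on the study year whose length adapts to how bad the coding is
#' in that year: below 30% problematic the same year alone is used, 30-49%
#' pools 3 years, 50-69% pools 5 years and 70% or more pools 7 years.
#' Windows are truncated to the years the country actually has.
#'
#' Redistribution is age-group specific within 65+; an age stratum with a
#' zero window denominator falls back to the pooled all-65+ share, and to
#' zero (flagged) if that is empty too. Shares come from observed counts
#' and stage allocations add up, so corrected counts never fall below
#' observed ones, and each stage conserves its garbage total across the
#' full target universe.
#'
#' @name garbage_redistribution
NULL

#' Window-length rule for the proportionate method
#'
#' @param p proportion of deaths with problematic codes in the study year,
#'   in \[0,1\].
#' @param policy window policy from [window_policy()].
#' @return integer window length in years: 1 (p < 0.30), 3 (0.30-0.49),
#'   5 (0.50-0.69) or 7 (p >= 0.70) under the default policy.
#' @examples
#' window_length(c(0.29, 0.45, 0.60, 0.70))
#' @export
window_length <- function(p, policy = window_policy()) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    rlang::abort("problematic proportion must lie in [0, 1]",
                 class = "fallcoding_contract_violation")
  }
  idx <- findInterval(p, policy$breaks) + 1L
  out <- policy$lengths[idx]
  out[is.na(p)] <- policy$lengths[1]
  as.integer(out)
}

#' Window policy: breakpoints and pooling lengths
#'
#' @param breaks strictly increasing breakpoints in (0,1) on the
#'   problematic proportion; default `c(0.30, 0.50, 0.70)`.
#' @param lengths odd, increasing window lengths in years, one more than
#'   `breaks`; default `c(1, 3, 5, 7)`, centred on the study year.
#' @return a `window_policy` list.
#' @export
window_policy <- function(breaks = c(0.30, 0.50, 0.70),
                          lengths = c(1L, 3L, 5L, 7L)) {
  stopifnot(
    length(lengths) == length(breaks) + 1,
    all(diff(breaks) > 0), all(breaks > 0), all(breaks < 1),
    all(lengths %% 2 == 1), all(diff(lengths) > 0)
  )
  structure(list(breaks = breaks, lengths = as.integer(lengths)),
            class = "window_policy")
}

# Stage definitions: garbage mask, target-universe mask, and which of the
# three quality proportions drives the window choice.
.stage_masks <- function(cls) {
  garbage1 <- cls$unspecified_death
  garbage2 <- cls$undetermined_intent
  garbage3 <- cls$unspecified_unintentional
  any_garbage <- garbage1 | garbage2 | garbage3
  list(
    garbage = list(garbage1, garbage2, garbage3),
    target = list(
      !any_garbage,
      cls$injury & !any_garbage,
      cls$unintentional & !any_garbage
    ),
    prop_denominator = list(
      rep(TRUE, nrow(cls)), # all deaths
      cls$injury,
      cls$unintentional
    )
  )
}

# per-year x age-group totals for rows selected by a mask
.year_age_totals <- function(deaths, mask) {
  m <- as.matrix(deaths[.age_cols])
  if (!any(mask)) {
    out <- matrix(0, nrow = 0, ncol = length(.age_cols))
    colnames(out) <- .age_cols
    return(out)
  }
  rowsum(m[mask, , drop = FALSE], deaths$year[mask])
}

.window_sum <- function(totals, years) {
  keep <- rownames(totals) %in% as.character(years)
  colSums(totals[keep, , drop = FALSE])
}

#' Pooled fall share within a stage's target universe
#'
#' The fraction of a redistribution stage's target-universe deaths that
#' are falls, pooled over a window of years. Used as the allocation share
#' for garbage-coded deaths.
#'
#' @param deaths internal death table (any countries/years).
#' @param country country code.
#' @param year study year (window centre).
#' @param window odd window length in years; truncated to available years.
#' @param stage redistribution stage 1, 2 or 3.
#' @param age_group one of [age_groups()], or `NULL` for the pooled
#'   all-65+ share.
#' @return a list: `share` in \[0,1\], `years_used`, `truncated`,
#'   `fallback` (age stratum was empty, pooled share used), `empty`
#'   (no target deaths at all; share 0).
#' @export
pooled_share <- function(deaths, country, year, window, stage,
                         age_group = NULL) {
  sub <- deaths[deaths$country == country & is_icd10_list(deaths$list), ,
                drop = FALSE]
  cls <- classify_cause(sub$cause)
  masks <- .stage_masks(cls)
  half <- (window - 1L) %/% 2L
  years_avail <- sort(unique(sub$year))
  years_used <- intersect((year - half):(year + half), years_avail)
  if (length(years_used) == 0) {
    return(list(share = 0, years_used = integer(0), truncated = TRUE,
                fallback = FALSE, empty = TRUE))
  }
  fall_tot <- .year_age_totals(sub, cls$fall)
  targ_tot <- .year_age_totals(sub, masks$target[[stage]])
  num <- .window_sum(fall_tot, years_used)
  den <- .window_sum(targ_tot, years_used)
  idx <- if (is.null(age_group)) NULL else match(age_group, age_groups())
  fallback <- FALSE
  empty <- FALSE
  if (is.null(idx) || den[idx] == 0) {
    if (!is.null(idx)) fallback <- TRUE
    n <- sum(num)
    d <- sum(den)
  } else {
    n <- num[idx]
    d <- den[idx]
  }
  share <- if (d > 0) n / d else {
    empty <- TRUE
    0
  }
  list(share = unname(share), years_used = years_used,
       truncated = length(years_used) < window,
       fallback = fallback, empty = empty)
}

#' Correct one country-year's fall deaths for garbage coding
#'
#' Runs the three redistribution stages for one study year: each stage
#' picks its pooling window from that stage's problematic proportion,
#' computes age-specific fall shares of its target universe pooled over
#' the window, and allocates the study year's observed garbage deaths to
#' falls by those shares. Allocations accumulate additively on top of the
#' observed fall counts.
#'
#' @inheritParams pooled_share
#' @param policy window policy, default [window_policy()].
#' @return an object of class `fall_correction`: a list with `country`,
#'   `year`, `by_age` (tibble `age_group, observed, alloc_stage1..3,
#'   corrected`), `stages` (tibble `stage, proportion, garbage_total,
#'   window, years_used, truncated`), and `flags` (fallback/empty strata
#'   per stage).
#' @export
correct_year <- function(deaths, country, year, policy = window_policy()) {
  sub <- deaths[deaths$country == country & is_icd10_list(deaths$list), ,
                drop = FALSE]
  if (!year %in% sub$year) {
    rlang::abort(
      paste0("no ICD-10 data for ", country, " in ", year),
      class = "fallcoding_missing_year"
    )
  }
  cls <- classify_cause(sub$cause)
  masks <- .stage_masks(cls)
  study <- sub$year == year
  m <- as.matrix(sub[.age_cols])
  years_avail <- sort(unique(sub$year))
  fall_tot <- .year_age_totals(sub, cls$fall)

  observed <- colSums(m[study & cls$fall, , drop = FALSE])
  alloc <- matrix(0, nrow = 3, ncol = length(.age_cols),
                  dimnames = list(paste0("stage", 1:3), .age_cols))
  stage_rows <- vector("list", 3)
  flags <- vector("list", 3)

  for (s in 1:3) {
    garbage_age <- colSums(m[study & masks$garbage[[s]], , drop = FALSE])
    denom <- sum(m[study & masks$prop_denominator[[s]], , drop = FALSE])
    p <- if (denom > 0) sum(garbage_age) / denom else NA_real_
    L <- window_length(p, policy)
    half <- (L - 1L) %/% 2L
    years_used <- intersect((year - half):(year + half), years_avail)
    truncated <- length(years_used) < L
    fb <- logical(length(.age_cols))
    em <- logical(length(.age_cols))
    if (sum(garbage_age) > 0) {
      targ_tot <- .year_age_totals(sub, masks$target[[s]])
      num <- .window_sum(fall_tot, years_used)
      den <- .window_sum(targ_tot, years_used)
      for (a in seq_along(.age_cols)) {
        if (garbage_age[a] == 0) next
        if (den[a] > 0) {
          share <- num[a] / den[a]
        } else if (sum(den) > 0) {
          # sparse stratum: fall back to the pooled all-65+ share
          fb[a] <- TRUE
          share <- sum(num) / sum(den)
        } else {
          em[a] <- TRUE
          share <- 0
        }
        alloc[s, a] <- garbage_age[a] * share
      }
    }
    stage_rows[[s]] <- tibble::tibble(
      stage = s, proportion = p, garbage_total = sum(garbage_age),
      window = L, years_used = list(years_used), truncated = truncated
    )
    flags[[s]] <- tibble::tibble(
      stage = s, age_group = age_groups(), fallback = fb, empty = em
    )
  }

  corrected <- observed + colSums(alloc)
  structure(
    list(
      country = country,
      year = year,
      by_age = tibble::tibble(
        age_group = age_groups(),
        observed = unname(observed),
        alloc_stage1 = unname(alloc[1, ]),
        alloc_stage2 = unname(alloc[2, ]),
        alloc_stage3 = unname(alloc[3, ]),
        corrected = unname(corrected)
      ),
      stages = dplyr::bind_rows(stage_rows),
      flags = dplyr::bind_rows(flags)
    ),
    class = "fall_correction"
  )
}

#' @export
print.fall_correction <- function(x, ...) {
  cat("Fall-mortality garbage-code correction:", x$country, x$year, "\n")
  cat("  observed 65+ falls:", sum(x$by_age$observed),
      "-> corrected:", round(sum(x$by_age$corrected), 2), "\n")
  cat("  stage windows (years):",
      paste(x$stages$window, collapse = ", "), "\n")
  invisible(x)
}

#' Full per-cause allocation of one stage's garbage deaths
#'
#' Audit view of a redistribution stage: allocates the study year's
#' garbage deaths across every cause of the stage's target universe (not
#' just falls), using the same windowed shares and fallbacks as
#' [correct_year()]. Within each age stratum with a non-empty window
#' denominator, allocations sum exactly to the stratum's garbage count.
#'
#' @inheritParams pooled_share
#' @param window odd window length in years; chosen by the caller (use the
#'   stage's [window_length()] for consistency with [correct_year()]).
#' @return tibble `cause, age_group, allocation`.
#' @export
stage_allocations <- function(deaths, country, year, stage, window) {
  sub <- deaths[deaths$country == country & is_icd10_list(deaths$list), ,
                drop = FALSE]
  cls <- classify_cause(sub$cause)
  masks <- .stage_masks(cls)
  half <- (window - 1L) %/% 2L
  years_avail <- sort(unique(sub$year))
  years_used <- intersect((year - half):(year + half), years_avail)
  m <- as.matrix(sub[.age_cols])
  study <- sub$year == year
  garbage_age <- colSums(m[study & masks$garbage[[stage]], , drop = FALSE])

  tmask <- masks$target[[stage]]
  in_window <- sub$year %in% years_used & tmask
  # per-cause x age pooled counts over the window
  cause_tot <- rowsum(m[in_window, , drop = FALSE], sub$cause[in_window])
  den <- colSums(cause_tot)
  out <- list()
  for (a in seq_along(.age_cols)) {
    if (garbage_age[a] == 0) next
    if (den[a] > 0) {
      shares <- cause_tot[, a] / den[a]
    } else if (sum(den) > 0) {
      shares <- rowSums(cause_tot) / sum(den)
    } else {
      next
    }
    out[[a]] <- tibble::tibble(
      cause = rownames(cause_tot),
      age_group = age_groups()[a],
      allocation = unname(garbage_age[a] * shares)
    )
  }
  dplyr::bind_rows(out)
}

#' Correct every year of one or more countries
#'
#' @param deaths internal death table.
#' @param countries country codes; default all countries present.
#' @param policy window policy.
#' @return a tidy tibble with one row per country-year-age-group:
#'   `country, year, age_group, observed_falls, corrected_falls,
#'   alloc_stage1..3, window_stage1..3, fallback` (any zero-denominator
#'   fallback in that stratum).
#' @export
correct_all <- function(deaths, countries = NULL, policy = window_policy()) {
  icd10 <- deaths[is_icd10_list(deaths$list), , drop = FALSE]
  if (is.null(countries)) countries <- sort(unique(icd10$country))
  rows <- list()
  for (ct in countries) {
    years <- sort(unique(icd10$year[icd10$country == ct]))
    for (y in years) {
      cr <- correct_year(deaths, ct, y, policy)
      fb <- dplyr::summarise(
        dplyr::group_by(cr$flags, .data$age_group),
        fallback = any(.data$fallback | .data$empty), .groups = "drop"
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        country = ct, year = y,
        age_group = cr$by_age$age_group,
        observed_falls = cr$by_age$observed,
        corrected_falls = cr$by_age$corrected,
        alloc_stage1 = cr$by_age$alloc_stage1,
        alloc_stage2 = cr$by_age$alloc_stage2,
        alloc_stage3 = cr$by_age$alloc_stage3,
        window_stage1 = cr$stages$window[1],
        window_stage2 = cr$stages$window[2],
        window_stage3 = cr$stages$window[3],
        fallback = fb$fallback[match(cr$by_age$age_group, fb$age_group)]
      )
    }
  }
  dplyr::bind_rows(rows)
}
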