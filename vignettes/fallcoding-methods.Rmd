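---
title: "Assessing and correcting ICD-10 coding quality for elderly fall mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and correcting ICD-10 coding quality for elderly fall mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallcoding)
```

## The problem

Vital-registration systems report deaths by ICD-10 cause code, but a large
share of injury deaths carry codes too vague to say what actually
happened. For unintentional falls among adults aged 65 and older — a
leading and growing cause of injury death in ageing populations — five
kinds of problematic codes matter:

1. **Unspecified deaths** (R96, R98, R99): no usable cause at all.
2. **Injury deaths with undetermined intent** (Y30, Y31, Y34, Y87.2,
   Y89.9): external cause known, intent not.
3. **Unspecified unintentional injuries** (X59): unintentional, mechanism
   unknown.
4. **Falls with unspecified mechanism** (W19): a fall, but not what kind.
5. **Falls with unknown occurrence place** (fourth digit 9 of W00–W19).

The first three hide fall deaths inside vaguer categories and therefore
bias the *level* and *trend* of fall mortality; the last two only blur
subgroup detail within falls. This package measures all five per country
and year, redistributes the first three onto specific causes, and
quantifies how much the correction changes age-standardised rates,
between-year comparisons, and fitted time trends.

## Data model

Death inputs follow the WHO Mortality Database flat-file layout: one row
per country, year, ICD list, cause and sex, with 26 age-banded count
columns. Only the full-detail age format is accepted; coarser age formats
would require an under-determined band-merging step, so those rows are
rejected with a diagnostic. Sexes are combined at load time because the
analysis concerns both sexes together. Ages 65+ are collapsed to five
groups (65–69, 70–74, 75–79, 80–84, 85+), the lowest common resolution
between the source bands and the standard-population weights. Deaths of
unspecified age (band 26) are excluded from 65+ analyses and their
magnitude logged; their age is unrecoverable and assigning them to strata
would inject an arbitrary age pattern. The loader recomputes the all-ages
total from the bands and counts rows whose stored total disagrees, since
source files are not internally consistent.

Quality analysis is restricted to ICD-10-coded years (list tags with
prefix `10`); earlier revisions are only tagged for the availability
summary. All five indicators are computed on the 65+ restriction by
default, with an all-ages switch, because the fall-specific indicators are
only meaningful within the elderly population being studied.

### Code ranges

The injury universe is V01–Y89, which includes the late-effect (sequelae)
codes Y85–Y89; the unintentional universe is V01–X59, which excludes
them. This is the conventional reading of the external-cause chapter:
sequelae of intentional or undetermined events must not enter the
unintentional denominator, and keeping Y85–Y86 out of it makes the
undetermined-intent sequelae rule (Y87.2) coherent. Codes are handled in
the 4-character MDB convention without decimal points, so Y87.2 is the
string `Y872`. A three-character fall code (plain `W19`) carries no place
digit; the place is unrecoverable, so the default policy counts it as
unknown place — the indicator measures place *specificity*, and a code
that omits the digit is exactly as uninformative as digit 9. The policy
is a flag (`missing_is_unknown`) for users who prefer to treat missing
digits as missing data.

## The five indicators

For one country-year, with all counts restricted to 65+:

$$p_1 = \frac{\text{unspecified deaths}}{\text{total deaths}},\quad
  p_2 = \frac{\text{undetermined-intent injury deaths}}{\text{injury deaths}},\quad
  p_3 = \frac{\text{X59 deaths}}{\text{unintentional injury deaths}},$$
$$p_4 = \frac{\text{W19 deaths}}{\text{fall deaths}},\quad
  p_5 = \frac{\text{unknown-place fall deaths}}{\text{fall deaths}}.$$

Internally all proportions live in $[0,1]$ and are `NA` when the
denominator is zero (never silently 0). Cross-country comparison by
World Bank income class uses the Kruskal–Wallis rank-sum test with
country-years as the analysis units — each year contributes one point, so
countries with longer series carry more weight, matching how the
indicator distributions are usually displayed. Group summaries report
medians and quartiles under the linear-interpolation (type 7) convention;
the convention is stated because quartiles of small groups depend on it.

## Proportionate redistribution with adaptive windows

The correction assumes garbage-coded deaths follow the same cause
distribution as specifically coded deaths, and redistributes them
proportionally. Three stages run in order, broadest garbage first:

| stage | garbage set | target universe | driving proportion |
|---|---|---|---|
| 1 | R96/R98/R99 | all specified causes | $p_1$ |
| 2 | Y30/Y31/Y34/Y87.2/Y89.9 | injury causes | $p_2$ |
| 3 | X59 | unintentional causes | $p_3$ |

with every target universe excluding all three garbage sets. The cause
distribution used for allocation is estimated from a window of years
centred on the study year; the window grows with the study year's
problematic proportion: below 30% the same year alone, 30–49% three
years, 50–69% five years, 70% and above seven years. A noisier
numerator (worse coding means fewer specific deaths) needs more pooling.
The printed thresholds are integers on a continuous quantity, so the gaps
are closed as half-open intervals $[0.30, 0.50)$ and $[0.50, 0.70)$.

For age group $a$ and stage $s$, with $G_s(a)$ the study year's garbage
count and window-pooled fall and target totals $F^w_s(a)$, $T^w_s(a)$:

$$g_s(a) = G_s(a) \cdot \frac{F^w_s(a)}{T^w_s(a)}, \qquad
  d^*(a) = d(a) + \sum_{s=1}^3 g_s(a).$$

Design choices worth stating, since the procedure sketch leaves them
open:

* **Stage order 1→2→3.** No order is canonical; because shares are
  computed on observed counts, order affects nothing at all here — the
  three allocations are independent and additive. The equivalent
  cause-level view is a stage-wise cascade in which each stage removes
  its garbage and scales the current target counts by
  $(T_s + G_s)/T_s$; the cascade and the additive form agree exactly
  (the cascade's later denominators inflate by precisely the factor that
  cancels the cross terms), and the test suite verifies this equivalence
  against an independent full-table cascade oracle at $10^{-9}$.
* **Observed denominators.** A variant in which stage $s$ pools
  stage-$(s-1)$-corrected counts changes nothing either, because
  proportional scaling is uniform within each later target universe; the
  observed-count formulation is kept for reproducibility and windowed
  pooling simplicity.
* **Window truncation.** At series boundaries the window keeps only the
  years that exist within $\pm(L-1)/2$ of the study year, rather than
  shifting; shifting would weight boundary years asymmetrically and is
  left as a possible extension.
* **Age-specific shares with pooled fallback.** Direct standardisation
  needs corrected counts per age group, so shares are age-specific within
  65+; a stratum whose window denominator is zero falls back to the
  pooled all-65+ share, and to zero (flagged) if even that is empty.
  Every fallback and truncation is flagged in the output — these flags
  are the audit trail for any data-quality claim built on the corrected
  series.
* **Real-valued corrected counts.** No rounding to integers: rates, not
  counts, are the downstream quantity, and rounding would break the
  conservation property (each stage's allocations over its whole target
  universe sum exactly to the stage's garbage count).

## Rates, impact tiers, trends

Age-standardised 65+ fall mortality uses the direct method with the WHO
World Standard Population age weights renormalised over 65+, the terminal
85–89/90–94/95–99/100+ groups merged into 85+. The full published
standard ships as a CSV (`extdata/who_world_standard.csv`) so an
alternative standard or truncation scheme can be substituted. Rates are
reported per 100,000; ratios and regressions are scale-invariant, so the
unit only affects display.

The per-year impact of coding problems is the ratio
$r(y) = R^*(y)/R(y)$ of corrected to uncorrected rates; under the
additive correction $r(y) \ge 1$. Countries are classified into six
quality tiers by their *maximum* ratio across years: highest
$[1.0, 1.1)$, higher $[1.1, 1.2)$, high $[1.2, 1.3)$, low $[1.3, 1.4)$,
lower $[1.4, 1.5)$, lowest $\ge 1.5$. Tier boundaries operate on the
unrounded maximum; display rounding to two decimals is separate, so a
maximum of 1.3999 is "low" even though it prints as 1.40.

Trend impact is assessed two ways. First, the absolute and relative rate
change between two reference years (default 2005 and 2015, strictly
matched) is compared before and after correction, with a reversal flag
when the direction flips. Second, for countries with at least five data
years, ordinary least squares of the rate on calendar year gives slope
$b$ with classical standard error $S_b$ and a two-sided $t$-test;
significance means $p \le 0.05$. A constant series is reported as
$b = 0$, $p = 1$; an exactly zero slope counts as "no reversal".
Heteroskedasticity-robust errors are deliberately not used — the classical
$b\ (S_b)$ form is the comparison target — and no joinpoint or spline
models are fitted; linearity is a stated limitation of the approach, not
of the implementation.

## What the synthetic data emulate — and what they do not

The generator draws deaths per country, year and age group from binomial
models (population × rate) for four cause groups: falls (with an
age-increasing rate schedule), other unintentional injuries, other
injuries, and non-injury causes. Problematic codes are then injected by
*relabelling*: each death becomes R99 with probability $q_1$; surviving
injury deaths become Y34 with probability $q_2$; surviving unintentional
deaths become X59 with probability $q_3$; surviving falls are coded W19
with probability $q_4$ and get place digit 9 with probability $q_5$.
Relabelling (rather than adding deaths) preserves total mortality and
makes the proportionate method's assumption true *by construction* — so
parameter-recovery tests probe the implementation, not the assumption.
That is also the honest limit of what passing tests show: on real data
the assumption can fail (garbage codes may preferentially hide falls, or
preferentially hide other causes), and no test here speaks to that. The
generator likewise does not mimic any real country's levels, the
migration between ICD revisions, subnational reporting gaps, or
correlated miscoding across years.

Default scenario conditions (the shipped `scenario_library()`):

* **clean** — no injection; correction must be an exact identity.
* **tiered** — four countries at $q_1$ = 20/40/60/75%, one per window
  regime, one per income class; populations of 100,000 over the five age
  groups with an overall death rate near 6% so each country-year has at
  least 5,000 deaths, and roughly 480 true fall deaths per year so that
  windowed shares are estimated well enough for corrected totals to sit
  within a few percent of truth. Recovery is checked at 5% relative
  error over three seeds.
* **indicators** — one country at double that population (about 33,000
  deaths per year) with all five rates set ($q_1$=0.10, $q_2$=0.15,
  $q_3$=0.20, $q_4$=0.50, $q_5$=0.60); measured indicators must sit
  within three binomial standard deviations of the injected rates.
* **improving_coding** — $q_1$ falls linearly from 50% to 10% over
  2000–2015 while the true fall rate is flat: the uncorrected series
  shows a spurious rise and the corrected slope must land closer to the
  true slope in every seed.
* **sparse** — populations of a few hundred per age group with a high
  $q_3$, so some strata have empty target universes; exercises the
  pooled-share fallback and window truncation paths.

The per-age fall rates (100–2,000 per 100,000 from 65–69 up to 85+) are
on the high side of real elderly fall mortality; they were chosen so that
fall counts are large enough for share estimation at desk-scale
populations while keeping the age gradient (roughly doubling per 5-year
group) realistic.

## Numerical conventions

* Proportions are `NA`, never 0, when a denominator is zero.
* Window choice with an undefined driving proportion (no deaths at all)
  defaults to the single-year window; with zero garbage the stage is a
  no-op regardless.
* Conservation is exact up to floating-point (checked at $10^{-9}$
  relative); standardisation against a brute-force weighted sum at
  $10^{-12}$; OLS against closed-form formulas at $10^{-10}$.
* All randomness flows from a single integer seed per generated
  scenario; identical configuration and seed give byte-identical files.

## Known limitations

* The proportionate method redistributes only the first three code
  types; W19 and unknown-place falls are left as coded, so mechanism-
  and place-specific subgroup rates remain biased (by design — those two
  types do not affect the overall fall rate).
* No confidence intervals on standardised rates are produced.
* Countries are identified by their file codes; no name harmonisation is
  attempted beyond the income lookup.
* The income comparison treats country-years as exchangeable units;
  within-country serial correlation is ignored, as is standard for this
  descriptive display.
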