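---
title: "Methods: puff topography, nicotine emission and cohort adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: puff topography, nicotine emission and cohort adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufftopo)
```

## The problem

Puff-recording electronic nicotine delivery systems (PR-ENDS) log every
activation of the device: a timestamp, the puff duration (firmware cuts
power at 10 s), one of three discrete power settings (low 7–9 W, medium
9–11 W, high 11–13 W), and the user-reported e-liquid nicotine
concentration. Over a two-month observation of ~58 users this yields on
the order of 200,000 puffs — enough that significance tests are
uninformative (everything is "significant"), so the scientific questions
are about *magnitudes*: how much nicotine does a puff deliver, how large
are the effects of device power, e-liquid strength and nicotine history
on puffing behaviour, how variable is one user day to day, and how does
a cohort's daily use evolve after first pickup?

`pufftopo` implements that analysis as a pipeline over plain tibbles:
validated ingestion → per-puff emission estimation → descriptive and
effect-size statistics → per-user variability → relative-day cohort time
courses. Because no raw cohort of this kind is publicly deposited, the
package also ships a seeded synthetic-cohort generator whose defaults
state the emulated study, so every stage is testable end to end.

## Per-puff emission model

The laboratory anchor: on the bench, the device emits `E_ref = 0.0952`
mg of nicotine per puff with 12 mg/mL e-liquid at high power under the
Coresta machine-puffing regime (55 mL volume, 3-s puff, 30-s interval).
Field puffs are scaled off that anchor with a separable model

\[
e \;=\; E_{\mathrm{ref}} \cdot \frac{c}{c_{\mathrm{ref}}} \cdot
\frac{d}{d_{\mathrm{ref}}} \cdot \frac{w(P)}{w(P_{\mathrm{ref}})},
\]

with `c` the nicotine concentration (mg/mL), `d` the puff duration (s),
and `w(P)` the representative wattage of the power band — the band
midpoint (8, 10, 12 W), since only ranges are specified. Assumptions
worth making explicit:

* **Linearity in each input.** Aerosol nicotine yield is taken
  proportional to concentration, to energising time, and to power. This
  is the simplest model consistent with the four inputs the device
  records; volume and flow rate enter only through the calibration
  constant. The strategy is injected (`model` argument of
  `puff_emission()`), so a refined formula — nonlinear wattage,
  duty-cycle or PG/VG terms — can replace it without touching callers.
* **Missingness is never imputed.** A puff without a concentration
  record is *not estimable* (`NA`), and daily totals report how many
  puffs were excluded. Zero-nicotine puffs have exactly zero emission.
* **Calibration identity.** By construction the model returns
  `emission_ref` exactly at the calibration point; this is asserted, not
  approximated.

```{r emission}
puff_emission(12, 3, "high")            # the bench anchor
puff_emission(c(6, 3), c(3, 4.5), c("high", "medium"))
```

## Effect sizes instead of p-values

With n in the hundreds of thousands, ANOVA p-values collapse to zero for
any factor; the package therefore computes no p-values at all.

* **Eta-squared** (`eta_squared()`): the one-way decomposition
  SS\_between / SS\_total — the proportion of outcome variance explained
  by a categorical factor. This is the standard construction behind an
  "R² coefficient for a categorical variable"; the source analysis never
  writes the formula, so the choice is documented here prominently.
* **Cohen's d** (`cohen_d()`): standardized mean difference with the
  pooled-SD denominator
  \(\sqrt{((n_a-1)s_a^2+(n_b-1)s_b^2)/(n_a+n_b-2)}\). The Hedges
  small-sample correction is available (`correction = TRUE`) but off by
  default — at these group sizes it is immaterial, and the uncorrected
  pooled form is the conventional default. The reporting layer
  (`effect_size_report()`) suppresses |d| < 0.5 as not-applicable,
  mirroring the convention of presenting only medium-or-larger effects.

The unit of analysis is the puff. Puffs within a user are dependent, so
puff-level effect sizes describe the recorded corpus, not a
user-sampling distribution; for sensitivity, the same functions can be
applied to per-user aggregates (one value per user) — both views are
legitimate, and the puff-level one matches the published tables'
n values.

## Intra-individual variability

`user_cv()` computes, per user over their own *active* days (days with
at least one puff), the coefficient of variation
\( \mathrm{CV}\% = 100\, s/\bar{x} \) of daily puff count, daily mean
duration and daily nicotine consumption. A CV is undefined — reported as
`NA` with a reason, never zeroed — when a user has fewer than two active
days or a non-positive mean. The expected signature of real use is
duration CVs concentrated below ~40% while count and consumption CVs
spread up to ~160%: puff duration is a stable motor habit, intensity of
use is not.

## Relative-day cohort time courses

Users enrol on different calendar dates, so cohort curves align users by
*experience*: each user's first day with ≥ 1 puff is their relative
day 1. Three semantics matter and are all deliberate:

* **Active-user means.** A relative day's cohort mean averages over the
  users active that day; inactive days are absent, not zero-filled. A
  zero-filled alternative materially changes the curves (it mixes
  "how much, when using" with "whether using") and can be obtained by
  densifying the summaries before `cohort_series()`.
* **Two-stage duration aggregation.** The duration curve averages each
  active user's own daily mean — one value per user per day — rather
  than pooling puffs, so heavy users do not dominate.
* **SE bands** use the sample SD across active users divided by
  √n_active, with no autocorrelation correction.

`adaptation_metrics()` quantifies the day-1-low → ramp → plateau
pattern: the day-1 mean, the plateau mean over a stated window, the
first day whose mean is within `tolerance × plateau_mean` of the plateau
(`ramp_days`), and the least-squares slope (±SE) over the plateau
window. The plateau window defaults to relative days 8–21, following
the observed stabilisation after the first week; it is configurable and
errors when outside the observed range. `subgroup_by_duration()`
repeats the analysis within use-span subgroups; span is the last active
relative day rounded up to whole weeks — the published subgrouping is
not defined precisely, so this interpretation is stated rather than
assumed silently.

## The synthetic cohort: a stated world

`synthetic_cohort_config()` defaults encode the emulated study; they are
chosen once from the published summaries and are not tuning knobs.

```{r config}
cfg <- synthetic_cohort_config(n_users = 6, n_days = 14, seed = 11)
sim <- generate_cohort(cfg)
sim
```

* **Durations** are lognormal *censored* at the 10-s cutoff — draws
  beyond 10 s are recorded as 10 s, reproducing the spike at exactly
  10 s that the auto-shutoff produces. The lognormal is the simplest
  right-skewed family consistent with "slightly right skewed".
  (`meanlog`, `sdlog`) are solved numerically (nested `uniroot`,
  tolerance 1e-12, closed-form censored moments in
  `censored_lnorm_moments()`) so the *censored* law has mean 3.44 s and
  SD 1.65 s. Those targets describe the stabilised regime; day-1
  durations are deflated by 2.8/3.5 = 0.8 with a 6-day linear ramp
  (the 2.8 s → ~3.5 s first-week rise), applied as a multiplier on the
  lognormal scale. Whole-study raw means therefore sit slightly below
  3.44 s; recovery tests measure the plateau regime (relative day ≥ 7).
* **Daily intensity.** Each user draws a baseline λ_u from a lognormal
  with mean 250 puffs/day (sdlog 0.9), clamped to [5, 600] — the
  reported per-user range of 5 to >400 puffs/day with a stable cohort
  plateau near 250. Non-skipped days draw a zero-truncated negative
  binomial around λ_u × ramp multiplier, with a per-user dispersion
  drawn log-uniformly on [0.5, 10] to produce the wide spread of count
  CVs. Sporadic inactivity is modelled *solely* by `p_skip` (a
  non-skipped day always has ≥ 1 puff), so "p_skip = 0" means "active
  every day" deterministically. The ground truth records each user's
  expected active-day count μ/(1−p₀), the generator's own stated
  expectation under truncation.
* **Day-1 deflation.** The count ramp starts at δ = 120/250 on day 1
  and reaches 1 after 2 days (the "about 120 puffs on day 1, about 250
  after 1–2 days" pattern). The first active day's count is drawn as
  1 + NB(mean = δλ_u − 1), which makes its expectation *exactly* δλ_u
  while keeping support ≥ 1.
* **Usage mixture.** The joint (power, concentration) distribution is
  the published 12-cell power-by-bin cross-tabulation with each bin's
  mass split over its observed concentration values \{0\}, \{1, 3, 6\},
  \{10, 11\}, \{14, 18\} mg/mL in proportion to their whole-cohort
  prevalences. Two values (1 and 10 mg/mL) have no printed prevalence,
  only the statement that they are less used than their neighbours;
  they are fixed once at 2.5% and 2.0% of total puffs. By default each
  user mixes among a small personal subset of 1–3 (power, conc) pairs,
  one pair per day — the "users prefer certain power settings for
  certain concentrations" structure. Population shares still match the
  mixture in expectation, but the *effective* sample size for share
  checks is then the number of users, not puffs; the i.i.d. mode
  (`per_user_preference = FALSE`) exists for oracle tests where
  puff-level multinomial standard errors are exact.
* **Missingness.** Each puff's concentration is unrecorded with
  probability 0.41, independent of everything else (about 59% of
  observed puffs carried a concentration record). Real missingness is
  plausibly informative (users who never set up the app); that
  structure is *not* emulated.
* **Scale.** Use spans are drawn in whole weeks (mean ≈ 3.3 weeks,
  mode 3 — the trial length — with a tail of extensions to 8 weeks),
  start dates stagger uniformly over the window, and `p_skip = 0.33`.
  These two scale parameters were calibrated a priori from the
  closed-form expected total so a default 58-user/60-day run lands near
  the observed ~200,000 puffs; the plateau anchor (250/day), δ and the
  duration targets were never adjusted.
* **Reproducibility.** Each user's data comes from an RNG stream seeded
  by (seed, user index), so identical (config, seed) regenerate
  byte-identical files and *adding users never perturbs existing
  users*. Within-day timestamps are uniform over the day — inter-puff
  intervals are deliberately unstructured, as no interval statistics
  were reported; treat them as unvalidated.

### What a green test does and does not establish

The recovery suite shows that the pipeline, run on cohorts whose
generating process is known, returns the stated duration moments,
day-1 deflation, plateau intensity (each within 3 Monte-Carlo SE over
100 seeded replicates) and the ramp day (±1 day). That validates the
*estimators and aggregation semantics*, not the generator's fidelity to
real behaviour: the generator does not emulate inter-puff intervals,
weekday effects, informative missingness, concentration switching
within a day, or correlation between intensity and span. Conclusions
about real cohorts rest on the printed-table reproductions (exact) and
on the model assumptions above, not on the synthetic world.

## Numerical choices

* **Half-up rounding.** Printed tables use 2-decimal percentages with
  half-up rounding; `round_half_up()` implements it with a 1e-9 guard
  against binary representation error. One published prose share
  (high power, 46.43%) is a truncation of 46.4356 rather than a
  rounding; reproduction tests for prose shares therefore assert
  agreement to one unit in the last printed digit.
* **Ramp-day tolerance.** In recovery tests the "arrived at plateau"
  tolerance is 0.15, not 0.10: with 58 users, one relative day's cohort
  mean has a sampling SD near 45 puffs, and a ±25-puff band (10% of
  250) would flag noise as non-arrival on a sizeable fraction of
  plateau days regardless of the ramp. The band must exceed the
  day-level SE for ramp detection to measure the ramp; 0.15 leaves the
  *expected* series' ramp day unchanged (day 3).
* **Degenerate inputs.** Empty samples yield explicit empty summaries
  (n = 0), single-group eta-squared and zero-pooled-SD Cohen's d return
  `NA` with a warning, single-active-user days have undefined SE, and a
  perfectly flat plateau fits slope 0 without complaint.
* **Validation is collected, not fatal.** Real device logs are dirty;
  `read_puff_log()` rejects invalid rows with per-row reasons
  (attribute `rejections`) and loads the rest. A missing mandatory
  column, by contrast, is a format error and aborts.

## Known limitations

Concentration is self-reported and the emission model is theoretical —
anchored to one bench point, linear by assumption, and validated only
at that point. Puff-level effect sizes ignore within-user dependence.
The relative-day curves carry survivorship structure (later days are
averaged over the users who still use the device). None of these are
defects of the implementation; they are properties of the design being
implemented, and the sensitivity hooks (user-level aggregation,
zero-filled series, replaceable emission strategy) exist to probe them.
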