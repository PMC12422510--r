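---
title: "Estimating annual change in children's activity from pooled accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating annual change in children's activity from pooled accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actichange)
```

## The problem

Children's physical activity declines and sedentary time rises with age,
but quantifying *how fast*, and whether the rate differs across
demographic subgroups, requires repeated device-based measurement pooled
across many studies. Pooling brings two methodological obligations that
this package operationalises:

1. a **common processing protocol** turning heterogeneous epoch-level
   ActiGraph count files into comparable daily behaviour summaries, and
2. a **hierarchical model** respecting the data structure — time points
   nested in participants nested in studies — when estimating the
   per-year-of-age change in each behaviour.

Because pooled child accelerometry repositories are access-controlled,
the package treats a synthetic-data generator as a first-class module:
every stage is specified, tested and demonstrated against simulated
cohorts with known ground truth.

## Processing protocol

**Reintegration.** Source files may arrive at any epoch length dividing
60 s. `reintegrate()` sums counts over non-overlapping windows anchored at
the first target-aligned boundary; a leading misaligned fragment and a
trailing partial window are dropped rather than padded. Counts over
retained windows are conserved exactly.

**Non-wear.** A non-wear bout is a maximal window of zero-count epochs
spanning ≥60 min in which zero runs may be merged across non-zero
interruptions. Two readings of the "2 minutes of interruption" tolerance
circulate in the field: per interruption (each interruption ≤2 consecutive
non-zero minutes, unlimited interruptions) and per bout (all interruptions
of a bout total ≤2 min). `detect_nonwear()` implements both via
`tolerance_scope`, defaulting to per-interruption, which matches the
dominant Troiano-family implementations; no cap is placed on the magnitude
of interrupting counts. Bouts must begin and end on a zero epoch.
Detection runs over *all* epochs, including overnight, because physical
non-wear does not respect clock cut-offs; the overnight exclusion below
removes those minutes from wear accounting regardless. The implementation
(a run-length-merge scan) is verified in the test suite against a
brute-force enumeration of maximal qualifying windows on thousands of
random series.

**Overnight exclusion.** Epochs starting in the half-open window
[23:00, 06:00) are excluded to avoid scoring overnight sleep as sedentary
time. The half-open convention makes the 06:00 epoch unambiguous and
yields a maximum of 1020 analysable minutes per day. Timestamps are
interpreted as local clock time (stored in UTC), so daylight-saving
transitions cannot shift the window.

**Intensity classification.** Counts per minute are classified with
Evenson youth cut-points — sedentary ≤100 CPM, light 101–2294, MVPA
≥2295 — exhaustively and exclusively, so per-day intensity minutes sum
exactly to wear minutes. The cut-points are arguments
(`cutpoints_evenson()`), not constants, but alternative sets are
deliberately out of scope.

**Validity rules.** A day is valid with ≥600 wear minutes; a
participant-wave is valid with ≥2 valid weekdays plus ≥1 valid weekend
day (Saturday/Sunday). The weekday/weekend streams inherit the wave-level
gate: a wave that passes on all days contributes whatever stream days it
has, and a stream with zero valid days is omitted with a warning rather
than fabricated.

**Wear standardization.** Mean daily intensity minutes at each wave are
rescaled to the participant's pooled mean daily wear:
`std_I(w) = raw_I(w) / wear(w) × pooled_wear`. The pooled mean is taken
over the participant's valid days pooled across waves — i.e. weighted by
each wave's number of valid days — and computed separately per stream
(weekday standardization uses weekday wear), mirroring the protocol's
printed weekday example, which this reduces to under equal day counts.
Only waves passing the valid-file rule, and only their valid days,
contribute. Standardized minutes are left unrounded; presentation rounding
(1 d.p.) happens only in `tidy_report()`.

## Covariates

- **Decimal age** is elapsed days / 365.25 from birth to the first
  accelerometer day, falling back to an investigator-provided age and
  then to a proxy assessment date. 365.25 keeps the measure leap-safe.
- **Age group** dichotomises baseline age at the 10th birthday
  (child < 10 ≤ adolescent).
- **Season** is meteorological by month, with a per-study hemisphere
  switch (southern seasons shifted six months).
- **BMI z-scores** use the LMS transformation
  `z = ((x/M)^L − 1)/(L·S)` (log form at `L = 0`). Growth-reference
  L/M/S values are licensed external tables and are therefore injected by
  the caller; tests use a synthetic reference. Weight categories come
  from injected z cutoffs for the same reason (the test fixture uses
  −2 / +1.33).
- **Inclusion**: intervention-arm participants of intervention studies
  are dropped; each participant is capped at their first three waves; at
  least two valid waves are required. Maternal education and ethnicity
  are ingested as already-harmonised binary labels — recoding
  study-specific scales happens upstream of this package.

## The three-level model

`fit_three_level()` estimates, for each outcome (standardized min/day),

y = β₀ + β_age·age + β_sex·sex + β_season·season + u_study +
v_participant(study) + ε

with random intercepts at the study and participant-within-study levels,
by REML through `lme4::lmer`. Choices where the design was genuinely
open:

- **Random intercepts only.** A three-level intercept model is the
  minimal faithful reading of the design; a participant-level random age
  slope is available via `random_slope = TRUE` as a sensitivity analysis.
- **Wald inference.** 95% CIs are `β ± 1.96·SE` and p-values come from
  the normal approximation. With hundreds of participants the difference
  from profile or Kenward-Roger intervals is immaterial, and Wald is what
  a β (95% CI) table convention implies.
- **Season enters as three dummies** (reference spring); the reference
  choice does not affect the age coefficient.
- **Listwise deletion** per model for missing covariates, with the count
  of dropped rows reported on the fit object.
- **Degenerate designs raise** (single study, no repeated measurements,
  one-level moderator) instead of returning silently misleading output;
  singular variance estimates are flagged on the result, not hidden.

Stratified fits (`fit_stratified()`) refit independently per stratum and
report skipped strata. Effect modification (`fit_interaction()`) adds a
binary moderator and its age interaction; the moderator-level slope is
the reference slope plus the interaction (`moderated_slopes()`). The
day-of-week moderator is fit on weekday and weekend wave rows stacked
long with a shared participant intercept — the only design consistent
with reporting a day main effect alongside an age×day interaction.

## The synthetic cohort generator

`simulate_cohort()` draws a study/participant hierarchy and wave-level
outcomes directly from the model above, so the estimator is tested
against its own data-generating process; `render_traces()` additionally
materialises epoch-level count days (overnight zeros, injected non-wear
bouts with optional ≤2-min interruptions, worn counts sampled within
intensity intervals) so the processing chain can be tested end to end.
Two tiers exist because model tests should not pay trace-rendering costs.

Defaults describe a pooled child cohort: 5 studies × 100 participants,
2–3 waves, baseline age 10.6 (SD 2.1, range 4.1–15.8) years, first
follow-up after 2.5 (1.4) years and second after 4.3 (1.1) cumulative
years; 44.5% boys, 89.2% white, 26.9% low/mid maternal education.
Outcome levels at the reference age (sedentary 355.7, LPA 388.5, MVPA
55.9 min/day) sum to a ~800-min daily wear budget, and default age
slopes are +24.9, −22.4 and −2.5 min/day/year. The male reference
intercept absorbs the sex-mix term so that the *population* mean at the
reference age equals the stated level.

**Truncation and variance calibration.** Outcomes are truncated into
[0, wear budget], and truncation events are counted in the truth record.
Heavy truncation would bend the linear data-generating process and bias
slope-recovery tests, so default variance components are calibrated so
that every outcome's expected value stays ≥3 total SDs from both bounds
across the design envelope (both sexes, youngest baseline age to oldest
baseline plus the mean cumulative follow-up). For MVPA — a small, floor-
adjacent outcome, especially for older girls — this forces a marginal SD
(~5 min/day) well below what real cohorts show (~25–30): the generator
deliberately trades marginal-variance realism for exact linearity.
`sim_config()` warns when a configuration violates the 3-SD rule.
Consequently, passing recovery tests demonstrate that the estimation
machinery is correct and unbiased under the declared hierarchy; they do
not demonstrate robustness to skewed, floor-censored real MVPA
distributions, to informative wear patterns, or to missingness.

Other respects in which the generator is simpler than real data: no
diurnal activity rhythm and no autocorrelation in count traces (counts
are drawn independently within intensity intervals, since classification
depends only on the interval), no device noise, no seasonal confounding
with age, and wave-level wear varies independently of behaviour.

**Exact round trip.** `render_traces()` makes each day satisfy
`sed + lpa + mvpa + non-wear = 1020` and forces worn epochs adjacent to
any zero block to be non-zero, so injected bouts are recovered exactly
and the render → flag → summarize chain reproduces the day's targets to
the minute. A remainder between 0 and 60 minutes cannot form a legal
bout and is rejected as infeasible.

## Recovery studies and problem sizes

`recovery_study()` repeats simulate-and-refit over seeded replicates and
`summarize_recovery()` reports the mean estimate, its Monte-Carlo
standard error, the deviation from truth in MC-SE units, and 95% CI
coverage. The package's standard study size — 50 replicates of
5 studies × 100 participants × 2–3 waves — gives Monte-Carlo standard
errors of roughly 0.06 min/day/year for the sedentary slope and 0.005
for MVPA, sharp enough to detect biases far smaller than any
scientifically relevant effect while keeping a full run in the tens of
seconds. `scripts/acceptance.R` runs exactly this design with the
published annual-change estimates as generating truths.

## Numerical conventions and degenerate inputs

- Timestamp gaps in input files are a hard error by default
  (`gap_action = "zero_fill"` opts into explicit zero filling), because
  silent zero-fill manufactures non-wear.
- Non-monotone timestamps, missing counts columns and unsupported epoch
  lengths raise typed format errors.
- `detect_nonwear()` requires `min_bout ≥ tolerance + 2` (a shorter bout
  could not bracket an interruption with zeros).
- Day boundaries use the calendar date of the epoch start.
- A wave with zero mean wear cannot be standardized (undefined
  proportion) and raises.
- `change_summary()` sorts waves internally, so reversed input order can
  never silently flip baseline and follow-up; fewer than two valid waves
  raises.
- Reported tables round to 1 d.p.; full-precision columns are kept
  alongside the formatted strings.

## Known limitations

- Bout-level MVPA metrics, vector-magnitude axes, raw (30 Hz) signal
  processing, sleep estimation and imputation of missing days are out of
  scope.
- Real growth-reference tables are not shipped; all weight-category
  results depend on caller-supplied cutoffs.
- Wald intervals can undercover slightly in designs with very few
  studies; the recovery tests run at 5 studies, where coverage is
  nominal.
- The generator's fidelity limits are described above; conclusions about
  estimator behaviour under gross model misspecification require a
  different simulation design.
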