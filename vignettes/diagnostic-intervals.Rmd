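---
title: "Measuring diagnostic-interval inequities from administrative claims: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diagnostic-interval inequities from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxinterval)
```

This vignette is the package's account of its science: the measurement
model, every tunable parameter with its default and rationale, what the
synthetic-data generator does and does not emulate, the numerical
conventions, and the design decisions that were genuinely open.

## 1. The measurement problem

Administrative claims record *when* people touch the healthcare system and
*what* was coded, but not why a test was ordered or when symptoms began. The
diagnostic interval — days from the earliest cancer-related healthcare
contact ("first contact") to the diagnosis date — is a measurable proxy for
time-to-diagnosis that can be constructed entirely from claims. The package
estimates how this interval differs by severe psychiatric illness (SPI)
status, a population with well-documented inequities in cancer detection,
where mechanisms such as diagnostic overshadowing (attributing physical
complaints to the psychiatric condition) plausibly delay workup.

Three classification problems precede any inference:

* **Exposure.** SPI status is assessed over the window from 1825 days (5
  years) to 183 days (6 months) before diagnosis, both endpoints inclusive.
  The 6-month blackout exists because mental-health care often intensifies
  during an undiagnosed illness; counting those contacts would make the
  exposure a consequence of the outcome. The hierarchy is: *inpatient* (at
  least one hospitalization with an eligible SPI code) over *outpatient* (at
  least two emergency-department or psychiatrist visits with eligible
  codes). Mental-health contact in the window that meets neither rule — a
  single qualifying visit, family-physician-only care, or non-SPI
  mental-health codes — is an *inconclusive history*: such persons are
  neither clearly exposed nor clearly unexposed and are excluded rather than
  misclassified.
* **First contact.** Constructed empirically (Section 2).
* **Detection route.** "No symptom recorded" — a non-emergent gFOBT or
  lower-GI endoscopy on the first contact date with no co-recorded and no
  previously recorded symptom codes — serves as a surrogate for
  screen-initiated detection; everyone else is symptomatic. Symptomatic
  diagnoses are further classified by workup procedures (colonoscopy only /
  colonoscopy + imaging / imaging only / neither) crossed with emergency
  presentation on the diagnosis date: eight pathways.

## 2. The empirical interval algorithm

**Encounter-type selection.** For each encounter-type group (a config
dictionary maps diagnosis codes to groups), pooled cohort event rates are
computed in the pre-diagnostic window (days 0–90 before diagnosis) and a
control window (days 720–810). All "month" windows use fixed 30-day months,
so both windows are 91 days wide and the rates are directly comparable. A
group is *selected* (treated as cancer-related) when its frequency ratio —
pre-diagnostic rate over control rate — is at least 1.2. Only persons with
at least 810 days of pre-diagnosis coverage contribute to rate estimation.

Division by zero is resolved by an explicit rule: a group with zero control
events is selected when it has at least 5 pre-diagnostic events (evidence of
a genuinely new encounter type); otherwise the reported ratio uses a +0.5
continuity correction on both counts. Whether rates pool raw encounter
counts or person-level any-encounter indicators is configurable
(`unit = "count"` is the default).

**Lookback windows.** For each selected group the package builds the
cohort-level weekly encounter-count series for weeks 1–104 before diagnosis
(week *w* covers days 7(w−1) to 7w−1, so week 1 includes the diagnosis
day). Control limits come from a Shewhart-style individuals chart: mean +
3·SD of the counts over the control weeks (default weeks 96–104; at least 8
control weeks are required, otherwise the fit errors). The lookback is 7·w*
days where w* is the largest week such that *every* week from w* down to 1
exceeds the upper limit — the unbroken elevated run ending at diagnosis.
Isolated spikes beyond the run are ignored; if week 1 itself is not elevated
the lookback defaults to 90 days. The lookback is capped at 730 days so it
can never reach into its own control period. The run rule, limit type and
control weeks are explicit, configurable choices: the literature this style
of algorithm comes from names "statistical control charts" without fixing
the chart, and the run-ending-at-diagnosis rule is the variant that directly
answers "since when has contact been elevated?".

**First contact and referral.** A person's candidate encounters are those
whose group is selected and whose date falls within that group's lookback
before diagnosis (endpoints inclusive). The first contact is the earliest
candidate; ties on the same day prefer non-procedure encounters (so a
same-day referral visit outranks the procedure it led to), then encounter
id for determinism. If the first contact is a procedure with a recorded
referring provider, the start date moves back to the *latest* visit with
that provider in the preceding 365 days, when one exists — the most recent
plausible referral, a deliberate tie-break among "previous visits". The
interval is the day difference from the resolved start date to diagnosis
(same day = 0). Persons with no candidate encounter have no identifiable
first contact and leave the cohort (recorded in the exclusion ledger).

One property worth stating: enlarging a group's lookback can only move the
first contact earlier or leave it unchanged. The *referral-resolved*
interval is not monotone in the lookback, because an earlier non-procedure
first contact can displace a procedure whose referral lookback had reached
back further still. The tests assert monotonicity of the first contact in
general and of the interval on referral-free histories.

## 3. Quantile regression

Interval distributions are strongly right-skewed, so effects are estimated
at the 50th and 90th percentiles by minimizing the check loss
$\sum_i \rho_\tau(y_i - x_i'\beta)$, $\rho_\tau(u) = u(\tau - 1[u<0])$,
solved exactly as a linear program (the Barrodale–Roberts simplex from
`quantreg` is the solver behind `fit_quantile_regression()`).

**Tie-break and the median-difference identity.** When a subgroup count
times τ is an integer the minimizer is set-valued. The package fits at
$\tau_{\text{eff}} = \tau - \min(\tau, 1-\tau)\cdot 10^{-3}/n$: small enough
never to cross a quantile breakpoint for any τ = p/q with q ≤ 1000 at any
subgroup size, large enough to steer the simplex to the *lower* vertex of
the optimal set. Descriptive percentiles use the same lower-interpolation
(type 1) convention (`quantile_lower()`). Consequence, verified exactly in
the tests: unadjusted group-dummy fits reproduce the descriptive table —
each coefficient is a difference of group quantiles and the intercept is
the reference group's quantile. This is the internal-consistency identity
that links a published descriptive table to its published unadjusted
quantile regression.

**Confidence intervals.** Person-level resampling bootstrap, 500 replicates
by default, percentile intervals, optionally widened to contain the point
estimate so the componentwise bracket always holds. Replicate fits use the
Frisch–Newton interior-point solver (vertex choice is immaterial inside a
resampling distribution; it is roughly twice as fast at n ≈ 5000). A
degenerate stratum with all-identical responses returns zero-width
intervals with a warning rather than failing. Rank-inversion intervals are
not implemented: for multi-covariate designs they would need a substantial
additional inference machinery for an alternative the headline analysis
never uses; the bootstrap is the default and only method.

**Model set.** Analyses are a priori stratified by symptom status, because
screen-type and symptomatic detection follow conceptually different
pathways. Per stratum and τ: an unadjusted model (exposure dummies,
reference = no SPI) and an adjusted model adding age (centered at the
stratum median), sex (female indicator), urban residence (rural is the
reference), and diagnosis year (centered at the last study year) — so the
adjusted intercept is interpretable as the interval for an unexposed rural
male of median age diagnosed in the final year. Comorbidity and income are
*never* adjusted for: under the effect-decomposition view of health-equity
confounder selection they lie on the causal pathway from exposure to
interval (and are unfairly distributed with respect to exposure), so
conditioning on them would absorb part of the inequity being measured. An
optional sex-by-exposure interaction model probes effect modification.
Strata smaller than `min_stratum_n` (default 50) are skipped with a
warning. No multiplicity adjustment is applied anywhere.

## 4. The synthetic-claims generator

Real linked claims holdings are not publicly sharable, so the package
generates synthetic linked tables with known ground truth
(`simulate_claims()`), parameterized by `sim_config()`. The generator's job
is *calibration*, not demography: it produces data on which the analytic
chain's recovery properties can be measured against truth.

The generating model:

* Each person gets a diagnosis date (uniform over 2007–2019), an exposure
  group from `spi_mix` (default 95% none / 2% outpatient / 1% inpatient /
  2% inconclusive), demographics drawn per group from `covariate_spec`
  (defaults follow the published cohort: exposed groups younger, more
  often female, lower income, higher comorbidity), and 2200 days of
  coverage before diagnosis unless injected into an exclusion arm.
* A true interval is drawn per group — log-normal parameterized by median
  and log-SD, matching the right-skew of real intervals — and the true
  onset date is diagnosis minus interval. Defaults: symptomatic medians
  106 / 147 / 160 days (none / outpatient / inpatient), log-SD 0.6;
  no-symptom-pathway medians 69 / 67 / 62, log-SD 0.5.
* Encounters arrive as piecewise-constant Poisson processes per
  encounter-type group: background rate over the whole coverage window,
  multiplied by `signal_rate_multipliers` between onset and diagnosis. A
  presenting encounter is always placed on the onset date: a symptom-coded
  GI visit for symptomatic persons, a non-emergent gFOBT (70%) or
  colonoscopy (30%) for no-symptom persons, optionally carrying a referring
  provider whose visit 7–60 days earlier is also emitted.
* Workup procedures (colonoscopy with probability 0.62, imaging 0.58),
  an emergency visit on the diagnosis date (34% of symptomatic persons),
  and group-appropriate mental-health encounter streams realize the true
  pathway and exposure. Unexposed persons receive occasional historical
  psychiatric visits strictly before the exposure window opens; exposed
  persons receive low-rate continuation visits during the blackout, so
  mental-health contact behaves as a persistent process rather than a
  spurious pre-diagnosis signal.

**Why these signal rates.** The defaults — background 0.0005/person-week
for the three cancer-workup groups with multipliers 25 / 20 / 15
(endoscopy / imaging / GI-physician) — come from a design analysis, not
from fitting any dataset. Two error modes trade off against each other
through the fitted lookback L: intervals longer than L are truncated
(biasing the computed median down), and background encounters of selected
types in the window before onset are picked up as false first contacts
(biasing it up, at rate ≈ combined background rate × (L − true interval)).
With the default rates the combined background intensity of selected groups
is 0.0015/week, the chart extends L to roughly the 93rd–97th percentile of
the onset distribution, and both error modes stay at a few days on a 106-day
median — small enough that interval-recovery experiments measure the
algorithm rather than the generator. Raising background rates toward
clinically realistic levels for, say, abdominal imaging would be more
demographically faithful and strictly harder for the method; users can do
exactly that through the config.

**What the generator does not emulate.** Real code vocabularies (codes are
synthetic labels mapped through the dictionary), visit clustering and
weekday/seasonal structure, regional provider supply, and — importantly —
the full dispersion of real intervals: published interquartile ranges imply
a log-SD above 1, while the default 0.6 gives a sharper onset. Passing
recovery tests on this generator therefore shows the chain is correct and
well-calibrated *under a sharp-onset process*; it does not certify accuracy
on data with heavier interval tails, more background noise in workup codes,
or symptom under-recording. The primary-care and "other care" groups default
to multiplier 1.0 — cancer-related primary-care contact is represented by
GI-symptom-coded visits (grouping is by diagnosis code, not provider type) —
so the frequency-ratio step always faces genuine negative controls.

**Determinism.** One seed drives a single RNG stream through fully
vectorized generation: identical config + seed give identical tables, and
the pipeline manifest's file digests are reproducible end to end.

## 5. Numerical conventions and degenerate inputs

* Dates are ISO-8601 on disk, integer days internally; month = 30 days,
  year = 365 days for window definitions; same-day differences are 0.
* All descriptive percentiles are type-1 (lower interpolation); the
  regression tie-break matches them (Section 3).
* Exposure window: [diagnosis − 1825, diagnosis − 183], both endpoints
  inclusive. Exactly two years of coverage is sufficient (the exclusion is
  strictly-less-than). Two qualifying outpatient visits may share a date
  (configurable via `distinct_dates`): the data record distinct claims, and
  requiring distinct dates would silently discount same-day ED-plus-
  psychiatrist contact.
* The prior-symptom scan for the no-symptom classification is unbounded
  (the full available record), the conservative reading of "no previously
  recorded symptoms"; a lookback-horizon variant would only reclassify
  toward no-symptom.
* Collinear designs error, naming the dependent columns; strata with an
  empty exposure level drop that dummy; empty groups in descriptive tables
  report zero counts with missing percentiles.
* Validation experiments in the test suite run at n = 5000 persons with
  200 replicates for estimator recovery, 50 seeds for lookback recovery,
  20 seeds for end-to-end median recovery, and 2000 simulations for test
  calibration — sizes chosen so Monte-Carlo error is well inside the
  asserted tolerances.

## 6. Known limitations

* The interval algorithm measures recorded contact, not symptom onset; if
  early symptoms of exposed persons are differentially misattributed (the
  overshadowing mechanism itself), first contacts are differentially missed
  and the measured inequity is an underestimate.
* "No symptom recorded" cannot be validated against true screening intent
  from claims alone.
* The control-chart reconstruction (limit type, control weeks, run rule) is
  one faithful-in-spirit member of a family of defensible choices; all are
  exposed as parameters rather than frozen.
* Exposure misclassification is asymmetric by design (hierarchy +
  inconclusive exclusion); the generator reproduces this structure but real
  coding behavior may not be as clean.
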