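---
title: "Compositional analysis of 24-hour time use: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour time use: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codatime)
```

## The problem

Time-use epidemiology treats the 24-hour day as a closed budget: minutes
per behaviour set sum to 1440, so behaviours cannot be modelled as
independent exposures. Raw minutes entered jointly in a regression are
perfectly collinear; entered separately they smuggle in an unstated
assumption about where the extra time comes from. Compositional data
analysis resolves this by modelling the *relative* allocation. This
vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## Diary model and validity filtering

A person-day is 144 ten-minute slots from 04:00 to 04:00 the next day;
slot `k` (0-based) covers `[04:00 + 10k, 04:00 + 10(k+1))`. The day starts
at 04:00 because that is the conventional low point of activity, but it
means "sleep" is all sleep inside the window — naps included, overnight
sleep possibly split. Slot activity codes are recoded through a total
mapping into six mutually exclusive behaviour sets on weekdays (sleep,
physical activity, electronic media, school-related, hobbies/socialising,
domestic/personal care/work). The shipped default mapping assigns
plausible codes for the common diary categories to these sets; real
instruments differ, so the mapping is fully user-overridable via a
two-column CSV (`activity_code, behaviour_set`) — configurability isolates
this instrument-specific detail from the analysis.

A diary is excluded as an unreliable account of a complete day if any slot
is blank (`missing_data`), if it records no sleep (`no_sleep`), or no
domestic/personal-care activity (`no_domestic`) — everyone dresses and
eats, so a day without any such entry is implausible rather than unusual.
The reasons are assigned in that fixed priority order so removal counts
are reproducible. `build_analytic_sample()` filters complete covariates →
diary validity → non-missing outcome, in that order, and logs the count
removed at each step; the log is part of the pipeline's output because
participant-flow accounting is itself a result worth reproducing.

Weekend days use a four-part composition (sleep, media, hobbies,
domestic): too little weekend time is spent in physical activity and
school to support meaningful time reallocations. The weekend composition
is the *subcomposition* of the six recoded parts, re-closed to 1440.
Validation is applied before taking the subcomposition — dropping parts
first could mask a no-sleep day. Each participant contributes at most one
weekday and one weekend diary; duplicates are a format error rather than
silently averaged.

## Compositional core

* **Closure** rescales non-negative parts to sum to 1440 (the "linear
  adjustment" used when reporting compositional means).
* **Multiplicative zero replacement**: log-ratios cannot absorb zeros, and
  10-minute diaries produce genuine zeros in short behaviours. Each zero
  part is set to `impute` minutes and the non-zero parts are scaled by
  `(1440 − impute·z)/1440` (z = number of zeros), which preserves the
  ratios among non-zero parts exactly and the 1440 total. The default
  `impute = 5` is half the slot resolution — the centre of the plausible
  range for a behaviour recorded as zero at 10-minute granularity; any
  value in (0, 10) is accepted and sensitivity to it can be explored via
  the `impute_minutes` pipeline option. Values ≥ 10 are rejected: an
  imputed duration at or above the slot size is no longer "below detection".
* **ILR pivot coordinates**: the default basis is the sequential binary
  partition that peels parts off in their given order, coordinate `j`
  contrasting part `j` against all later parts with normalising constant
  `sqrt((D−j)/(D−j+1))`. No substantive claim hangs on this choice:
  substitution estimates are invariant to the pivot order (asserted to
  1e-9 in the test suite), because any two ILR bases differ by an
  orthogonal rotation that OLS absorbs. Natural logarithms throughout.
* **Compositional mean**: part-wise geometric mean, closed to 1440.

Numerical tolerances are fixed at 1e-6 for closure checks, 1e-9 for the
ILR round-trip, and 1e-10 for basis orthonormality; `ilr_inverse()`
subtracts the row maximum on the log scale before exponentiating so that
extreme coordinates cannot overflow (closure is invariant to that shift).

## Outcome model and joint test

`fit_outcome_model()` runs OLS of the outcome on the D−1 ILR coordinates
plus treatment-coded covariate dummies (sex, six-category ethnicity,
free-school-meal eligibility, six-level maternal education). Reference
categories default to the modal category of each covariate — the
conventional epidemiological choice when no category is a natural control
— and are configurable. Age is not in the default adjustment set (it can
be added as a covariate column); complete-case analysis only, matching the
removal-log design — no imputation is attempted. A rank-deficient design
fails loudly, naming the aliased columns.

Whether "the composition is associated with the outcome" is a joint
statement about all D−1 coordinates, so it is tested with a nested-model F
test of the full model against the covariates-only model (`df1 = D−1`) —
the standard choice for a block of regressors; with a single coordinate it
reduces to the squared t statistic. Descriptive tables report n (%) for
categoricals and mean (SD) for continuous columns; included-vs-excluded
comparisons use Welch t tests and Pearson chi-square without continuity
correction (the large-sample form; both choices are stated because
conventions differ).

## Isotemporal substitution

`reallocate()` moves Δ minutes between two named parts, leaving the others
untouched. The predicted outcome difference uses the contrast
`a = ilr(x*) − ilr(x₀)`: covariate terms cancel exactly, so
`β̂ = aᵀβ̂_ilr` with Wald standard error from the ILR block of the
coefficient covariance and a t-based 95% CI (residual df). Wald-on-the-
contrast is the standard delta-method choice for this class of model; a
bootstrap would relax the homoscedastic-OLS assumption at two orders of
magnitude more computation and is out of scope.

Design points:

* **Base composition** defaults to the compositional mean of the analytic
  sample — substitution effects are nonlinear in the base, and the mean
  day is the natural reporting point; any strictly positive base can be
  supplied instead.
* **Feasibility** requires substituted parts to stay strictly positive
  (ILR needs positivity); infeasible pairs are flagged in tables, not
  fatal. This is why short behaviours are dropped from the weekend
  composition rather than reallocated.
* **Asymmetry is expected**: `β(add A, remove B)` need not equal
  `−β(add B, remove A)` because the log-ratio contrast is nonlinear in Δ;
  the implementation deliberately does not symmetrise.
* Defaults: Δ = 20 min with a ±20-minute grid on weekdays, Δ = 30 with
  ±30 at weekends, both in 5-minute steps. Reports round to 2 decimal
  places with a significance flag (95% CI excluding zero); CSVs keep full
  precision.

## Synthetic cohort generator

The generator defines the operating conditions for all recovery and
calibration tests; its defaults are fixed once and are not tuned to test
outcomes.

* **Compositions** are logistic-normal: ILR vectors drawn from a Gaussian
  centred at the ILR of a target geometric-mean day (weekday default
  897/23/143/50/61/266 minutes for sleep/PA/media/school/hobbies/domestic;
  weekend 852/202/114/272), inverted to minutes, and rounded to the
  10-minute grid by largest-remainder apportionment (deterministic
  tie-break by part order) so rows still sum to exactly 1440. A
  logistic-normal rather than Dirichlet law makes the generating model
  identical in form to the analysis model, so noiseless recovery is exact
  rather than approximate. Zeros arise mechanically from rounding —
  no zero-inflation mixture — mirroring how diary zeros arise; with the
  default spread the shortest set (physical activity) rounds to zero in a
  few percent of days.
* **ILR covariance** defaults to `0.5·I` (coordinate SD ≈ 0.7). This gives
  minute-scale dispersion broadly comparable to observed diary data, where
  arithmetic means of short behaviours exceed their geometric means
  severalfold — a heavily right-skewed allocation — while keeping zero
  rates low enough that multiplicative replacement stays a small
  perturbation.
* **Covariates** are drawn independently per participant from
  Table-1-style frequencies (54% female, 80% White British, 7% FSM, modal
  maternal education NVQ4/5).
* **Outcome**: `y = 56 + zᵀβ_ilr + cᵀβ_cov + ε`, `ε ~ N(0, 15²)`, default
  `β_ilr = (−3, 2, 1, −1, 1.5)` — effect sizes that put 20-minute
  substitution effects on the sub-point scale typical of this literature —
  and covariate effects of a few points (e.g. FSM −8). The outcome is
  generated from the *zero-replaced* composition, so the analysis model is
  correctly specified and coverage tests are exact; clipping to [0, 90] is
  off by default because it breaks that linearity (enabling it is flagged).
* **Diary expansion** anchors sleep at the start and end of the 04:00
  window (split in half) with the other sets in randomised contiguous
  blocks between — enough structure for the recode∘expand round-trip to be
  exact, with no pretence of realistic circadian sequencing. Corruption
  switches (`missing_slot_rate`, `zero_sleep_rate`) exist solely to
  exercise the validity filters.
* Weekday and weekend cohorts are generated independently; the
  within-person correlation between a participant's weekday and weekend
  days is not modelled (no published value to emulate), so paired
  weekday–weekend analyses are outside what the generator can validate.

What passing tests show — and do not. The synthetic cohort has exactly the
correlation structure the analysis assumes: no measurement error beyond
grid rounding, no informative missingness, no residual confounding, no
day-to-day variation within person. Green recovery and coverage tests
therefore validate the *machinery* (transforms, fitting, contrasts,
accounting), not the causal or measurement assumptions of any real diary
study.

## Simulation sizes and determinism

Every stochastic routine takes an explicit integer seed (defaulting to the
truth object's), and cohort simulation derives per-stage seeds from it, so
identical truth + seed gives byte-identical cohorts and pipeline reruns
give byte-identical CSVs. The packaged calibration checks use 500
replicates of n = 2000 for confidence-interval coverage (binomial SE
≈ 1% at 95%) and 1000 null simulations of n = 500 for the type-I error of
the joint F test (SE ≈ 0.7% at 5%) — sizes chosen to make the Monte-Carlo
error small relative to the tolerance being asserted; module tests use
smaller versions of the same checks with proportionally wider bands.

## Known limitations

* Single-diary-day design: no multi-day averaging or within-person
  variance modelling.
* One activity per slot (no primary/secondary coding), no diary-mode
  effects.
* No survey weighting or attrition modelling; complete-case only.
* Zero replacement is the simple multiplicative form; Bayesian-
  multiplicative and lrEM alternatives are deliberately out of scope.
* Wald CIs assume homoscedastic OLS errors; no robust or bootstrap
  variants.
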