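---
title: "Estimating emergency department crowding from staff workload: the SEAL score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating emergency department crowding from staff workload: the SEAL score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealscore)
```

## The problem and the model

Emergency department (ED) crowding degrades care quality, but "crowding"
has no agreed operational definition. The SEAL approach treats the staff's
own perception of workload — a 1–6 rating, 6 being the highest — as the
reference standard, and estimates it from quantities any computerized
patient log system already records. Fourteen candidate variables, each a
size-independent ratio or mean measured over the hour preceding an
assessment, are regressed on the mean staff workload rating; the variables
surviving a p < 0.05 filter form the operational score:

$$
\mathrm{SEAL} = 1.589 + 14.73\,\mathrm{PatientHours}
  + 1.80\,\mathrm{HighPriority} + 1.39\,\mathrm{AwaitingMD}
  - 1.10\,\mathrm{Occupancy},
$$

clipped to the 1–6 scale. `seal_2013()` ships this model as an immutable
constant; `seal_score()` evaluates it; the rest of the package reproduces
the pipeline that produced it — variable extraction, schedule
randomization, regression, reduction and rater-agreement validation —
plus a discrete-event simulator that makes the whole chain testable with
no hospital data.

The negative Occupancy coefficient is not a typo: at fixed patient-hours,
higher occupancy means quicker turnover per patient, which the staff
experience as *less* workload.

## Window arithmetic

All numerators are measured over the trailing hour `[t − 1h, t)`. Windows
are half-open: a patient departing exactly at the window start contributes
nothing, so adjacent windows partition time exactly. Timestamps are naive
local times at minute resolution (daylight-saving transitions are out of
scope — a documented limitation, since the collection period in practice
avoids them). An open departure means the patient is still in the ED; all
duration computations truncate open intervals at the window end.

"Patients in the ED during the prior hour" is the count of *distinct*
patients with positive presence overlap — not a point-in-time census and
not a time-average. Two consequences matter for coefficient magnitudes:
patient-hours accrue at most one hour per patient per window (so
`patient_hours` of a busy mid-size ED sits around 0.1–0.3, and
14.73 × that contributes 1.5–4.4 score points, consistent with observed
mean scores near 3); and every ratio stays a pure number, which is what
makes the score comparable across EDs of different sizes. The package
verifies this size-invariance exactly: replicating every visit and staff
identity k-fold while scaling beds and daily visits by k leaves all 14
variables unchanged.

Two definitional choices were genuinely open:

* **Awaiting MD.** Waiting is the overlap of `[arrival, first physician
  contact)` with the window; a never-seen patient accrues waiting until the
  window end, *not* truncated at departure. Whether the source log system
  instead stored total historical waiting of currently-waiting patients is
  unknowable from the published description; the window-accrued definition
  keeps the variable bounded by 1 hour per patient and consistent with the
  other window-measured numerators.
* **Occupancy rate vs Occupancy.** The published variable list
  distinguishes "registered patients" from "patients in the ED" without
  defining registration. The data model carries a `registration` timestamp
  defaulting to arrival, so the two occupancies coincide unless a log
  system supplies a distinct registration interval. (When they coincide,
  the full 14-variable design is rank-deficient; the `derive` command
  drops exactly dependent columns by QR pivoting and says so —
  `average_volume` is likewise proportional to `occupancy` by
  construction.)

Empty windows define every patient-denominated mean and ratio as 0, so
continuous monitoring never produces an undefined score; an empty ED
scores the clipped intercept, 1.589.

## Scoring

The affine form is unbounded, while the scale is declared 1–6; the package
clips by default and exposes the flag (`seal_2013(clip = FALSE)` is the
raw form, which is also the simulator's noise-free ground truth). The
published coefficients enter to the printed precision; "high priority"
means RETTS priorities {1, 2} exactly.

## Derivation pipeline

`fit_linear_model()` is ordinary least squares (`lm`) with intercept;
p-values and 95% CIs are the standard t-based ones. `univariate_screen()`
and `collinearity_check()` mirror the pre-regression checks; collinearity
reporting is advisory only (threshold |r| ≥ 0.8 by default, configurable)
because no automatic exclusion was part of the procedure.
`select_reduced()` retains variables with p strictly below 0.05 in a
single pass — fit once, filter once, refit once; no stepwise search — and
a boundary p-value of exactly 0.05 is excluded. Applied to the published
coefficient table (`published_full_fit()`), the filter retains exactly
High priority, Awaiting MD, Patient hours and Occupancy. Fits are on
complete cases; rank deficiency is an error naming the offending columns
rather than a silent drop.

## Assessment schedule

Collection time points are drawn from the daily slots 04:00, 08:00,
12:00, 16:00, 20:00 and 24:00 (materialized as midnight of the next day),
sampling (day, slot) pairs without replacement with the night slots at
half weight — normalized slot probabilities (0.1, 0.2, 0.2, 0.2, 0.2,
0.1). Whether the original randomization enforced the half frequency
exactly or in expectation is not stated; weighted sampling is the default
reading, and `quota = TRUE` provides the exact-count alternative. Note
that successive without-replacement sampling only matches the weights
when the draw is a small fraction of the slot supply; the package's
frequency tests therefore pool many schedules over long periods.
Validation-mode schedules drop 04:00 and replace 24:00 with 23:00.

## The synthetic ED

`simulate_ed_log()` is a small discrete-event generator: nonhomogeneous
Poisson arrivals by thinning against a 24-hour diurnal profile;
multinomial RETTS priorities; log-normal door-to-physician delay (a delay
exceeding the stay leaves the patient never seen); log-normal
length-of-stay lengthening with acuity; Bernoulli admission followed by a
log-normal boarding interval; one physician and one nurse assigned
round-robin from fixed pools for the whole stay. One seed drives a run;
assessment noise uses its own sub-seed so logs and ratings can be varied
independently.

Defaults emulate a mid-size Swedish ED and were fixed once from
steady-state arithmetic — about 7 arrivals/hour at the daily mean, mean
length of stay ≈ 3 h, admission probability 0.30, boarding ≈ 1.8 h — so
that hourly mean scores land in the 3.0–3.5 band reported for the study
EDs (the best-bedded ED config runs slightly hot, ≈ 3.8, because its low
occupancy weakens the negative term). `simulate_assessments()` turns the
clip-free model value at each time point into per-rater scores by adding
Gaussian noise (default sd 0.5 score units) and, optionally, rounding to
the integer questionnaire scale.

What the simulator does *not* emulate: bed-blocking feedback between
boarding and arrivals, staff rosters (staffing is a per-visit
responsibility proxy, as in the source system), priority upgrades during
a stay, or any correlation structure between rater errors. Passing tests
on simulated data therefore demonstrate that the pipeline recovers a
known generating model under realistic marginal distributions — not that
the published coefficients are correct for any particular real ED.

For coefficient-recovery experiments the event simulator is deliberately
bypassed: `sample_variable_vectors()` draws the four model variables
independently and uniformly over their plausible operating ranges
(patient_hours 0–0.3, high_priority 0–0.5, awaiting_md 0–1, occupancy
0–1.5), because the event dynamics couple patient_hours with occupancy
and the induced collinearity would inflate recovery variance for reasons
unrelated to the fitting code.

## Validation statistics

`combine_assessments()` implements the combination rule: head mode
averages the head nurse and head physician, uses the available value when
one is missing, and excludes the time point when both are; all-staff mode
averages every rater. `staff_agreement()` reports the squared Pearson
correlation between head-staff and remaining-staff combined scores and a
paired two-sided t-test of nurse vs physician means on common time points
(the original analysis says only "T-Test"; paired on shared time points
is the natural reading, and all-zero differences yield an `NA` p-value
rather than a spurious one). Significance convention is p < 0.05 with a
CI excluding zero, and no multiple-testing correction anywhere — matching
the original analysis.

## Numerical and testing choices

Interval arithmetic is validated against a brute-force minute-grid
occupancy oracle (tolerance one minute per patient; with minute-aligned
timestamps the two agree to rounding error). Scoring is validated against
an independently coded dot product. Recovery tests refit on 2,000
sampler draws with noise sd 0.05 and check calibration of the
standardized errors across 20 replicates rather than a single 3-SE draw,
which would fail by chance about once in a hundred seeds. Simulation
sizes in the test suite (tens to a few hundred simulated hours, 100-log
oracle sweeps) were chosen as the smallest runs that make the binomial
and Poisson 3-SE checks meaningful.

## Limitations

The score's cut-offs for "crowded" are deliberately not modelled — they
were never established. Model transfer to EDs using triage systems other
than RETTS is untested. The empirical correlations between score and real
staff assessments (r² ≈ 0.5–0.64 in the original data) depend on data
that were never deposited and are not reproducible here; the package's
claims are correctness of the pipeline, not re-estimation of those
correlations.
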