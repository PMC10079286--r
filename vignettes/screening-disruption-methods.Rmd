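---
title: "Modelling disruptions to population cancer screening programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disruptions to population cancer screening programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screendisrupt)
```

## What the package models

`screendisrupt` is a microsimulation of Australia's three organised cancer
screening programmes — biennial mammography for women 50–74 (BreastScreen),
biennial iFOBT bowel screening for persons 50–74 with colonoscopy follow-up
(NBCSP), and five-yearly primary HPV cervical screening for women 25–74
(NCSP) — built to evaluate what happens when screening is disrupted, as it
was by COVID-19 control measures from early 2020. A disruption scenario
(a complete pause with a capacity-constrained recovery, or a reduction in
attendance) is applied to a synthetic cohort and every outcome is measured
against a *status quo* counterfactual run that shares the cohort, the
disease histories, and every random draw (common random numbers), so
scenario-minus-status-quo differences carry no cohort-level noise.

The reported outcomes mirror routine programme reporting: screens provided
and missed, cancer diagnoses (counts and rates per 100,000 including
non-participants), screen-detected and interval cancers (12- and 27-month
windows), programme sensitivity, tumour size / nodal involvement / grade
distributions, stage shift ("upstaging"), and diagnostic service demand
(assessments, colonoscopies, colposcopies).

## Natural histories

Each cancer is a continuous-time multistate process with exponential
(memoryless) dwell times:

* **Breast** — healthy → preclinical tumour ≤15 mm → preclinical >15 mm →
  clinical (symptomatic) cancer. Grade (3 vs 1–2) is fixed at onset;
  grade-3 tumours run all clocks faster (`grade3_speed`). Nodal
  involvement accrues at a low hazard while the tumour is small and a much
  higher one once it is large. This reproduces the three reported
  tumour-characteristic axes without a tumour-growth ODE.
* **Bowel** — healthy → adenoma (which may regress) → preclinical CRC
  stage 1–2 → preclinical stage 3–4 → clinical cancer, with symptomatic
  presentation competing in both cancer stages. Removing an adenoma at
  colonoscopy truncates the pathway; this is how screening prevents
  cancer, and why a pause produces later-stage and excess diagnoses.
* **Cervix** — healthy → HPV infection (usually clears) → CIN (may
  regress) → localised → regional → distant invasive cancer. CIN treated
  at colposcopy cannot progress. HPV vaccination multiplies the
  acquisition hazard by `vaccine_multiplier` (default 0.1) in birth
  cohorts from 1993 with 80% coverage.

Because all dwell times are exponential, a person's complete
no-intervention trajectory can be drawn up front as a set of competing
exponential event times. Monthly stepping of competing hazards converges
to exactly this law; the pre-drawn form is faster, matches the
matrix-exponential occupancy solution exactly in distribution (one of the
test-suite invariants), and makes common-random-number pairing exact:
screening changes which part of a trajectory is *observed*, never the
trajectory itself. Stages never reverse (precursor regression is allowed
only for adenomas and CIN).

Disease onsets follow a stationary Poisson process over a lookback window
long relative to the sojourn times, so prevalent disease at the simulation
start has its stationary distribution. Participants' prevalent disease is
additionally thinned by their *pre-simulation screening history* (the
rounds implied by their schedule, back to each programme's inception era),
and people whose disease had already presented clinically before the
simulation start are prevalent survivors, not new cases. Without these two
initialisation steps the early simulation years ride an
unscreened-stationary prevalence wave and detection rates sit far above
the programme's steady state.

## Calibration

The free natural-history and test-characteristic parameters are not
directly observable; they are set by calibrating the *status quo* run to
the published status quo reporting column (diagnoses per 100,000,
screen-detected and interval-cancer rates, tumour-characteristic shares,
recall rates) with `calibrate()`, a derivative-free coordinate search with
a shrinking multiplicative step against a fixed-seed (hence deterministic)
objective: the weighted sum of squared relative errors (`discrepancy()`).
Scenario outputs are never fitted — the model is calibrated to the
no-disruption world and scenarios are predictions. The packaged defaults
in `default_nh_params()` and `programme_config()` are the product of this
search; `calibrate_breast()` re-runs it from those defaults.

Parameter recovery on self-generated targets (the targets produced by a
known parameter set under the same seed) is part of the test suite.

## Cohorts and screening behaviour

Cohorts are synthetic. Default sizes are the national eligible
populations (7.1 M persons for bowel — 3.5 M men, 3.6 M women; 3.54 M
women for breast; 8.2 M for cervix), scaled 1:100 by default for
desk-scale runs; all rates are scale-invariant and counts are rescaled on
report. Ages are uniform within the eligible span (no age pyramid is
published for the screening populations; a table-driven pyramid is
accepted). The default span covers everyone age-eligible at some point in
the 2020–2021 reporting window (roughly birth years 1945–1971 for the
50–74 programmes), which matters: invitation inflow at the lower age
bound then balances ageing-out at the upper bound and status quo
throughput is stationary across the reporting window, as it is for the
real programmes.

Ever-screeners are assigned by a participation draw (55% breast, 43.5%
bowel, 46% cervix). Screeners carry an attendance-delay profile: a
personal on-schedule probability drawn from 0.60–0.84 (the observed
round-specific spread), with off-schedule rounds attended late (1 +
geometric months, mean 6, capped at 12) or, for 35% of off-schedule
rounds, up to three months early. Routine re-invitation is anchored to
the last attended screen, matching `due_date()`. Bowel kit mailouts are
anchored to the biennial round schedule instead, since kits are mailed on
a fixed cycle regardless of when the previous kit was returned.

Cervical cohorts carry the HPV-renewal transition state: 53.6% of women
had already attended their first HPV test (next routine screen five years
later, i.e. not before December 2022) and the remainder are due their
first HPV test two years after their last cytology test, with
last-cytology dates uniform over 2018–2019. Initial surveillance pools
(bowel colonoscopy surveillance, cervical 12-month repeat testing) and
the bowel 4-year post-colonoscopy return pool are seeded at their
approximate steady-state sizes so that follow-up service volumes are
stationary from the start.

What the generator does *not* emulate: age-dependent incidence and
participation, socio-economic and geographic structure, HPV genotypes,
annual-screening high-risk breast subgroups, treatment and mortality
(apart from an optional flat background mortality used only by the
long-horizon bowel mode). Passing tests therefore demonstrate internal
consistency of the mechanism under these stylised conditions, not
fidelity to any particular subgroup of the real populations.

## Scenarios

Scenario defaults reproduce the evaluated 2020 grid. Breast and bowel
disruptions are complete pauses starting 1 April 2020 (the 12-month bowel
pause spans calendar 2020, matching its published framing); cervical
disruptions are attendance reductions to *routine* screening only (50%,
75%, 95% for 6, 9, 12 months — the tables specify 95% for the 12-month
scenario and that is the default; surveillance and follow-up visits are
unaffected). Missed bowel rounds are taken at the next round two years
later; missed cervical screens are re-attended uniformly over 2021
(9-month scenario) or spread over 2021–2022 (6- and 12-month scenarios);
missed breast appointments are re-booked by the prioritisation queue.

A bowel pause also leaves a lasting participation after-effect: each
person whose kit round is cancelled leaves the programme for good with
probability `missed_round_dropout` (default 0.2). The published
long-horizon excess of colorectal cancers is attributed to both the
detection changes of 2020–2021 and long-term changes in screening
behaviour attributable to the disruption; the dropout probability is the
behavioural half of that statement. No published rate exists for it; 0.2
was chosen once as a plausible attrition among people whose round was
cancelled, and the long-horizon check is a sign check only.

**Capacity.** Breast throughput is a calendar-anchored multiplier
schedule: 1 before the pause, 0 during it, then a linear ramp reaching
the recovery target in the seventh month after resumption. For the 3- and
6-month pauses throughput creeps back to the status quo target from a low
restart (ramp start fraction 0.3); the 12-month pause is described as
triggering expanded recovery strategies reaching 150% of status quo by
month seven, and restarts near status quo throughput (fraction 0.65). Only
the month-seven endpoint is published; the start fractions are this
package's reading, chosen to reproduce simultaneously the provided-screen
fractions of the shorter pauses and the recovery dynamics of the
12-month scenario, and are configurable (`ramp_start_frac`).

Base capacity (screens per month at multiplier 1) is measured inside each
run as the mean monthly attended screens over the twelve months before
the pause — the run's own status quo demand — so "150% capacity" is
meaningful without external data.

## The prioritisation queue

During a breast pause and recovery, appointments become booking requests
allocated under the capacity schedule by a deterministic four-factor
priority: women in the 50–74 target ages first, then appointments that
fell during the pause before those falling during recovery, then existing
clients before newly invited, then weeks overdue (descending), with ties
broken by id. The published description lists the four factors and states
that target-age and most-overdue clients were prioritised, but not the
full ordering; the ordering here is a configurable permutation with that
default. Capacity is never exceeded, no lower-priority request is served
while a higher-priority one waits, and allocation is seed-independent
given the queue (all test-suite invariants).

## Outcome definitions and numerical choices

* Interval cancers: non-screen-detected invasive cancers within 12 or 27
  months of a negative screening episode; the 12-month figures cover
  diagnoses in 2020, the 27-month figures 2020–2021. Interval-12 is a
  subset of interval-27 by construction.
* Programme sensitivity: screen-detected / (screen-detected +
  interval-27), as a percentage; undefined (NA, with a warning) when both
  counts are zero.
* Upstaging attribution is excess-flow bookkeeping between the paired
  stage-by-year tables: total excess cancers are additional diagnoses at
  the earliest stage; any increase at the latest stage is upstaging from
  the stage below; residual lower-stage changes are upstaging one step
  up. The same rules applied to the grouped CRC ladder (1–2 / 3–4) give
  the stage-advance count. "Women affected by delays" is additional plus
  upstaged.
* Rates per 100,000 use the full cohort (participants and
  non-participants) as denominator.
* Calendar time is an integer month index (`ym()`); natural-history event
  times are continuous and floored to months only when they generate
  dated events. Weeks are months × 365.25/12/7, so a 24-month interval
  reports as 104.3 weeks.
* Degenerate inputs: zero hazards produce no events; empty interval
  subgroups return NA with a warning; a zero-duration scenario follows
  exactly the status quo code path and reproduces it bit for bit.

## Problem sizes

Desk-scale analyses run at 1:100 (35,380 women for breast, 71,000 persons
for bowel, 82,000 women for cervix) over 2018–2022/23 horizons; the
acceptance analysis averages the breast scenario effect over 24 paired
seeds at 1:100. Cervical disruption effects are small in absolute terms
(tens of cancers nationally), so direction-of-effect checks run at 1:10
with a 2018–2026 horizon, where the common-random-number pairing makes
the scenario cancer set a near-superset of the status quo set. The
long-horizon bowel mode runs 2018–2050 at 1:250 with background
mortality. These sizes were chosen so each check has adequate resolution
for the quantity it asserts.

## Known limitations

Absolute incidence levels are meaningful only through calibration; the
simplified natural histories have no age structure, so outputs should be
read as programme-level aggregates. Breast recall rates sit slightly
below the published status quo figure because non-invasive (in situ)
detections are not modelled, and the published screens-missed totals for
the combined programmes are not exactly reconcilable from the published
provided-screen rows (the embedded fixture report flags, rather than
hides, this). Mortality, treatment, and life-year outcomes are out of
scope.
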