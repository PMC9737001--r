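---
title: "Simulating whole-hospital congestion and decongestion scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating whole-hospital congestion and decongestion scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospitalflow)
```

## The model

`hospitalflow` is a continuous-time discrete-event simulation of patient flow
through a large tertiary hospital, built to compare congestion-triggered
decongestion interventions on a relative scale. Four physical units are
modelled as bed pools: the ED admission side (18 beds by default), an acute
medical unit (AMU, 24 beds), a medical ward (170) and a surgical ward (143) —
337 inpatient beds in total. Patient agents carry a triage score (1–5, 1 most
urgent), an arrival mode (walk-in, ambulance, elective), a class (medical or
surgical) and journey milestones (arrival, ED bed, admission request, ward
bed, exit).

Flow follows the standard access-block anatomy:

* ED arrivals wait for an ED treatment space (queue discipline: triage
  ascending, then request time), are treated for a log-normal duration, and
  are then either discharged or admitted.
* Admitted patients **board** in their ED bed until an inpatient bed frees;
  boarding consumes ED capacity, which is the coupling that turns ward
  saturation into ED crowding.
* Admitted medical patients pass through the AMU when an AMU bed is free
  (an AMU leg followed by a medical-ward stay, boarding in the AMU bed if the
  ward is full); otherwise they go directly to the medical ward for the
  combined duration, so total medical bed-hours are path-invariant.
* Elective surgical patients arrive in weekday-morning windows and occupy
  surgical beds; when postponed by an intervention they enter a backlog that
  is rescheduled FIFO whenever a surgical bed frees outside a congestion
  episode, ahead of newly arriving electives.

All stochastic inputs (arrival times, triage, admission decisions, class,
every length of stay) are drawn on the R side from a single seed and passed
to the engine as a patient table; the engine itself is deterministic. Runs
are therefore bit-reproducible, and scenarios compared under the same seed
share **common random numbers**, which sharpens paired comparisons
considerably at these event rates.

## Congestion definition

At every integer hour the simulator evaluates three indicators jointly:
occupied ED admission beds ≥ 17 (of 18), inpatient occupancy fraction
≥ 0.97, and ED waiting-queue length ≥ 28. All three thresholds are inclusive
and, by default, combined conjunctively; a disjunctive mode exists for
sensitivity analysis (`congestion_thresholds(conjunctive = FALSE)`). A
congestion **episode** is a maximal run of consecutive congested checks; a
run truncated by the horizon closes at the horizon. Episodes are counted at
detection time (the first congested check). No minimum-duration filter is
applied: interventions activate at the check one hour after onset, and only
if congestion persists at that check, so one-hour episodes receive no
intervention and their quota lapses.

The queue threshold of 28 can also be re-derived on the synthetic system
with `calibrate_queue_threshold()`, which bisects over `queue_min` until the
uncontrolled baseline produces a target episode frequency — the
reverse-engineering route from an assumed "roughly weekly" congestion
frequency.

## Interventions

`scenario_catalog()` enumerates the 27 scenarios. Scenarios 1–12 re-size bed
pools; by default these are permanent ("right-sizing") changes for the whole
run, because the activation-delay rule is read as governing patient-level
actions. Setting `episodic_capacity = TRUE` in the configuration instead
opens/closes the extra beds with each episode (the alternative reading;
occupancy may then transiently exceed the reverted capacity until beds drain).

Scenarios 13–26 act on patients once per episode, one hour after onset:

* **ED out-transfers** remove boarders from ED beds, least urgent first
  (highest triage), longest-boarding first within a triage score.
* **Early discharges** release inpatients whose triage score is ≥ 4,
  nearest-to-scheduled-discharge first within that set. A configuration flag
  (`allow_discharge_fallback`) optionally extends eligibility to triage 3
  when the pool is exhausted; it is off by default, the strict reading.
* **Postponements** move waiting (not-yet-admitted) electives to the backlog,
  most recently scheduled first; any unfilled quota applies to electives
  arriving before the episode ends.
* **Diversions** redirect the next *n* ambulance arrivals between activation
  and episode end; unfilled quota lapses at episode end, keeping annual
  diversions proportional to episode counts.

When fewer eligible patients exist than requested, the intervention acts on
all of them; counters always record actual, not requested, numbers.

## The synthetic hospital

The original patient-journey data behind this class of model are not
publicly available, so the package ships a synthetic generator whose
defaults are chosen once to reproduce the *structure* the model assumes:

* **Arrivals**: time-varying Poisson processes on an hour-of-day ×
  day-of-week intensity grid. The ED profile is afternoon-peaked (night
  trough ≈ 0.35× the mean, mid-afternoon ≈ 1.4×) with a mild day-of-week
  modulation; electives arrive only weekday mornings (07:00–11:00). Base ED
  volume is 182 presentations/day, 30% by ambulance.
* **Triage mix** (0.02, 0.13, 0.35, 0.35, 0.15) over scores 1–5, leaving a
  substantial triage ≥ 4 pool for the discharge rule; admission probability
  declines with triage score (0.90, 0.65, 0.45, 0.25, 0.10), giving a mean
  admission fraction of 0.3625. Electives draw triage from the same mix; in
  reality scheduled patients skew less urgent, but the choice only matters
  for the discharge-eligibility pool and is tunable.
* **Class split**: the probability that an admitted ED patient is medical is
  derived so that expected medical admissions exceed expected surgical
  admissions (emergency plus elective) by the ratio 1.173 — 17.3% more
  medical than surgical patients.
* **Lengths of stay** are log-normal per class (ED treatment mean 1.3 h;
  AMU 24 h; medical ward 84 h; surgical 96 h; elective 84 h; log-scale SDs
  0.5–0.7), the canonical right-skewed choice for hospital stays.
* **Discharge window**: ward stays whose raw end falls outside 10:00–18:00
  are deferred to the next window (placed deterministically by the fractional
  hour of the raw end). Without this, continuous discharges keep ward
  occupancy nearly constant and congestion, once started, persists for days;
  the morning-discharge/evening-fill rhythm is what makes real hospital
  congestion episodic, and the 10 AM census convention sits near the daily
  occupancy peak.
* **Calibration**: a single global arrival multiplier scales every stream.
  It was fixed by bisection on replicated two-year baseline runs until the
  collection-year behaviour landed in the target band — mean 10 AM occupancy
  in [320, 335] beds and 50–160 congestion episodes per year — and is
  committed as `arrival_multiplier = 0.88` in `default_config()`. With it,
  unit utilisations sit near 0.96–0.98 and the baseline produces roughly
  70–120 episodes per collection year across seeds.

What the generator does **not** emulate: seasonality and holidays, weekday
discharge suppression at weekends, patient-level covariates beyond triage
and class, staff and diagnostic resources, and intra-day transfer decisions.
Passing tests on this synthetic system therefore demonstrate that the
mechanics (flow, congestion detection, triggered interventions, accounting)
are correct and that the qualitative scenario orderings are reproduced; they
do not certify quantitative agreement with any real hospital's episode
counts or durations.

## Experiments and metrics

`run_experiment()` replicates each scenario (20 times by default, matching
standard practice for this design), simulates two years per run and discards
the first as warm-up, collecting only second-year results. Replication *r*
of every scenario uses seed `base_seed + r`. Per-run metrics are the daily
10 AM inpatient occupancy mean and **population** standard deviation (the
convention is fixed for determinism), episode count, maximum/minimum/mean
episode duration, and the intervention tallies. Replications aggregate by
field-wise means, so the aggregated maximum is the mean of per-replication
maxima and fractional event counts are expected.

Decongestion **efficiency** divides the reduction relative to the baseline
by the number of patients the intervention touched:

$$\text{event efficiency} = \frac{N_0 - N_s}{A_s}, \qquad
  \text{time efficiency} = \frac{\bar T_0 - \bar T_s}{A_s},$$

where \(N\) is the annual episode count, \(\bar T\) the mean episode
duration in hours, and \(A_s\) the scenario's affected patients (transfers +
early discharges) plus diverted ambulances plus postponed electives. This
divisor reproduces the published efficiency table exactly for the diversion
and combination scenarios (22, 24, 25, 26) from the published inputs; the
printed row for scenario 23 (0.14, 0.004) is inconsistent with every other
row under any simple divisor ((111.75 − 29.15)/438.6 ≈ 0.19), and is treated
as a typesetting error: the implementation follows the formula. Efficiency
is undefined (an error) for capacity-only scenarios, which touch no
patients, and negative when a scenario worsens congestion. Report rounding
follows the published precision: two decimals for event efficiency, four for
time efficiency.

`rank_scenarios()` orders scenarios ascending on congestion metrics and
descending on efficiencies, with ties broken by scenario id.

## Numerical and design notes

* Time is continuous; snapshots and congestion checks occur on integer
  hours. At equal times the engine processes bed-release events first, then
  arrivals, then the hourly check, fixing determinism.
* Bed queues everywhere order by (triage, request time, id); the elective
  backlog alone is FIFO. Already-waiting patients precede backlog
  readmissions at a freed surgical bed; the backlog precedes newly arriving
  electives.
* Capacity reductions never evict patients: occupancy drains to the new
  capacity as stays end.
* An infeasible configuration (queue growing without bound) completes and is
  flagged: the run warns when the ED queue never drains below 20 over the
  final fifth of the horizon and ends long.
* Degenerate inputs: zero arrival intensities give all-zero trajectories; a
  zero log-scale SD makes a length-of-stay class deterministic; an empty
  episode list summarises as zeros by convention.
* A structural finding worth knowing: adding ED beds reduces *episode
  counts* but can lengthen the *time-average ED queue*, because the ED queue
  throttles admissions — extra ED capacity feeds saturated wards and breeds
  boarders. The monotone "more beds, shorter queue" property holds in the
  regime where wards are not binding, and that is where the test suite
  asserts it.

## Reduced problem sizes

The shipped tests run the full 27-scenario conservation audit at half-year
horizon with 3 replications, the calibration check at 5 × 2 years, and the
directional comparisons at 10 paired one-year replications with a half-year
warm-up — sizes chosen so the whole suite completes in about a minute while
keeping Monte-Carlo error far below the asserted margins.

## Limitations

Staffing, ICU and diagnostic resources are not modelled; beds are the only
constrained resource. The synthetic hospital is one internally consistent
configuration, not a fit to any real data, so absolute episode counts and
durations carry no clinical meaning — only relative scenario comparisons do.
Cost–benefit trade-offs of the interventions are out of scope.
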