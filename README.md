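# hospitalflow

Whole-hospital patient-flow simulation for evaluating congestion-triggered
decongestion interventions.

Emergency-department (ED) overcrowding is largely an *access-block* problem:
admitted patients board in ED beds because the inpatient wards are full, the
ED loses treatment capacity, and the waiting queue grows. Interventions that
relieve such congestion — opening beds, transferring or discharging patients,
postponing elective surgery, diverting ambulances — differ not only in how
much congestion they remove but in how many patients they disturb.
`hospitalflow` is for health-services researchers and hospital capacity
planners who want to rank such interventions on a *relative* scale with a
transparent, reproducible model.

The package provides:

* a discrete-event engine (C++ core) moving patient agents through
  ED queue → ED treatment → AMU / medical / surgical wards, with admitted
  patients boarding in ED beds while wards are full and electives admitted
  into surgical beds from weekday scheduling windows;
* a synthetic hospital generator (time-varying Poisson arrivals on an
  hour-of-day × day-of-week grid, log-normal stays, triage mix, a
  medical:surgical admissions ratio of 1.173) calibrated so the uncontrolled
  baseline produces a mean 10 AM census of ≈ 325 of 337 inpatient beds and
  congestion roughly one to two times a week;
* hourly congestion detection — congested iff occupied ED beds ≥ 17 **and**
  inpatient occupancy ≥ 0.97 **and** ED queue ≥ 28 — segmented into episodes;
* a catalogue of 27 scenarios (baseline; ±beds; per-episode ED
  out-transfers, triage ≥ 4 early discharges, elective postponements into a
  reschedulable backlog, ambulance diversions; combinations), activated one
  hour after episode onset;
* replicated experiments with common random numbers, and the efficiency
  statistic

  ```
  event efficiency = (baseline events − scenario events) / patients affected
  time  efficiency = (baseline mean episode hours − scenario mean hours) / patients affected
  ```

  where *patients affected* counts transfers + early discharges + diversions
  + postponements.

## Worked example

```r
library(hospitalflow)

cfg  <- default_config()
plan <- experiment_plan(c(0, 6, 22), replications = 5, years = 2, base_seed = 1)
ex   <- run_experiment(plan, cfg)
ex
#> <hospital_experiment> 3 scenario(s) x 5 replication(s), 2 year(s) (1 warm-up)
#> # A tibble: 3 × 6
#>   scenario label       mean_occupancy_10am n_congestion_events mean_congestion_h
#>      <dbl> <chr>                     <dbl>               <dbl>             <dbl>
#> 1        0 Baseline (…                326.                91.4              13.0
#> 2        6 Adding 6 A…                327.                42.8              10.3
#> 3       22 Diverting …                325.                82.4              11.8

rank_scenarios(ex, "events")[, c("rank", "scenario", "n_congestion_events")]
#> # A tibble: 3 × 3
#>    rank scenario n_congestion_events
#>   <int>    <dbl>               <dbl>
#> 1     1        6                42.8
#> 2     2       22                82.4
#> 3     3        0                91.4
```

Reading the numbers: each run simulates two years and collects only the
second (the first is warm-up), so `n_congestion_events` is episodes per
year, averaged over 5 paired replications. The 10 AM occupancy barely moves
across scenarios (325–327 beds) while episode counts move a lot — opening
six AMU beds halves the congestion frequency (91.4 → 42.8), and diverting
two ambulances per episode trims it (→ 82.4) while touching ~140 ambulance
arrivals a year. `efficiency()` then expresses those reductions per affected
patient, `plot_efficiency()` draws the efficiency scatter, and
`autoplot(ex)` the per-scenario event counts. `tidy(ex)`/`glance(ex)` return
the results as tibbles for further dplyr work.

Single runs are available at a lower level: `run_simulation()` returns
hourly snapshots, patient milestones, episodes and intervention records;
`extract_episodes()`, `episode_stats()`, `summarize_run()` and
`aggregate_replications()` are the building blocks the experiment driver
uses. A thin CLI (`inst/cli/hospitalflow`) wraps the same functions as
`simulate` / `report` / `calibrate` subcommands.

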