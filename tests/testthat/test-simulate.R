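test_that("an empty hospital produces all-zero snapshots", {
  tr <- run_simulation(silent_config(), build_scenario(0), years = 1, seed = 1)
  expect_true(all(tr$snapshots$ed_occupied == 0))
  expect_true(all(tr$snapshots$ed_queue_len == 0))
  expect_true(all(tr$snapshots$inpatient_occupied == 0))
  expect_identical(nrow(tr$episodes), 0L)
})

test_that("a single non-admitted walk-in hand-traces exactly", {
  pats <- trace_patients(list(id = 1L, time_h = 0.5, ed_los = 3))
  tr <- run_simulation(silent_config(), build_scenario(0), years = 1,
                       seed = 1, patients = pats)
  p <- tr$patients
  expect_equal(p$t_ed_bed, 0.5)
  expect_equal(p$t_exit, 3.5)
  expect_identical(as.character(p$disposition), "discharged")
  # occupied at the checks falling inside [0.5, 3.5): hours 1, 2, 3
  occ_hours <- tr$snapshots$time_h[tr$snapshots$ed_occupied == 1]
  expect_identical(occ_hours, c(1L, 2L, 3L))
})

test_that("an admitted medical patient walks the AMU-then-ward path", {
  pats <- trace_patients(list(id = 1L, time_h = 0.25, ed_los = 2,
                              admitted = TRUE, class = "medical",
                              amu_los = 10, ward_los = 24))
  tr <- run_simulation(silent_config(), build_scenario(0), years = 1,
                       seed = 1, patients = pats)
  p <- tr$patients
  expect_equal(p$t_admit_request, 2.25)
  expect_equal(p$t_ward_bed, 2.25)  # AMU bed free: admitted immediately
  expect_equal(p$t_exit, 2.25 + 10 + 24)
  expect_identical(as.character(p$disposition), "completed")
  # milestones are non-decreasing along the pathway
  expect_true(all(diff(c(p$time_h, p$t_ed_bed, p$t_admit_request,
                         p$t_ward_bed, p$t_exit)) >= 0))
})

test_that("ED queue forms when beds are busy and serves triage order", {
  # one bed occupied for 10 h; two waiters with triage 4 then 2
  cfg <- silent_config(ed_admission_beds = 1)
  pats <- trace_patients(
    list(id = 1L, time_h = 0.1, ed_los = 10),
    list(id = 2L, time_h = 0.2, ed_los = 1, triage = 4L),
    list(id = 3L, time_h = 0.3, ed_los = 1, triage = 2L))
  tr <- run_simulation(cfg, build_scenario(0), years = 1, seed = 1,
                       patients = pats)
  p <- tr$patients
  # triage 2 is seated before triage 4 despite arriving later
  expect_lt(p$t_ed_bed[p$id == 3], p$t_ed_bed[p$id == 2])
  expect_equal(max(tr$snapshots$ed_queue_len), 2)
})

test_that("identical (config, scenario, seed) reruns bit-identically", {
  cfg <- busy_little_hospital()
  a <- suppressWarnings(run_simulation(cfg, build_scenario(22), years = 1,
                                       seed = 10))
  b <- suppressWarnings(run_simulation(cfg, build_scenario(22), years = 1,
                                       seed = 10))
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$patients, b$patients)
  expect_identical(event_log(a), event_log(b))
})

test_that("occupancy never exceeds capacity in any unit", {
  cfg <- busy_little_hospital()
  for (id in c(0, 9, 16, 22)) {
    # scenario 9 overloads the small surgical ward; warnings are expected
    tr <- suppressWarnings(run_simulation(cfg, build_scenario(id), years = 1,
                                          seed = 4))
    expect_true(all(tr$snapshots$inpatient_occupied <=
                      tr$snapshots$inpatient_capacity))
    expect_true(all(tr$snapshots$ed_occupied <=
                      cfg$ed_admission_beds +
                      build_scenario(id)$capacity_deltas[["ed"]]))
  }
})

test_that("10 AM occupancy summary follows the population convention", {
  sn <- tibble::tibble(time_h = 0:47,
                       inpatient_occupied = ifelse(0:47 < 24, 320, 330))
  out <- snapshot_10am_occupancy(sn, window = c(0, 48))
  expect_equal(out$mean, 325)
  expect_equal(out$sd, 5) # population std-dev of {320, 330}
  expect_identical(out$n_days, 2L)

  const <- tibble::tibble(time_h = 0:71, inpatient_occupied = 327)
  out2 <- snapshot_10am_occupancy(const, window = c(0, 72))
  expect_equal(c(out2$mean, out2$sd), c(327, 0))

  expect_error(snapshot_10am_occupancy(const, window = c(100, 100)), "window")
})

test_that("an infeasible configuration flags queue divergence", {
  cfg <- default_config(ed_admission_beds = 1, ed_arrivals_per_day = 60,
                        electives_per_week = 0)
  expect_warning(
    tr <- run_simulation(cfg, build_scenario(0), years = 1, seed = 1),
    "without bound")
  expect_true(tr$queue_divergence)
})

test_that("trajectory artefacts export and read back", {
  cfg <- busy_little_hospital()
  tr <- suppressWarnings(run_simulation(cfg, build_scenario(19), years = 1,
                                        seed = 2))
  dir <- withr::local_tempdir()
  write_trajectory(tr, dir, run_id = "r1")
  sn <- readr::read_csv(file.path(dir, "r1_snapshots.csv"),
                        show_col_types = FALSE)
  expect_identical(nrow(sn), nrow(tr$snapshots))
  ev <- readr::read_csv(file.path(dir, "r1_events.csv"),
                        show_col_types = FALSE)
  expect_true(all(c("patient_id", "event", "time_h") %in% names(ev)))
})
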