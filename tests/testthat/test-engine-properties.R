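# Rule-level properties of the event engine, checked through the artefacts
# of full runs on a small hospital that congests often.

run_busy <- function(id, seed = 21, cfg = busy_little_hospital()) {
  suppressWarnings(run_simulation(cfg, build_scenario(id), years = 1,
                                  seed = seed))
}

test_that("every arrival ends in exactly one disposition (conservation)", {
  for (id in c(0, 13, 16, 19, 22, 26)) {
    tr <- run_busy(id)
    expect_identical(sum(is.na(tr$patients$disposition)), 0L)
    expect_identical(nrow(tr$patients), length(tr$patients$disposition))
    counts <- table(tr$patients$disposition)
    expect_identical(sum(counts), nrow(tr$patients))
  }
})

test_that("early-discharged inpatients all have triage >= 4", {
  tr <- run_busy(18)
  dis <- tr$patients[tr$patients$disposition == "early_discharged", ]
  expect_gt(nrow(dis), 0)
  expect_true(all(dis$triage >= 4))
})

test_that("per-episode action counts respect the scenario quota", {
  for (id in c(13, 16, 22)) {
    tr <- run_busy(id)
    s <- build_scenario(id)
    quota <- s$transfer_ed_n + s$discharge_inpatient_n +
      s$discharge_medical_n + s$discharge_surgical_n +
      s$postpone_elective_n + s$divert_ambulance_n
    per_ep <- tr$interventions |> dplyr::count(.data$episode_start_h)
    expect_true(all(per_ep$n <= quota))
    # actions happen one hour after episode onset (diversions and arriving
    # postponements later, but always inside the episode)
    joined <- dplyr::left_join(tr$interventions, tr$episodes,
                               by = c(episode_start_h = "start_h"))
    expect_true(all(joined$time_h >= joined$episode_start_h + 1))
    expect_true(all(joined$time_h <= joined$end_h))
  }
})

test_that("diverted ambulance arrivals are bounded by quota times episodes", {
  tr <- run_busy(22)
  n_div <- sum(tr$patients$disposition == "diverted")
  expect_gt(n_div, 0)
  expect_lte(n_div, 2 * nrow(tr$episodes))
  # diverted patients arrived by ambulance and consumed no bed
  div <- tr$patients[tr$patients$disposition == "diverted", ]
  expect_true(all(div$mode == "ambulance"))
  expect_true(all(is.na(div$t_ed_bed)))
})

test_that("postponement feeds the backlog and conserves electives", {
  tr <- run_busy(21)
  n_post <- tr$counters$postponed
  expect_gt(n_post, 0)
  expect_identical(sum(tr$interventions$action == "postpone"),
                   as.integer(n_post))
  # a postponed elective is never lost: it either completed, is in a bed,
  # or is still in the backlog at the horizon
  post_ids <- tr$interventions$patient[tr$interventions$action == "postpone"]
  fates <- tr$patients$disposition[match(post_ids, tr$patients$id)]
  expect_true(all(as.character(fates) %in%
                    c("completed", "in_system", "postponed")))
})

test_that("capacity-only scenarios touch no patients", {
  for (id in c(2, 8, 11)) {
    tr <- run_busy(id)
    expect_identical(nrow(tr$interventions), 0L)
    expect_identical(
      sum(tr$patients$disposition %in%
            c("transferred_out", "diverted", "early_discharged", "postponed")),
      0L)
  }
})

test_that("adding ED beds weakly reduces queueing when wards are not binding", {
  # pure ED queueing regime (no admissions, so no boarding feedback):
  # more treatment spaces can only shorten the queue
  cfg <- hospital_config(
    ed_admission_beds = 4L, amu_beds = 4L, medical_beds = 20L,
    surgical_beds = 16L, ed_arrivals_per_day = 60,
    admit_probability = rep(0, 5), electives_per_week = 0,
    los_means_h = c(ed_treatment = 1.2, amu = 9, medical = 33,
                    surgical = 33, elective_surgical = 29),
    discharge_window_hours = 0)
  qmeans <- sapply(c(0, 1, 2), function(id) {
    mean(sapply(1:4, function(r) {
      pats <- hospitalflow:::build_patient_table(cfg, 8760, 50 + r)
      tr <- suppressWarnings(
        run_simulation(cfg, build_scenario(id), years = 1,
                       seed = 50 + r, patients = pats))
      mean(tr$snapshots$ed_queue_len)
    }))
  })
  expect_lte(qmeans[2], qmeans[1] + 1e-9)
  expect_lte(qmeans[3], qmeans[2] + 1e-9)
})

test_that("transferred patients were boarding in the ED when removed", {
  tr <- run_busy(15)
  moved <- tr$patients[tr$patients$disposition == "transferred_out", ]
  expect_gt(nrow(moved), 0)
  expect_true(all(moved$admitted))
  expect_true(all(!is.na(moved$t_admit_request)))
  expect_true(all(is.na(moved$t_ward_bed)))
})
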