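test_that("request_bed seats when free and queues when full", {
  st <- hospital_state(units = tibble::tibble(unit = "ward", capacity = 1L,
                                              occupied = 0L))
  r1 <- request_bed(st, list(id = 1L, triage = 3L), "ward")
  expect_identical(r1$outcome, "seated")
  r2 <- request_bed(r1$state, list(id = 2L, triage = 4L), "ward")
  expect_identical(r2$outcome, "queued")
  expect_error(request_bed(r2$state, list(id = 1L, triage = 3L), "ward"),
               "double allocation")
  expect_error(request_bed(st, list(id = 9L, triage = 3L), "icu"), "icu")
})

test_that("queue is served most-urgent first", {
  st <- hospital_state(units = tibble::tibble(unit = "ward", capacity = 1L,
                                              occupied = 1L))
  st <- request_bed(st, list(id = 10L, triage = 4L), "ward")$state
  st <- request_bed(st, list(id = 11L, triage = 2L), "ward")$state
  expect_identical(st$queues$ward$id[1], 11L) # triage 2 ahead of triage 4
})

test_that("early discharges only touch triage >= 4 inpatients", {
  st <- hospital_state(
    units = tibble::tibble(unit = c("ed", "amu", "medical", "surgical"),
                           capacity = c(18L, 24L, 170L, 143L),
                           occupied = c(0L, 0L, 10L, 0L)),
    inpatients = tibble::tibble(
      id = 1:10, unit = "medical",
      triage = c(3L, 3L, 4L, 4L, 5L, 3L, 2L, 4L, 5L, 3L),
      remaining_h = c(5, 1, 30, 2, 50, 9, 4, 80, 3, 6)))
  out <- apply_episode_actions(st, build_scenario(16),
                               tibble::tibble(start_h = 100))
  dis <- out$record[out$record$action == "discharge", ]
  expect_identical(nrow(dis), 2L)
  tri <- st$inpatients$triage[match(dis$id, st$inpatients$id)]
  expect_true(all(tri >= 4))
  # nearest to scheduled discharge first within the triage >= 4 set
  expect_identical(dis$id, c(4L, 9L))
})

test_that("transfers pick the least urgent, longest-boarding ED patients", {
  st <- hospital_state()
  st$queues$ed_boarders <- tibble::tibble(
    id = 1:4, triage = c(3L, 5L, 5L, 4L), request_time = c(1, 5, 2, 0))
  out <- apply_episode_actions(st, build_scenario(13),
                               tibble::tibble(start_h = 10))
  tr <- out$record[out$record$action == "transfer", ]
  expect_identical(tr$id, c(3L, 2L)) # triage 5 first, earliest request first
  expect_identical(nrow(out$state$queues$ed_boarders), 2L)
})

test_that("postponements move waiting electives to the backlog", {
  st <- hospital_state()
  st$queues$waiting_electives <- tibble::tibble(id = 5:7,
                                                request_time = c(2, 4, 9))
  out <- apply_episode_actions(st, build_scenario(19),
                               tibble::tibble(start_h = 50))
  po <- out$record[out$record$action == "postpone", ]
  expect_identical(nrow(po), 2L)
  expect_identical(out$state$elective_backlog$id, po$id)
  # shortfall: requesting more than exist acts on all and stops
  st2 <- st
  out2 <- apply_episode_actions(st2, build_scenario(21),
                                tibble::tibble(start_h = 50))
  expect_identical(nrow(out2$record[out2$record$action == "postpone", ]), 3L)
})

test_that("baseline scenario produces an empty record", {
  st <- hospital_state()
  out <- apply_episode_actions(st, build_scenario(0),
                               tibble::tibble(start_h = 1))
  expect_identical(nrow(out$record), 0L)
  expect_identical(out$divert_quota, 0)
})

test_that("backlog reschedules FIFO into free surgical beds when calm", {
  st <- hospital_state(
    units = tibble::tibble(unit = "surgical", capacity = 3L, occupied = 1L),
    elective_backlog = tibble::tibble(id = c(7L, 9L, 11L),
                                      request_time = c(1, 2, 3)))
  out <- reschedule_backlog(st)
  expect_identical(out$admissions$id, c(7L, 9L))
  expect_identical(out$state$elective_backlog$id, 11L)
  # congested hospital leaves the backlog untouched
  st$congested <- TRUE
  expect_identical(nrow(reschedule_backlog(st)$admissions), 0L)
  # empty backlog is a no-op
  st0 <- hospital_state()
  expect_identical(nrow(reschedule_backlog(st0)$admissions), 0L)
})
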