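# a minimal trajectory object with known content
fake_trajectory <- function(horizon = 48, episodes = NULL,
                            interventions = NULL, occupied = 300) {
  sn <- tibble::tibble(
    time_h = seq_len(horizon) - 1L,
    ed_occupied = 0L, ed_queue_len = 0L,
    inpatient_occupied = occupied, inpatient_capacity = 337L,
    inpatient_occupancy = occupied / 337, congested = FALSE)
  structure(list(
    snapshots = sn,
    patients = tibble::tibble(),
    episodes = episodes %||% tibble::tibble(
      episode = integer(), start_h = numeric(), end_h = numeric(),
      duration_h = numeric()),
    interventions = interventions %||% tibble::tibble(
      time_h = numeric(), action = factor(character(),
        levels = c("transfer", "discharge", "postpone", "divert")),
      patient = integer(), episode_start_h = numeric()),
    counters = list(), queue_divergence = FALSE,
    scenario = build_scenario(0), years = horizon / 8760, seed = 1L),
    class = "hospital_trajectory")
}

test_that("summarize_run reproduces hand arithmetic on a fixture", {
  eps <- tibble::tibble(episode = 1:2, start_h = c(5, 20),
                        end_h = c(7, 23), duration_h = c(2, 3))
  ivs <- tibble::tibble(
    time_h = c(6, 6, 21, 21), action = factor(
      c("transfer", "transfer", "transfer", "transfer"),
      levels = c("transfer", "discharge", "postpone", "divert")),
    patient = 1:4, episode_start_h = c(5, 5, 20, 20))
  tr <- fake_trajectory(episodes = eps, interventions = ivs, occupied = 327)
  m <- summarize_run(tr, window = c(0, 48))
  expect_equal(m$n_congestion_events, 2)
  expect_equal(m$max_congestion_h, 3)
  expect_equal(m$min_congestion_h, 2)
  expect_equal(m$mean_congestion_h, 2.5)
  expect_equal(m$affected_patients, 4)
  expect_equal(m$mean_occupancy_10am, 327)
  expect_equal(m$occupancy_std, 0)
})

test_that("zero-activity runs summarise to zero metrics", {
  m <- summarize_run(fake_trajectory(), window = c(0, 48))
  expect_true(all(unlist(m[c("n_congestion_events", "max_congestion_h",
                             "mean_congestion_h", "affected_patients",
                             "postponed_electives",
                             "diverted_ambulances")]) == 0))
  expect_error(summarize_run(fake_trajectory(), window = c(0, 100)),
               "horizon")
})

test_that("summaries restrict to the collection window", {
  eps <- tibble::tibble(episode = 1:2, start_h = c(5, 30),
                        end_h = c(7, 33), duration_h = c(2, 3))
  tr <- fake_trajectory(episodes = eps)
  expect_equal(summarize_run(tr, c(24, 48))$n_congestion_events, 1)
  expect_equal(summarize_run(tr, c(24, 48))$mean_congestion_h, 3)
})

test_that("replication aggregation is a field-wise mean", {
  m1 <- summarize_run(fake_trajectory(), c(0, 48)) |>
    dplyr::mutate(n_congestion_events = 100, max_congestion_h = 20)
  m2 <- m1 |> dplyr::mutate(n_congestion_events = 124, max_congestion_h = 24)
  agg <- aggregate_replications(dplyr::bind_rows(m1, m2))
  expect_equal(agg$n_congestion_events, 112)
  expect_equal(agg$max_congestion_h, 22) # mean of per-replication extrema
  expect_identical(aggregate_replications(m1), m1)
  expect_error(aggregate_replications(m1[0, ]), "at least one")
  # permutation invariance
  set.seed(8)
  ms <- dplyr::bind_rows(lapply(1:5, function(i) {
    m1 |> dplyr::mutate(n_congestion_events = stats::runif(1, 0, 200))
  }))
  expect_equal(aggregate_replications(ms),
               aggregate_replications(ms[sample(5), ]))
})

test_that("efficiency divides congestion reduction by patients affected", {
  base <- tibble::tibble(n_congestion_events = 111.75, mean_congestion_h = 6.78)
  sc22 <- tibble::tibble(n_congestion_events = 39.55, mean_congestion_h = 3.68,
                         affected_patients = 0, postponed_electives = 0,
                         diverted_ambulances = 316)
  e <- efficiency(base, sc22)
  expect_equal(e$total_affected, 316)
  expect_equal(round(e$event_efficiency, 2), 0.23)
  expect_equal(round(e$time_efficiency, 4), 0.0098)

  # identical metrics give exactly zero efficiency
  same <- base |> dplyr::mutate(affected_patients = 10,
                                postponed_electives = 0,
                                diverted_ambulances = 0)
  e0 <- efficiency(base, same)
  expect_equal(c(e0$event_efficiency, e0$time_efficiency), c(0, 0))

  # capacity-only scenarios have no defined efficiency
  none <- base |> dplyr::mutate(affected_patients = 0,
                                postponed_electives = 0,
                                diverted_ambulances = 0)
  expect_error(efficiency(base, none), "undefined")
})

test_that("efficiency is antisymmetric in the metric difference", {
  a <- tibble::tibble(n_congestion_events = 90, mean_congestion_h = 6,
                      affected_patients = 12, postponed_electives = 0,
                      diverted_ambulances = 8)
  b <- tibble::tibble(n_congestion_events = 70, mean_congestion_h = 4,
                      affected_patients = 12, postponed_electives = 0,
                      diverted_ambulances = 8)
  ab <- efficiency(a, b)
  ba <- efficiency(b, a)
  expect_equal(ab$event_efficiency, -ba$event_efficiency)
  expect_equal(ab$time_efficiency, -ba$time_efficiency)
})
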