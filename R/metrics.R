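#' Scenario metrics for one simulated run
#'
#' Restricts a trajectory to a collection window (by convention the second
#' simulated year) and computes the per-scenario summary row: mean and
#' population standard deviation of daily 10 AM inpatient occupancy, the
#' number of congestion episodes starting in the window with their maximum /
#' minimum / mean durations, and the intervention tallies — affected patients
#' (ED out-transfers plus early discharges), postponed electives and diverted
#' ambulance arrivals.
#'
#' @param trajectory A [run_simulation()] result.
#' @param window `c(start_h, end_h)` half-open hour interval inside the
#'   horizon; defaults to the final simulated year.
#' @return One-row tibble with columns `mean_occupancy_10am`, `occupancy_std`,
#'   `n_congestion_events`, `max_congestion_h`, `min_congestion_h`,
#'   `mean_congestion_h`, `affected_patients`, `postponed_electives`,
#'   `diverted_ambulances`.
#' @export
#' @examples
#' cfg <- default_config()
#' tr <- run_simulation(cfg, years = 1, seed = 7)
#' summarize_run(tr, window = c(0, 8760))
summarize_run <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "hospital_trajectory"))
  horizon <- nrow(trajectory$snapshots)
  window <- window %||% collection_window(trajectory$years)
  if (window[1] < 0 || window[2] > horizon || window[2] <= window[1]) {
    abort("collection window lies outside the simulated horizon")
  }
  occ <- snapshot_10am_occupancy(trajectory, window)
  eps <- trajectory$episodes |>
    filter(.data$start_h >= window[1], .data$start_h < window[2])
  st <- episode_stats(eps)
  iv <- trajectory$interventions |>
    filter(.data$time_h >= window[1], .data$time_h < window[2])
  n_of <- function(a) sum(iv$action == a)
  tibble(
    mean_occupancy_10am = occ$mean,
    occupancy_std = occ$sd,
    n_congestion_events = as.numeric(st$n_events),
    max_congestion_h = st$max_h,
    min_congestion_h = st$min_h,
    mean_congestion_h = st$mean_h,
    affected_patients = as.numeric(n_of("transfer") + n_of("discharge")),
    postponed_electives = as.numeric(n_of("postpone")),
    diverted_ambulances = as.numeric(n_of("divert")))
}

#' Average scenario metrics over replications
#'
#' Field-wise arithmetic mean over replication rows; the maximum and minimum
#' congestion durations are therefore aggregated as the mean of the
#' per-replication extrema, so fractional values are expected.
#'
#' @param metrics A tibble of per-replication rows from [summarize_run()]
#'   (extra grouping columns such as `replication` or `seed` are dropped).
#' @return One-row tibble in the same shape.
#' @export
aggregate_replications <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    abort("`metrics` must contain at least one replication")
  }
  cols <- c("mean_occupancy_10am", "occupancy_std", "n_congestion_events",
            "max_congestion_h", "min_congestion_h", "mean_congestion_h",
            "affected_patients", "postponed_electives", "diverted_ambulances")
  stopifnot(all(cols %in% names(metrics)))
  metrics |> summarise(across(all_of(cols), mean))
}

#' Decongestion efficiency per affected patient
#'
#' The efficiency of a scenario is its congestion reduction relative to the
#' baseline, divided by the number of patients its interventions touched:
#' `total_affected = affected_patients + diverted_ambulances +
#' postponed_electives`, `event_efficiency = (baseline events - scenario
#' events) / total_affected` and `time_efficiency = (baseline mean congestion
#' hours - scenario mean congestion hours) / total_affected`. Efficiencies
#' are negative when a scenario worsens congestion, and undefined (an error)
#' for capacity-only scenarios that affect no patients.
#'
#' @param baseline One-row metrics tibble for the uncontrolled baseline
#'   (scenario 0 aggregate).
#' @param scenario One-row metrics tibble for the scenario of interest.
#' @return One-row tibble: `event_efficiency`, `time_efficiency`,
#'   `total_affected`.
#' @export
#' @examples
#' base <- tibble::tibble(n_congestion_events = 111.75,
#'                        mean_congestion_h = 6.78)
#' div2 <- tibble::tibble(n_congestion_events = 39.55,
#'                        mean_congestion_h = 3.68, affected_patients = 0,
#'                        postponed_electives = 0, diverted_ambulances = 316)
#' efficiency(base, div2)
efficiency <- function(baseline, scenario) {
  stopifnot(is.data.frame(baseline), nrow(baseline) == 1L,
            is.data.frame(scenario), nrow(scenario) == 1L)
  total <- sum(scenario$affected_patients %||% 0,
               scenario$postponed_electives %||% 0,
               scenario$diverted_ambulances %||% 0, na.rm = TRUE)
  if (total <= 0) {
    abort("efficiency is undefined: the scenario affected no patients")
  }
  tibble(
    event_efficiency =
      (baseline$n_congestion_events - scenario$n_congestion_events) / total,
    time_efficiency =
      (baseline$mean_congestion_h - scenario$mean_congestion_h) / total,
    total_affected = total)
}
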