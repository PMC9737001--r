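#' Run the whole-hospital patient-flow simulation
#'
#' Moves patient agents through ED queue, ED treatment, inpatient admission
#' (AMU / medical / surgical) or discharge, and elective patients into
#' surgical beds, as a continuous-time discrete-event simulation with state
#' snapshots on the hour. Congestion is checked at every hourly snapshot; the
#' scenario's patient-level actions are applied one hour after an episode
#' begins (if it is still ongoing), and its capacity deltas are applied
#' permanently from the start of the run (or only during episodes when the
#' configuration sets `episodic_capacity`).
#'
#' Admitted ED patients board in their ED bed until an inpatient bed frees;
#' medical admissions pass through the AMU when an AMU bed is free. All
#' randomness is drawn up front from `seed`, so a run is fully deterministic
#' given `(config, scenario, seed)` and scenarios compared under the same
#' seed share common random numbers.
#'
#' @param config A [hospital_config()].
#' @param scenario A [build_scenario()] result (default: baseline).
#' @param years Simulated years; the horizon is `years * 8760` hours
#'   (fractional years give reduced-scale runs).
#' @param seed Integer seed.
#' @param patients Optional pre-built patient table (internal use, for common
#'   random numbers across scenarios); normally left `NULL`.
#' @return A list of class `hospital_trajectory` with elements
#'   \describe{
#'     \item{snapshots}{hourly tibble: `time_h`, `ed_occupied`,
#'       `ed_queue_len`, `inpatient_occupied`, `inpatient_capacity`,
#'       `inpatient_occupancy`, `congested`.}
#'     \item{patients}{per-patient tibble with arrival attributes, journey
#'       milestones (`t_ed_bed`, `t_admit_request`, `t_ward_bed`, `t_exit`)
#'       and final `disposition`.}
#'     \item{episodes}{congestion episodes (`start_h`, `end_h`,
#'       `duration_h`).}
#'     \item{interventions}{one row per intervention action with `time_h`,
#'       `action`, `patient`, `episode_start_h`.}
#'     \item{counters}{whole-run action totals.}
#'     \item{queue_divergence}{`TRUE` when the ED queue grows without bound
#'       (infeasible configuration).}
#'   }
#' @export
#' @examples
#' cfg <- default_config()
#' tr <- run_simulation(cfg, build_scenario(0), years = 1, seed = 42)
#' tr
run_simulation <- function(config, scenario = build_scenario(0), years = 2L,
                           seed = 1L, patients = NULL) {
  stopifnot(inherits(config, "hospital_config"))
  if (!inherits(scenario, "scenario_config")) {
    scenario <- build_scenario(scenario)
  }
  if (!is.numeric(years) || years <= 0) abort("`years` must be positive")
  horizon <- as.integer(round(years * 8760))

  if (is.null(patients)) {
    patients <- build_patient_table(config, horizon, seed)
  }
  cap <- c(config$ed_admission_beds, config$amu_beds, config$medical_beds,
           config$surgical_beds)
  delta <- as.integer(scenario$capacity_deltas)
  if (any(cap + delta < 0)) {
    abort("scenario removes more beds than the unit has")
  }

  thr <- config$thresholds
  raw <- .sim_core(
    t_arr = patients$time_h,
    stream = as.integer(patients$stream == "elective"),
    mode = as.integer(patients$mode == "ambulance") +
      2L * as.integer(patients$mode == "elective"),
    triage = as.integer(patients$triage),
    admitted = as.integer(patients$admitted),
    cls = as.integer(!is.na(patients$class) & patients$class == "surgical"),
    ed_los = patients$ed_los,
    amu_los = patients$amu_los,
    ward_los = patients$ward_los,
    cap = as.integer(cap), delta = delta,
    episodic = config$episodic_capacity,
    thr_ed = thr$ed_min_occupied, thr_occ = thr$inpatient_min_occupancy,
    thr_queue = thr$queue_min, conjunctive = thr$conjunctive,
    actions = as.integer(c(scenario$transfer_ed_n,
                           scenario$discharge_inpatient_n,
                           scenario$discharge_medical_n,
                           scenario$discharge_surgical_n,
                           scenario$postpone_elective_n,
                           scenario$divert_ambulance_n)),
    allow_fallback = config$allow_discharge_fallback,
    horizon = horizon,
    dw_start = config$discharge_window_start %||% 0,
    dw_len = config$discharge_window_hours %||% 0)

  sn <- raw$snapshots
  snapshots <- tibble(
    time_h = seq_along(sn$ed_occupied) - 1L,
    ed_occupied = sn$ed_occupied,
    ed_queue_len = sn$ed_queue_len,
    inpatient_occupied = sn$inpatient_occupied,
    inpatient_capacity = sn$inpatient_capacity,
    inpatient_occupancy = sn$inpatient_occupied / sn$inpatient_capacity,
    congested = as.logical(sn$congested))

  dispo_levels <- c("in_system", "discharged", "completed", "transferred_out",
                    "diverted", "early_discharged", "postponed")
  pt <- raw$patients
  patients_out <- patients |>
    mutate(t_ed_bed = pt$t_ed_bed,
           t_admit_request = pt$t_admit_request,
           t_ward_bed = pt$t_ward_bed,
           t_exit = pt$t_exit,
           disposition = factor(dispo_levels[pt$disposition + 1L],
                                levels = dispo_levels))

  episodes <- tibble(start_h = as.numeric(raw$episodes$start_h),
                     end_h = as.numeric(raw$episodes$end_h)) |>
    mutate(duration_h = .data$end_h - .data$start_h,
           episode = row_number(), .before = 1)

  action_levels <- c("transfer", "discharge", "postpone", "divert")
  interventions <- tibble(
    time_h = raw$interventions$time_h,
    action = factor(action_levels[raw$interventions$action],
                    levels = action_levels),
    patient = raw$interventions$patient + 1L,
    episode_start_h = as.numeric(raw$interventions$episode_start_h))

  # divergence: the queue never drains over the final fifth of the horizon
  # and ends long (a stable-but-bursty queue returns to ~0 regularly)
  q <- snapshots$ed_queue_len
  last_fifth <- tail(q, max(1L, length(q) %/% 5L))
  divergence <- length(q) > 0 &&
    tail(q, 1) > max(50, 5 * (cap[1] + delta[1])) &&
    min(last_fifth) > 20
  if (raw$capacity_violation) {
    warn("bed occupancy exceeded capacity during the run (engine defect?)")
  }
  if (divergence) {
    warn("ED queue appears to grow without bound; configuration is infeasible")
  }

  structure(list(snapshots = snapshots, patients = patients_out,
                 episodes = episodes, interventions = interventions,
                 counters = raw$counters, queue_divergence = divergence,
                 scenario = scenario, years = years, seed = seed),
            class = "hospital_trajectory")
}

#' @export
print.hospital_trajectory <- function(x, ...) {
  cat(sprintf("<hospital_trajectory> scenario %d (%s), %.3g year(s), seed %d\n",
              x$scenario$id, x$scenario$label, x$years, x$seed))
  cat(sprintf("  %d patients, %d congestion episodes, %d hourly snapshots\n",
              nrow(x$patients), nrow(x$episodes), nrow(x$snapshots)))
  if (x$queue_divergence) cat("  WARNING: queue divergence flagged\n")
  invisible(x)
}

#' Daily 10 AM inpatient occupancy
#'
#' Mean and standard deviation of total inpatient bed occupancy at 10:00 each
#' day within a collection window. The standard deviation is the population
#' form (divisor n).
#'
#' @param trajectory A [run_simulation()] result (or its snapshots tibble).
#' @param window `c(start_h, end_h)`: half-open hour interval, e.g.
#'   `c(8760, 17520)` for the second simulated year.
#' @return One-row tibble: `mean`, `sd`, `n_days`.
#' @export
snapshot_10am_occupancy <- function(trajectory,
                                    window = NULL) {
  sn <- if (inherits(trajectory, "hospital_trajectory")) {
    trajectory$snapshots
  } else trajectory
  window <- window %||% c(0, nrow(sn))
  if (window[2] <= window[1] ||
      window[1] < sn$time_h[1] || window[2] > tail(sn$time_h, 1) + 1) {
    abort("collection window is empty or outside the simulated horizon")
  }
  occ <- sn |>
    filter(.data$time_h >= window[1], .data$time_h < window[2],
           .data$time_h %% 24 == 10)
  if (nrow(occ) == 0L) abort("no 10 AM snapshots inside the window")
  x <- occ$inpatient_occupied
  tibble(mean = mean(x),
         sd = sqrt(mean((x - mean(x))^2)),
         n_days = length(x))
}

# hour window of the final collection year
collection_window <- function(years, warmup_years = years - 1) {
  c(warmup_years * 8760, years * 8760)
}

#' Write trajectory artefacts to disk
#'
#' Exports hourly snapshots (`time_h`, `ed_occupied`, `ed_queue_len`,
#' `inpatient_occupancy`), the congestion episodes, and a long-form
#' milestone event log (one row per patient milestone).
#'
#' @param trajectory A [run_simulation()] result.
#' @param dir Output directory (created if missing).
#' @param run_id Identifier used in file names and the episodes CSV.
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(trajectory, dir, run_id = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    trajectory$snapshots |>
      select("time_h", "ed_occupied", "ed_queue_len", "inpatient_occupancy"),
    file.path(dir, paste0(run_id, "_snapshots.csv")))
  readr::write_csv(
    trajectory$episodes |>
      mutate(run_id = run_id, .before = 1),
    file.path(dir, paste0(run_id, "_episodes.csv")))
  readr::write_csv(event_log(trajectory),
                   file.path(dir, paste0(run_id, "_events.csv")))
  invisible(dir)
}

#' Long-form milestone event log
#'
#' @param trajectory A [run_simulation()] result.
#' @return Tibble with `patient_id`, `event`, `time_h`, ordered by time.
#' @export
event_log <- function(trajectory) {
  p <- trajectory$patients
  long <- bind_rows(
    tibble(patient_id = p$id, event = "arrival", time_h = p$time_h),
    tibble(patient_id = p$id, event = "ed_bed_start", time_h = p$t_ed_bed),
    tibble(patient_id = p$id, event = "admit_request",
           time_h = p$t_admit_request),
    tibble(patient_id = p$id, event = "ward_bed_start", time_h = p$t_ward_bed),
    tibble(patient_id = p$id, event = as.character(p$disposition),
           time_h = p$t_exit)
  )
  long |> filter(!is.na(.data$time_h)) |> arrange(.data$time_h, .data$patient_id)
}
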