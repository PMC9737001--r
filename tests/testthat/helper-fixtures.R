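# Shared fixtures: everything is generated in code at test time.

# Independent run-length scanner used as the episode-extraction oracle:
# a plain index walk, deliberately unrelated to the rle-based implementation.
brute_force_episodes <- function(flags, start_hour = 0) {
  out <- list()
  i <- 1L
  n <- length(flags)
  while (i <= n) {
    if (isTRUE(flags[i])) {
      j <- i
      while (j <= n && isTRUE(flags[j])) j <- j + 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        start_h = start_hour + i - 1,
        end_h = start_hour + j - 1,
        duration_h = as.numeric(j - i))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start_h = numeric(), end_h = numeric(),
                          duration_h = numeric()))
  }
  dplyr::bind_rows(out)
}

# A small hospital that congests often (lenient thresholds), for fast
# engine-rule tests: ~50 ED arrivals/day on 6 ED + 40 inpatient beds.
busy_little_hospital <- function(...) {
  default_config(
    ed_admission_beds = 6L, amu_beds = 4L, medical_beds = 20L,
    surgical_beds = 16L, ed_arrivals_per_day = 50, electives_per_week = 20,
    arrival_multiplier = 1,
    los_means_h = c(ed_treatment = 1.2, amu = 9, medical = 33,
                    surgical = 33, elective_surgical = 29),
    los_sdlogs = c(ed_treatment = 0.5, amu = 0.5, medical = 0.6,
                   surgical = 0.6, elective_surgical = 0.5),
    thresholds = congestion_thresholds(ed_min_occupied = 5,
                                       inpatient_min_occupancy = 0.9,
                                       queue_min = 4),
    discharge_window_hours = 0,
    ...
  )
}

# Hand-built patient table for single-trace tests (one row per patient).
trace_patients <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      id = r$id, time_h = r$time_h, stream = r$stream %||% "ed",
      mode = r$mode %||% "walkin", triage = r$triage %||% 3L,
      admitted = r$admitted %||% FALSE, class = r$class %||% NA_character_,
      ed_los = r$ed_los %||% 0, amu_los = r$amu_los %||% 0,
      ward_los = r$ward_los %||% 0)
  })) |>
    dplyr::arrange(time_h)
}

# Empty hospital (zero arrival intensity), hand-trace friendly.
silent_config <- function(...) {
  default_config(ed_arrivals_per_day = 0, electives_per_week = 0,
                 discharge_window_hours = 0, ...)
}

`%||%` <- rlang::`%||%`
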