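#' Build a hospital configuration
#'
#' A `hospital_config` bundles everything the simulator needs to know about a
#' hospital: bed capacities for the ED admission side, the acute medical unit
#' (AMU) and the medical and surgical wards; hour-of-day by day-of-week
#' arrival intensity grids for the ambulance, walk-in and elective streams;
#' the triage mix; per-triage admission probabilities; the medical/surgical
#' class split among admitted patients; and log-normal length-of-stay
#' parameters per patient class.
#'
#' Arrival intensities are built from a daily ED volume, a 24-point
#' hour-of-day shape, a 7-point day-of-week shape (Monday first) and a global
#' `arrival_multiplier`, then split into ambulance and walk-in streams by
#' `ambulance_fraction`. Electives arrive only in the configured weekday
#' admission window.
#'
#' The medical/surgical class split among admitted ED patients is derived
#' from `med_surg_ratio` so that expected medical admissions exceed expected
#' surgical admissions (emergency plus elective) by that ratio.
#'
#' @param ed_admission_beds Beds on the ED admission side (default 18).
#' @param amu_beds,medical_beds,surgical_beds Inpatient unit capacities.
#' @param ed_arrivals_per_day Mean daily ED presentations before the
#'   multiplier is applied.
#' @param hour_shape Relative hour-of-day intensity, length 24 (hour 0-23);
#'   normalised internally to mean 1.
#' @param dow_shape Relative day-of-week intensity, length 7, Monday first;
#'   normalised internally to mean 1.
#' @param arrival_multiplier Global scaling of every arrival stream. The
#'   default is the committed calibration of the synthetic hospital.
#' @param ambulance_fraction Proportion of ED arrivals that come by
#'   ambulance, in `[0, 1]`.
#' @param electives_per_week Scheduled elective surgical admissions per week.
#' @param elective_days Days of week with elective admissions (1 = Monday).
#' @param elective_hours Hours of day (0-23) of the elective admission window.
#' @param triage_pmf Probability mass over triage scores 1-5 (1 = most
#'   urgent); must sum to 1.
#' @param admit_probability Probability that an ED patient is admitted, per
#'   triage score (length 5).
#' @param med_surg_ratio Target ratio of expected medical to surgical
#'   admissions (default 1.173, i.e. 17.3% more medical patients).
#' @param los_means_h Named mean lengths of stay in hours for classes
#'   `ed_treatment`, `amu`, `medical`, `surgical`, `elective_surgical`.
#' @param los_sdlogs Named log-scale standard deviations for the same classes.
#' @param thresholds A [congestion_thresholds()] object.
#' @param discharge_window_start,discharge_window_hours Daily inpatient
#'   discharge window (default 10:00 for 8 hours): a ward stay whose raw end
#'   falls outside the window is extended to the next window, reproducing the
#'   morning-discharge / evening-fill rhythm that makes hospital congestion
#'   episodic. Set `discharge_window_hours = 0` to disable.
#' @param allow_discharge_fallback If `TRUE`, early-discharge interventions
#'   may fall back to triage-3 inpatients once the triage >= 4 pool is
#'   exhausted. Default `FALSE` (strict rule).
#' @param episodic_capacity If `TRUE`, bed-resizing scenarios open/close beds
#'   only while an episode is active; default `FALSE` (permanent resizing).
#'
#' @return A list of class `hospital_config`. The `arrival_rates` element is
#'   a named list of three 24 x 7 intensity matrices (`ambulance`, `walkin`,
#'   `elective`), rows = hour of day, columns = Monday..Sunday; `class_split`
#'   is the derived probability that an admitted ED patient is medical.
#' @seealso [default_config()], [sample_arrivals()], [run_simulation()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$ed_admission_beds
#' rowSums(cfg$arrival_rates$walkin)
hospital_config <- function(ed_admission_beds = 18L,
                            amu_beds = 24L,
                            medical_beds = 170L,
                            surgical_beds = 143L,
                            ed_arrivals_per_day = 182,
                            hour_shape = default_hour_shape(),
                            dow_shape = default_dow_shape(),
                            arrival_multiplier = 0.88,
                            ambulance_fraction = 0.30,
                            electives_per_week = 84,
                            elective_days = 1:5,
                            elective_hours = 7:10,
                            triage_pmf = c(0.02, 0.13, 0.35, 0.35, 0.15),
                            admit_probability = c(0.90, 0.65, 0.45, 0.25, 0.10),
                            med_surg_ratio = 1.173,
                            los_means_h = c(ed_treatment = 1.3, amu = 24,
                                            medical = 84, surgical = 96,
                                            elective_surgical = 84),
                            los_sdlogs = c(ed_treatment = 0.5, amu = 0.6,
                                           medical = 0.7, surgical = 0.7,
                                           elective_surgical = 0.6),
                            thresholds = congestion_thresholds(),
                            discharge_window_start = 10,
                            discharge_window_hours = 8,
                            allow_discharge_fallback = FALSE,
                            episodic_capacity = FALSE) {
  beds <- c(ed_admission_beds, amu_beds, medical_beds, surgical_beds)
  if (any(beds <= 0) || any(beds != round(beds))) {
    abort("all bed counts must be positive integers")
  }
  if (length(hour_shape) != 24L || any(hour_shape < 0)) {
    abort("`hour_shape` must be 24 non-negative values")
  }
  if (length(dow_shape) != 7L || any(dow_shape < 0)) {
    abort("`dow_shape` must be 7 non-negative values")
  }
  if (abs(sum(triage_pmf) - 1) > 1e-9 || length(triage_pmf) != 5L ||
      any(triage_pmf < 0)) {
    abort("`triage_pmf` must be 5 non-negative probabilities summing to 1")
  }
  if (length(admit_probability) != 5L || any(admit_probability < 0) ||
      any(admit_probability > 1)) {
    abort("`admit_probability` must be 5 probabilities")
  }
  if (ambulance_fraction < 0 || ambulance_fraction > 1) {
    abort("`ambulance_fraction` must lie in [0, 1]")
  }
  cls <- c("ed_treatment", "amu", "medical", "surgical", "elective_surgical")
  if (!all(cls %in% names(los_means_h)) || !all(cls %in% names(los_sdlogs))) {
    abort(paste0("`los_means_h` and `los_sdlogs` must name the classes: ",
                 paste(cls, collapse = ", ")))
  }
  if (any(los_means_h[cls] <= 0) || any(los_sdlogs[cls] < 0)) {
    abort("length-of-stay means must be positive and sdlogs non-negative")
  }

  hour_shape <- hour_shape / mean(hour_shape)
  dow_shape <- dow_shape / mean(dow_shape)

  # ED intensity grid (arrivals/h), then the ambulance/walk-in split
  ed_grid <- arrival_multiplier * (ed_arrivals_per_day / 24) *
    outer(hour_shape, dow_shape)
  elec_grid <- matrix(0, 24, 7)
  if (length(elective_days) > 0 && length(elective_hours) > 0) {
    per_cell <- electives_per_week /
      (length(elective_days) * length(elective_hours))
    elec_grid[elective_hours + 1L, elective_days] <-
      arrival_multiplier * per_cell
  }
  dimnames(ed_grid) <- dimnames(elec_grid) <-
    list(hour = 0:23, day = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))

  # class split implied by the medical:surgical admissions ratio
  p_admit <- sum(triage_pmf * admit_probability)
  adm_per_day <- sum(ed_grid) / 7 * p_admit
  elec_per_day <- sum(elec_grid) / 7
  class_split <- med_surg_ratio * (adm_per_day + elec_per_day) /
    (adm_per_day * (1 + med_surg_ratio))
  if (is.nan(class_split)) class_split <- 0.5
  if (class_split > 1) {
    warn("medical/surgical target ratio unattainable; capping class_split at 1")
    class_split <- 1
  }

  los_params <- lapply(setNames(cls, cls), function(cl) {
    sdl <- unname(los_sdlogs[cl])
    c(meanlog = log(unname(los_means_h[cl])) - sdl^2 / 2, sdlog = sdl)
  })

  structure(list(
    ed_admission_beds = as.integer(ed_admission_beds),
    amu_beds = as.integer(amu_beds),
    medical_beds = as.integer(medical_beds),
    surgical_beds = as.integer(surgical_beds),
    arrival_rates = list(
      ambulance = ed_grid * ambulance_fraction,
      walkin = ed_grid * (1 - ambulance_fraction),
      elective = elec_grid
    ),
    ambulance_fraction = ambulance_fraction,
    admit_probability = setNames(admit_probability, paste0("triage", 1:5)),
    class_split = class_split,
    med_surg_ratio = med_surg_ratio,
    triage_pmf = setNames(triage_pmf, paste0("triage", 1:5)),
    los_params = los_params[setdiff(cls, "ed_treatment")],
    ed_treatment_params = los_params[["ed_treatment"]],
    arrival_multiplier = arrival_multiplier,
    thresholds = thresholds,
    discharge_window_start = discharge_window_start,
    discharge_window_hours = discharge_window_hours,
    allow_discharge_fallback = isTRUE(allow_discharge_fallback),
    episodic_capacity = isTRUE(episodic_capacity)
  ), class = "hospital_config")
}

#' Default synthetic hospital configuration
#'
#' Returns the committed default configuration of the synthetic tertiary
#' hospital: an 18-bed ED admission side and 337 inpatient beds (AMU 24,
#' medical 170, surgical 143), arrival and length-of-stay parameters
#' calibrated so that the uncontrolled baseline produces a mean 10 AM
#' inpatient occupancy of roughly 327 beds and congestion episodes at a rate
#' of one to three per week.
#'
#' @param seed Integer stored as the configuration's default simulation seed;
#'   the configuration itself is deterministic.
#' @param ... Overrides passed to [hospital_config()].
#' @return A `hospital_config`.
#' @export
#' @examples
#' cfg <- default_config(1)
#' cfg$amu_beds + cfg$medical_beds + cfg$surgical_beds  # 337
default_config <- function(seed = 1L, ...) {
  cfg <- hospital_config(...)
  cfg$seed <- as.integer(seed)
  cfg
}

# Afternoon-peaked ED presentation profile (relative, normalised to mean 1).
default_hour_shape <- function() {
  c(0.55, 0.45, 0.40, 0.35, 0.35, 0.40, 0.50, 0.70, 0.95, 1.15, 1.30, 1.40,
    1.40, 1.35, 1.30, 1.30, 1.30, 1.35, 1.40, 1.35, 1.20, 1.00, 0.85, 0.70)
}

default_dow_shape <- function() {
  c(1.06, 1.02, 1.00, 0.99, 1.01, 0.95, 0.97)
}

#' @export
print.hospital_config <- function(x, ...) {
  inp <- x$amu_beds + x$medical_beds + x$surgical_beds
  cat("<hospital_config>\n")
  cat(sprintf("  ED admission beds: %d | AMU %d + medical %d + surgical %d = %d inpatient beds\n",
              x$ed_admission_beds, x$amu_beds, x$medical_beds,
              x$surgical_beds, inp))
  cat(sprintf("  ED arrivals/day: %.1f (%.0f%% ambulance), electives/week: %.1f\n",
              sum(x$arrival_rates$ambulance + x$arrival_rates$walkin) / 7,
              100 * x$ambulance_fraction, sum(x$arrival_rates$elective)))
  cat(sprintf("  class split P(medical | admitted) = %.3f (target ratio %.3f)\n",
              x$class_split, x$med_surg_ratio))
  cat(sprintf("  arrival multiplier: %.4f\n", x$arrival_multiplier))
  invisible(x)
}

#' Read and write hospital configurations as YAML
#'
#' Serialises a [hospital_config()] to YAML with keys matching the
#' configuration fields, and reads one back.
#'
#' @param config A `hospital_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `hospital_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hospital_config"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$arrival_rates <- lapply(x$arrival_rates, function(m) {
    list(dim = dim(m), values = as.vector(m))
  })
  # named vectors must become maps, or YAML drops the names
  x$los_params <- lapply(x$los_params, as.list)
  x$ed_treatment_params <- as.list(x$ed_treatment_params)
  x$admit_probability <- as.list(x$admit_probability)
  x$triage_pmf <- as.list(x$triage_pmf)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$arrival_rates <- lapply(x$arrival_rates, function(g) {
    m <- matrix(g$values, g$dim[1], g$dim[2])
    dimnames(m) <- list(hour = 0:23,
                        day = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
    m
  })
  x$thresholds <- do.call(congestion_thresholds, x$thresholds)
  x$admit_probability <- unlist(x$admit_probability)
  x$triage_pmf <- unlist(x$triage_pmf)
  x$los_params <- lapply(x$los_params, unlist)
  x$ed_treatment_params <- unlist(x$ed_treatment_params)
  structure(x, class = "hospital_config")
}
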