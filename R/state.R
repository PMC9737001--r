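#' Construct an explicit hospital state
#'
#' A lightweight, fully tabular snapshot of the hospital at one instant, used
#' as the reference semantics for the bed-request and intervention policies
#' (the simulation engine applies the same rules internally). All patient
#' collections are tibbles.
#'
#' @param time Simulation time in hours.
#' @param units Tibble with columns `unit`, `capacity`, `occupied`.
#' @param queues Named list of per-unit waiting tibbles, each with columns
#'   `id`, `triage`, `request_time` (and optionally `kind`: `"ed_boarder"` or
#'   `"elective"` for the surgical queue).
#' @param inpatients Tibble of patients currently in beds: `id`, `unit`,
#'   `triage`, `remaining_h`.
#' @param elective_backlog Tibble of postponed electives: `id`,
#'   `request_time`.
#' @param congested Is the hospital currently inside a congestion episode?
#' @return A list of class `hospital_state`.
#' @export
hospital_state <- function(time = 0,
                           units = tibble(
                             unit = c("ed", "amu", "medical", "surgical"),
                             capacity = c(18L, 24L, 170L, 143L),
                             occupied = c(0L, 0L, 0L, 0L)),
                           queues = list(),
                           inpatients = tibble(id = integer(),
                                               unit = character(),
                                               triage = integer(),
                                               remaining_h = numeric()),
                           elective_backlog = tibble(id = integer(),
                                                     request_time = numeric()),
                           congested = FALSE) {
  stopifnot(all(c("unit", "capacity", "occupied") %in% names(units)),
            all(units$occupied >= 0), all(units$occupied <= units$capacity))
  for (u in units$unit) {
    if (is.null(queues[[u]])) {
      queues[[u]] <- tibble(id = integer(), triage = integer(),
                            request_time = numeric())
    }
  }
  structure(list(time = time, units = units, queues = queues,
                 inpatients = inpatients,
                 elective_backlog = elective_backlog,
                 congested = congested),
            class = "hospital_state")
}

#' Request a bed in a unit
#'
#' Seats the patient if the unit has a free bed, otherwise queues them. The
#' queue is served most-urgent first: triage ascending, ties by request time
#' then id.
#'
#' @param state A [hospital_state()].
#' @param patient One-row tibble (or named list) with `id`, `triage`, and
#'   optionally `remaining_h` (used if seated).
#' @param unit Unit name present in `state$units`.
#' @return A list with `state` (updated) and `outcome` (`"seated"` or
#'   `"queued"`).
#' @export
#' @examples
#' st <- hospital_state(units = tibble::tibble(unit = "ward", capacity = 1L,
#'                                             occupied = 0L))
#' request_bed(st, list(id = 1L, triage = 3L), "ward")$outcome  # seated
request_bed <- function(state, patient, unit) {
  stopifnot(inherits(state, "hospital_state"))
  if (!unit %in% state$units$unit) {
    abort(paste0("unknown unit: '", unit, "'"))
  }
  patient <- as.list(patient)
  remaining <- if (is.null(patient$remaining_h)) NA_real_ else
    patient$remaining_h
  if (patient$id %in% state$inpatients$id) {
    abort(paste0("patient ", patient$id,
                 " already holds a bed; double allocation"))
  }
  i <- which(state$units$unit == unit)
  if (state$units$occupied[i] < state$units$capacity[i]) {
    state$units$occupied[i] <- state$units$occupied[i] + 1L
    state$inpatients <- bind_rows(
      state$inpatients,
      tibble(id = patient$id, unit = unit, triage = patient$triage,
             remaining_h = remaining))
    list(state = state, outcome = "seated")
  } else {
    state$queues[[unit]] <- bind_rows(
      state$queues[[unit]],
      tibble(id = patient$id, triage = patient$triage,
             request_time = state$time)) |>
      arrange(.data$triage, .data$request_time, .data$id)
    list(state = state, outcome = "queued")
  }
}

#' Apply a scenario's per-episode actions to a state
#'
#' Reference implementation of the congestion-triggered patient-level
#' actions, called one hour after episode onset:
#' \itemize{
#'   \item transfers remove up to `transfer_ed_n` admitted-side ED boarders,
#'     least urgent (highest triage) first, longest-boarding first within a
#'     triage score;
#'   \item early discharges select inpatients with triage >= 4,
#'     nearest-to-scheduled-discharge first within that set (optionally
#'     falling back to triage 3 when the configuration allows);
#'   \item postponements move up to `postpone_elective_n` waiting
#'     (not-yet-admitted) electives to the backlog, most recently scheduled
#'     first;
#'   \item diversions set a quota consumed by the next ambulance arrivals
#'     within the episode (represented here by the returned
#'     `divert_quota`).
#' }
#' When fewer eligible patients exist than requested, all eligible patients
#' are acted on and the shortfall is visible in the record.
#'
#' @param state A [hospital_state()] with an `ed_boarders` queue element
#'   (tibble `id`, `triage`, `request_time`) and `waiting_electives` element
#'   (tibble `id`, `request_time`).
#' @param scenario A [build_scenario()] result.
#' @param episode One-row tibble with `start_h` (used for the record).
#' @return List with `state` (updated), `record` (tibble `action`, `id`,
#'   `time_h`) and `divert_quota`.
#' @export
apply_episode_actions <- function(state, scenario, episode) {
  stopifnot(inherits(state, "hospital_state"),
            inherits(scenario, "scenario_config"))
  now <- state$time
  rec <- list()

  boarders <- state$queues[["ed_boarders"]] %||%
    tibble(id = integer(), triage = integer(), request_time = numeric())
  if (scenario$transfer_ed_n > 0 && nrow(boarders) > 0) {
    take <- boarders |>
      arrange(desc(.data$triage), .data$request_time, .data$id) |>
      head(scenario$transfer_ed_n)
    state$queues[["ed_boarders"]] <-
      boarders |> filter(!.data$id %in% take$id)
    rec[[length(rec) + 1L]] <-
      tibble(action = "transfer", id = take$id, time_h = now)
  }

  pick_discharge <- function(pool, k) {
    if (k <= 0 || nrow(pool) == 0) return(pool[0, ])
    elig <- pool |> filter(.data$triage >= 4)
    if (isTRUE(state$allow_fallback) && nrow(elig) < k) {
      elig <- bind_rows(elig, pool |> filter(.data$triage == 3))
    }
    elig |>
      mutate(tier = ifelse(.data$triage >= 4, 0L, 1L)) |>
      arrange(.data$tier, .data$remaining_h, .data$id) |>
      select(-"tier") |>
      head(k)
  }
  inp <- state$inpatients
  med_units <- c("amu", "medical")
  d1 <- pick_discharge(inp |> filter(.data$unit %in% med_units),
                       scenario$discharge_medical_n)
  inp <- inp |> filter(!.data$id %in% d1$id)
  d2 <- pick_discharge(inp |> filter(.data$unit == "surgical"),
                       scenario$discharge_surgical_n)
  inp <- inp |> filter(!.data$id %in% d2$id)
  d3 <- pick_discharge(inp, scenario$discharge_inpatient_n)
  dis <- bind_rows(d1, d2, d3)
  if (nrow(dis) > 0) {
    for (u in unique(dis$unit)) {
      i <- which(state$units$unit == u)
      state$units$occupied[i] <- state$units$occupied[i] -
        sum(dis$unit == u)
    }
    state$inpatients <- state$inpatients |> filter(!.data$id %in% dis$id)
    rec[[length(rec) + 1L]] <-
      tibble(action = "discharge", id = dis$id, time_h = now)
  }

  waiting <- state$queues[["waiting_electives"]] %||%
    tibble(id = integer(), request_time = numeric())
  if (scenario$postpone_elective_n > 0 && nrow(waiting) > 0) {
    take <- waiting |>
      arrange(desc(.data$request_time), desc(.data$id)) |>
      head(scenario$postpone_elective_n)
    state$queues[["waiting_electives"]] <-
      waiting |> filter(!.data$id %in% take$id)
    state$elective_backlog <- bind_rows(
      state$elective_backlog,
      take |> select("id", "request_time"))
    rec[[length(rec) + 1L]] <-
      tibble(action = "postpone", id = take$id, time_h = now)
  }

  record <- if (length(rec)) list_rbind(rec) else
    tibble(action = character(), id = integer(), time_h = numeric())
  list(state = state, record = record,
       divert_quota = scenario$divert_ambulance_n)
}

#' Reschedule the elective backlog
#'
#' While the hospital is not congested and surgical beds are free, the oldest
#' backlog patient is admitted (FIFO) before any newly arriving elective.
#'
#' @param state A [hospital_state()].
#' @return List with `state` (updated) and `admissions` (tibble of admitted
#'   backlog patients).
#' @export
#' @examples
#' st <- hospital_state(
#'   units = tibble::tibble(unit = "surgical", capacity = 2L, occupied = 1L),
#'   elective_backlog = tibble::tibble(id = c(7L, 9L),
#'                                     request_time = c(1, 2)))
#' reschedule_backlog(st)$admissions$id  # 7
reschedule_backlog <- function(state) {
  stopifnot(inherits(state, "hospital_state"))
  adm <- state$elective_backlog[0, ]
  if (state$congested) return(list(state = state, admissions = adm))
  i <- which(state$units$unit == "surgical")
  if (length(i) == 0) return(list(state = state, admissions = adm))
  while (state$units$occupied[i] < state$units$capacity[i] &&
         nrow(state$elective_backlog) > 0) {
    nxt <- state$elective_backlog[1, ]
    state$elective_backlog <- state$elective_backlog[-1, ]
    state$units$occupied[i] <- state$units$occupied[i] + 1L
    state$inpatients <- bind_rows(
      state$inpatients,
      tibble(id = nxt$id, unit = "surgical", triage = NA_integer_,
             remaining_h = NA_real_))
    adm <- bind_rows(adm, nxt)
  }
  list(state = state, admissions = adm)
}
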