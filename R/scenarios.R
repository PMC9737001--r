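#' The catalogue of decongestion scenarios
#'
#' Twenty-seven scenarios: the do-nothing baseline (0); permanent bed
#' right-sizing of the ED (1-3: +2/+4/+6), the AMU (4-6: +2/+4/+6) and the
#' inpatient wards with total beds unchanged (7-9 move 2/4/6 surgical beds to
#' medical, 10-12 the reverse); and congestion-triggered patient-level
#' actions activated one hour after episode onset — ED out-transfers (13-15:
#' 2/4/6 per episode), early inpatient discharges restricted to triage >= 4
#' (16-18: 2/4/6), elective-surgery postponements into a reschedulable
#' backlog (19-21: 2/4/6), ambulance diversions (22-23: 2/4), and
#' combinations (24: transfer 1 + divert 1; 25: transfer 2 + divert 2; 26:
#' transfer 1 + divert 1 + discharge 1 medical and 1 surgical inpatient).
#'
#' @return A tibble with one row per scenario: `id`, `label`, capacity deltas
#'   `d_ed`, `d_amu`, `d_medical`, `d_surgical`, and per-episode action
#'   counts `transfer_ed_n`, `discharge_inpatient_n`, `discharge_medical_n`,
#'   `discharge_surgical_n`, `postpone_elective_n`, `divert_ambulance_n`.
#' @export
#' @examples
#' scenario_catalog()
scenario_catalog <- function() {
  rows <- list()
  add <- function(id, label, d = c(0, 0, 0, 0), transfer = 0, dis = 0,
                  dis_med = 0, dis_surg = 0, postpone = 0, divert = 0) {
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, label = label,
      d_ed = d[1], d_amu = d[2], d_medical = d[3], d_surgical = d[4],
      transfer_ed_n = transfer, discharge_inpatient_n = dis,
      discharge_medical_n = dis_med, discharge_surgical_n = dis_surg,
      postpone_elective_n = postpone, divert_ambulance_n = divert)
  }
  add(0L, "Baseline (no intervention)")
  for (k in c(2, 4, 6)) add(k / 2L, sprintf("Adding %d ED beds", k),
                            d = c(k, 0, 0, 0))
  for (k in c(2, 4, 6)) add(3L + k / 2L, sprintf("Adding %d AMU beds", k),
                            d = c(0, k, 0, 0))
  for (k in c(2, 4, 6)) add(6L + k / 2L,
                            sprintf("Moving %d surgical beds to medical units", k),
                            d = c(0, 0, k, -k))
  for (k in c(2, 4, 6)) add(9L + k / 2L,
                            sprintf("Moving %d medical beds to surgical units", k),
                            d = c(0, 0, -k, k))
  for (k in c(2, 4, 6)) add(12L + k / 2L,
                            sprintf("Moving %d ED patients to other hospitals", k),
                            transfer = k)
  for (k in c(2, 4, 6)) add(15L + k / 2L,
                            sprintf("Discharging %d inpatients", k), dis = k)
  for (k in c(2, 4, 6)) add(18L + k / 2L,
                            sprintf("Postponing %d elective surgeries", k),
                            postpone = k)
  for (k in c(2, 4)) add(21L + k / 2L,
                         sprintf("Diverting %d ambulances", k), divert = k)
  add(24L, "Moving 1 ED patient and diverting 1 ambulance",
      transfer = 1, divert = 1)
  add(25L, "Moving 2 ED patients and diverting 2 ambulances",
      transfer = 2, divert = 2)
  add(26L, paste("Moving 1 ED patient, diverting 1 ambulance, and",
                 "discharging 1 surgical and 1 medical patient"),
      transfer = 1, divert = 1, dis_med = 1, dis_surg = 1)
  list_rbind(rows) |> arrange(.data$id)
}

#' Build one scenario configuration
#'
#' @param id Scenario identifier, 0-26 (0 = baseline).
#' @return A list of class `scenario_config` with the scenario's label,
#'   `capacity_deltas` (named: ed, amu, medical, surgical) and per-episode
#'   action counts (`transfer_ed_n`, `discharge_inpatient_n`,
#'   `discharge_medical_n`, `discharge_surgical_n`, `postpone_elective_n`,
#'   `divert_ambulance_n`).
#' @export
#' @examples
#' build_scenario(9)$capacity_deltas
#' build_scenario(26)
build_scenario <- function(id) {
  cat <- scenario_catalog()
  if (length(id) != 1L || is.na(id) || !id %in% cat$id) {
    abort(paste0("scenario id must be one of ",
                 paste(range(cat$id), collapse = "-"), "; got: ", id))
  }
  row <- cat[cat$id == id, ]
  structure(list(
    id = as.integer(row$id),
    label = row$label,
    capacity_deltas = c(ed = row$d_ed, amu = row$d_amu,
                        medical = row$d_medical, surgical = row$d_surgical),
    transfer_ed_n = row$transfer_ed_n,
    discharge_inpatient_n = row$discharge_inpatient_n,
    discharge_medical_n = row$discharge_medical_n,
    discharge_surgical_n = row$discharge_surgical_n,
    postpone_elective_n = row$postpone_elective_n,
    divert_ambulance_n = row$divert_ambulance_n
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config %d> %s\n", x$id, x$label))
  d <- x$capacity_deltas
  if (any(d != 0)) {
    cat("  capacity deltas:",
        paste(names(d)[d != 0], sprintf("%+d", d[d != 0]), collapse = ", "),
        "\n")
  }
  acts <- c(transfer = x$transfer_ed_n,
            discharge = x$discharge_inpatient_n +
              x$discharge_medical_n + x$discharge_surgical_n,
            postpone = x$postpone_elective_n,
            divert = x$divert_ambulance_n)
  if (any(acts > 0)) {
    cat("  per-episode actions:",
        paste(names(acts)[acts > 0], acts[acts > 0], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the scenario catalogue to YAML
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_catalog <- function(path) {
  cat <- scenario_catalog()
  yaml::write_yaml(lapply(seq_len(nrow(cat)), function(i) as.list(cat[i, ])),
                   path)
  invisible(path)
}
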