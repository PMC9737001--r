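#' Define an experiment plan
#'
#' @param scenario_ids Scenarios to run (subset of 0-26). Scenario 0 must be
#'   included when efficiencies are wanted.
#' @param replications Replications per scenario (default 20).
#' @param years Simulated years per run (default 2).
#' @param warmup_years Initial years discarded before collection (default 1).
#' @param base_seed Replication `r` of every scenario uses seed
#'   `base_seed + r`, giving common random numbers across scenarios.
#' @param output_dir Optional directory for results/episodes CSVs and the
#'   provenance record.
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(scenario_ids = 0:26, replications = 20L,
                            years = 2L, warmup_years = 1L, base_seed = 1L,
                            output_dir = NULL) {
  if (replications < 1) abort("`replications` must be >= 1")
  if (warmup_years >= years || warmup_years < 0) {
    abort("`warmup_years` must be non-negative and smaller than `years`")
  }
  valid <- scenario_catalog()$id
  if (!all(scenario_ids %in% valid)) {
    abort("`scenario_ids` must be a subset of 0-26")
  }
  structure(list(scenario_ids = sort(unique(as.integer(scenario_ids))),
                 replications = as.integer(replications),
                 years = years, warmup_years = warmup_years,
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir),
            class = "experiment_plan")
}

#' Run a replicated scenario experiment
#'
#' Runs every scenario in the plan for `replications` paired replications
#' (replication `r` of each scenario shares seed `base_seed + r`, i.e. the
#' same arrival and length-of-stay draws — common random numbers), discards
#' the warm-up years, aggregates the per-replication metrics by field-wise
#' means, and attaches efficiency statistics relative to scenario 0 for every
#' scenario whose interventions affected at least one patient.
#'
#' @param plan An [experiment_plan()].
#' @param config A [hospital_config()]; default [default_config()].
#' @return A list of class `hospital_experiment` with `results` (one row per
#'   scenario: metrics plus `event_efficiency`, `time_efficiency`,
#'   `total_affected`), `replications` (per-replication rows), `plan` and
#'   `provenance`. When the plan names an `output_dir`, `results.csv`,
#'   `replications.csv`, `episodes.csv` and `provenance.json` are written
#'   there.
#' @export
#' @examples
#' \donttest{
#' plan <- experiment_plan(c(0, 22), replications = 2, years = 2)
#' ex <- run_experiment(plan, default_config())
#' ex$results
#' }
run_experiment <- function(plan, config = default_config()) {
  stopifnot(inherits(plan, "experiment_plan"),
            inherits(config, "hospital_config"))
  window <- collection_window(plan$years, plan$warmup_years)
  horizon <- as.integer(round(plan$years * 8760))
  scen <- lapply(plan$scenario_ids, build_scenario)

  rep_rows <- list()
  ep_rows <- list()
  for (r in seq_len(plan$replications)) {
    seed_r <- plan$base_seed + r
    patients <- build_patient_table(config, horizon, seed_r)
    for (s in scen) {
      tr <- run_simulation(config, s, years = plan$years, seed = seed_r,
                           patients = patients)
      m <- summarize_run(tr, window) |>
        mutate(scenario = s$id, replication = r, seed = seed_r, .before = 1)
      rep_rows[[length(rep_rows) + 1L]] <- m
      eps <- tr$episodes |>
        filter(.data$start_h >= window[1], .data$start_h < window[2])
      if (nrow(eps)) {
        ep_rows[[length(ep_rows) + 1L]] <- eps |>
          mutate(scenario = s$id, replication = r, .before = 1)
      }
    }
  }
  reps <- list_rbind(rep_rows)
  episodes <- if (length(ep_rows)) list_rbind(ep_rows) else tibble()

  agg <- reps |>
    group_by(.data$scenario) |>
    group_modify(~aggregate_replications(.x)) |>
    ungroup()

  labels <- scenario_catalog() |> select("id", "label")
  results <- agg |>
    left_join(labels, by = c(scenario = "id")) |>
    relocate("label", .after = "scenario")

  if (0L %in% plan$scenario_ids) {
    base <- results |> filter(.data$scenario == 0L)
    eff <- map(seq_len(nrow(results)), function(i) {
      row <- results[i, ]
      tot <- row$affected_patients + row$postponed_electives +
        row$diverted_ambulances
      if (row$scenario == 0L || tot <= 0) {
        tibble(event_efficiency = NA_real_, time_efficiency = NA_real_,
               total_affected = tot)
      } else {
        efficiency(base, row)
      }
    }) |>
      list_rbind()
    results <- bind_cols(results, eff)
  }

  provenance <- list(
    package = "hospitalflow",
    version = as.character(packageVersion("hospitalflow")),
    base_seed = plan$base_seed,
    replications = plan$replications,
    years = plan$years,
    warmup_years = plan$warmup_years,
    scenario_ids = plan$scenario_ids,
    collection_window_h = window,
    config = config_as_list(config))

  out <- structure(list(results = results, replications = reps,
                        episodes = episodes, plan = plan,
                        provenance = provenance),
                   class = "hospital_experiment")
  if (!is.null(plan$output_dir)) write_results(out, plan$output_dir)
  out
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$arrival_rates <- lapply(x$arrival_rates, as.vector)
  x
}

#' Write experiment outputs
#'
#' Writes `results.csv` (one row per scenario, mirroring the summary-table
#' layout plus the two efficiency columns), `replications.csv`,
#' `episodes.csv` and a `provenance.json` containing the seeds, plan and full
#' configuration needed to regenerate the results exactly.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(experiment, dir) {
  stopifnot(inherits(experiment, "hospital_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(experiment$results, file.path(dir, "results.csv"))
  readr::write_csv(experiment$replications, file.path(dir, "replications.csv"))
  if (nrow(experiment$episodes)) {
    readr::write_csv(experiment$episodes, file.path(dir, "episodes.csv"))
  }
  jsonlite::write_json(experiment$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Rank scenarios by a congestion or efficiency key
#'
#' Congestion metrics rank ascending (fewer events / shorter durations are
#' better); efficiencies rank descending. Ties break by scenario id.
#'
#' @param results A `hospital_experiment` or its `results` tibble.
#' @param key One of `"events"`, `"mean_duration"`, `"max_duration"`,
#'   `"event_efficiency"`, `"time_efficiency"`.
#' @return The results tibble ordered by the key, with a `rank` column.
#' @export
#' @examples
#' tb <- tibble::tibble(scenario = c(0, 22, 6),
#'                      n_congestion_events = c(111.75, 39.55, 21.35))
#' rank_scenarios(tb, "events")$scenario  # 6, 22, 0
rank_scenarios <- function(results, key = c("events", "mean_duration",
                                            "max_duration",
                                            "event_efficiency",
                                            "time_efficiency")) {
  key <- match.arg(key)
  if (inherits(results, "hospital_experiment")) results <- results$results
  col <- switch(key,
                events = "n_congestion_events",
                mean_duration = "mean_congestion_h",
                max_duration = "max_congestion_h",
                event_efficiency = "event_efficiency",
                time_efficiency = "time_efficiency")
  if (!col %in% names(results)) {
    abort(paste0("results lack the column needed for key '", key, "'"))
  }
  descending <- key %in% c("event_efficiency", "time_efficiency")
  v <- results[[col]]
  ord <- order(if (descending) -v else v, results$scenario, na.last = TRUE)
  results[ord, , drop = FALSE] |>
    mutate(rank = row_number(), .before = 1)
}

#' @export
print.hospital_experiment <- function(x, ...) {
  cat(sprintf("<hospital_experiment> %d scenario(s) x %d replication(s), %g year(s) (%g warm-up)\n",
              length(x$plan$scenario_ids), x$plan$replications,
              x$plan$years, x$plan$warmup_years))
  print(x$results |>
          select(any_of(c("scenario", "label", "mean_occupancy_10am",
                          "n_congestion_events", "mean_congestion_h",
                          "event_efficiency"))), n = 27)
  invisible(x)
}
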