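#' Tidy a scenario experiment
#'
#' One row per scenario with the aggregated metrics and efficiencies.
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hospital_experiment
#' @export
tidy.hospital_experiment <- function(x, ...) {
  as_tibble(x$results)
}

#' One-line experiment summary
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#' @return One-row tibble with the experiment dimensions, baseline congestion
#'   frequency and the best scenario by annual events.
#' @method glance hospital_experiment
#' @export
glance.hospital_experiment <- function(x, ...) {
  res <- x$results
  base <- res$n_congestion_events[res$scenario == 0]
  best <- res$scenario[which.min(res$n_congestion_events)]
  tibble(n_scenarios = nrow(res),
         replications = x$plan$replications,
         years = x$plan$years,
         baseline_events = if (length(base)) base else NA_real_,
         best_scenario = best,
         best_events = min(res$n_congestion_events))
}

#' @export
generics::tidy

#' @export
generics::glance
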