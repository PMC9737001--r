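#' Plot a simulated trajectory
#'
#' Inpatient occupancy fraction and ED waiting-queue length over time, with
#' congestion episodes shaded.
#'
#' @param object A [run_simulation()] result.
#' @param window Optional `c(start_h, end_h)` to restrict the view.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hospital_trajectory
#' @export
autoplot.hospital_trajectory <- function(object, window = NULL, ...) {
  sn <- object$snapshots
  if (!is.null(window)) {
    sn <- sn |> filter(.data$time_h >= window[1], .data$time_h < window[2])
  }
  eps <- object$episodes
  if (!is.null(window)) {
    eps <- eps |> filter(.data$end_h > window[1], .data$start_h < window[2])
  }
  long <- sn |>
    select("time_h", `inpatient occupancy` = "inpatient_occupancy",
           `ED queue length` = "ed_queue_len") |>
    tidyr::pivot_longer(-"time_h", names_to = "panel")
  ggplot(long, aes(x = .data$time_h / 24, y = .data$value)) +
    geom_rect(data = eps,
              aes(xmin = .data$start_h / 24, xmax = .data$end_h / 24),
              ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
              fill = "firebrick", alpha = 0.25) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "day", y = NULL,
         title = sprintf("Scenario %d: %s", object$scenario$id,
                         object$scenario$label)) +
    theme_minimal()
}

#' Plot scenario comparison from an experiment
#'
#' Mean congestion events per collection year by scenario, baseline marked.
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hospital_experiment
#' @export
autoplot.hospital_experiment <- function(object, ...) {
  res <- object$results
  base <- res$n_congestion_events[res$scenario == 0]
  ggplot(res, aes(x = factor(.data$scenario),
                  y = .data$n_congestion_events)) +
    geom_col(fill = "steelblue") +
    {if (length(base)) geom_hline(yintercept = base, linetype = 2)} +
    labs(x = "scenario", y = "congestion events / year",
         title = "Decongestion scenarios: annual congestion frequency") +
    theme_minimal()
}

#' Efficiency scatter of patient-affecting scenarios
#'
#' Congestion reduction per affected patient (events or mean hours) against
#' the number of patients affected, one point per scenario.
#'
#' @param experiment A [run_experiment()] result (or its results tibble with
#'   efficiency columns).
#' @param measure `"events"` or `"time"`.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(experiment, measure = c("events", "time")) {
  measure <- match.arg(measure)
  res <- if (inherits(experiment, "hospital_experiment")) {
    experiment$results
  } else experiment
  col <- if (measure == "events") "event_efficiency" else "time_efficiency"
  res <- res |> filter(!is.na(.data[[col]]))
  ggplot(res, aes(x = .data$total_affected, y = .data[[col]],
                  label = .data$scenario)) +
    geom_point(colour = "firebrick") +
    geom_text(vjust = -0.7, size = 3) +
    labs(x = "patients affected per collection year",
         y = if (measure == "events") {
           "congestion events avoided per affected patient"
         } else {
           "mean congestion hours avoided per affected patient"
         }) +
    theme_minimal()
}
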