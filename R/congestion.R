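#' Congestion thresholds
#'
#' The whole-hospital congestion state is declared when, at an hourly check,
#' the ED admission side is almost full, the inpatient departments are at or
#' above a high occupancy fraction, and the queue of ED patients waiting for
#' treatment is long — all three jointly by default.
#'
#' @param ed_min_occupied Minimum occupied ED admission beds (default 17 of
#'   an 18-bed admission side).
#' @param inpatient_min_occupancy Minimum inpatient occupancy fraction in
#'   `(0, 1]` (default 0.97).
#' @param queue_min Minimum number of ED patients waiting for treatment
#'   (default 28).
#' @param conjunctive If `TRUE` (default) all three criteria must hold; if
#'   `FALSE` any one suffices (sensitivity-analysis mode).
#' @return A list of class `congestion_thresholds`.
#' @export
#' @examples
#' congestion_thresholds()
congestion_thresholds <- function(ed_min_occupied = 17L,
                                  inpatient_min_occupancy = 0.97,
                                  queue_min = 28L,
                                  conjunctive = TRUE) {
  if (inpatient_min_occupancy <= 0 || inpatient_min_occupancy > 1) {
    abort("`inpatient_min_occupancy` must lie in (0, 1]")
  }
  if (queue_min < 0 || ed_min_occupied < 0) {
    abort("thresholds must be non-negative")
  }
  structure(list(ed_min_occupied = as.integer(ed_min_occupied),
                 inpatient_min_occupancy = inpatient_min_occupancy,
                 queue_min = as.integer(queue_min),
                 conjunctive = isTRUE(conjunctive)),
            class = "congestion_thresholds")
}

#' @export
print.congestion_thresholds <- function(x, ...) {
  cat(sprintf(
    "<congestion_thresholds> ED beds >= %d %s inpatient occupancy >= %.2f %s queue >= %d\n",
    x$ed_min_occupied, if (x$conjunctive) "AND" else "OR",
    x$inpatient_min_occupancy, if (x$conjunctive) "AND" else "OR",
    x$queue_min))
  invisible(x)
}

#' Congestion predicate on an hourly state
#'
#' Vectorised test of the congestion state: occupied ED admission beds,
#' inpatient occupancy fraction and ED waiting-queue length are compared to
#' their thresholds (inclusive), combined conjunctively by default.
#'
#' @param ed_occupied Occupied ED admission beds (count).
#' @param inpatient_occupancy Inpatient occupancy fraction in `[0, 1]`.
#' @param queue_len ED patients waiting for treatment (count).
#' @param thresholds A [congestion_thresholds()].
#' @return Logical vector.
#' @export
#' @examples
#' is_congested(17, 0.97, 28)   # boundary: congested
#' is_congested(18, 0.99, 27)   # one criterion short: not congested
is_congested <- function(ed_occupied, inpatient_occupancy, queue_len,
                         thresholds = congestion_thresholds()) {
  if (any(ed_occupied < 0) || any(inpatient_occupancy < 0) ||
      any(queue_len < 0)) {
    abort("congestion indicators must be non-negative")
  }
  c_ed <- ed_occupied >= thresholds$ed_min_occupied
  c_occ <- inpatient_occupancy >= thresholds$inpatient_min_occupancy - 1e-12
  c_q <- queue_len >= thresholds$queue_min
  if (thresholds$conjunctive) c_ed & c_occ & c_q else c_ed | c_occ | c_q
}

#' Segment hourly congestion flags into episodes
#'
#' A congestion episode is a maximal run of consecutive congested hourly
#' checks. Its `start_h` is the hour index of the first congested check, its
#' `end_h` the first subsequent non-congested check (the horizon end for a
#' run truncated by the horizon), and `duration_h = end_h - start_h`.
#'
#' @param x Either a logical vector of hourly flags (hour indices taken as
#'   `0, 1, ...` or as `start_hour + 0, 1, ...`), a snapshots tibble with
#'   columns `time_h` and `congested`, or a `hospital_trajectory`.
#' @param start_hour Hour index of the first flag when `x` is a bare logical
#'   vector (default 0).
#' @return A tibble with columns `episode`, `start_h`, `end_h`, `duration_h`.
#' @export
#' @examples
#' extract_episodes(c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
extract_episodes <- function(x, start_hour = 0L) {
  if (inherits(x, "hospital_trajectory")) x <- x$snapshots
  if (is.data.frame(x)) {
    stopifnot(all(c("time_h", "congested") %in% names(x)))
    start_hour <- x$time_h[1] %||% 0L
    x <- x$congested
  }
  x <- as.logical(x)
  if (length(x) == 0L || !any(x)) {
    return(tibble(episode = integer(), start_h = numeric(),
                  end_h = numeric(), duration_h = numeric()))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(
    episode = seq_len(sum(keep)),
    start_h = as.numeric(start_hour + starts[keep] - 1),
    end_h = as.numeric(start_hour + ends[keep]),
    duration_h = as.numeric(r$lengths[keep])
  )
}

#' Summary statistics of congestion episodes
#'
#' @param episodes A tibble from [extract_episodes()].
#' @return One-row tibble with `n_events`, `max_h`, `min_h`, `mean_h`
#'   (all zero when there are no episodes).
#' @export
#' @examples
#' episode_stats(extract_episodes(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)))
episode_stats <- function(episodes) {
  if (nrow(episodes) == 0L) {
    return(tibble(n_events = 0L, max_h = 0, min_h = 0, mean_h = 0))
  }
  tibble(n_events = nrow(episodes),
         max_h = max(episodes$duration_h),
         min_h = min(episodes$duration_h),
         mean_h = mean(episodes$duration_h))
}

#' Calibrate the queue-length threshold to a target congestion frequency
#'
#' Reproduces, on the synthetic hospital, the reverse-engineering step that
#' turns an assumed baseline congestion frequency into a queue-length
#' criterion: a bisection over `queue_min` until the simulated baseline
#' produces the target number of episodes per collection year. Congestion
#' frequency is non-increasing in `queue_min`.
#'
#' @param config A [hospital_config()].
#' @param target_events_per_year Desired baseline episodes per collection
#'   year (e.g. 52 for roughly weekly congestion).
#' @param queue_range Integer search interval.
#' @param replications,years,seed Simulation effort for each evaluation.
#' @return The configuration with its `thresholds$queue_min` replaced;
#'   the search path is attached as attribute `"calibration"`.
#' @export
calibrate_queue_threshold <- function(config, target_events_per_year = 52,
                                      queue_range = c(0L, 80L),
                                      replications = 2L, years = 2L,
                                      seed = 1L) {
  events_at <- function(qmin) {
    cfg <- config
    cfg$thresholds$queue_min <- as.integer(qmin)
    mean(vapply(seq_len(replications), function(r) {
      tr <- run_simulation(cfg, build_scenario(0), years = years,
                           seed = seed + r)
      m <- summarize_run(tr, window = collection_window(years))
      m$n_congestion_events
    }, numeric(1)))
  }
  lo <- queue_range[1]; hi <- queue_range[2]
  path <- list()
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    ev <- events_at(mid)
    path[[length(path) + 1L]] <- tibble(queue_min = mid, events = ev)
    if (ev > target_events_per_year) lo <- mid else hi <- mid
  }
  ev_lo <- events_at(lo); ev_hi <- events_at(hi)
  pick <- if (abs(ev_lo - target_events_per_year) <=
              abs(ev_hi - target_events_per_year)) lo else hi
  config$thresholds$queue_min <- as.integer(pick)
  attr(config, "calibration") <- list_rbind(path)
  config
}
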