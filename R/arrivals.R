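#' Sample arrival streams from a hospital configuration
#'
#' Draws ambulance, walk-in and elective arrivals over a horizon as
#' independent time-varying Poisson processes on the configuration's
#' hour-of-day by day-of-week intensity grids (piecewise-constant rates;
#' hour 0 is Monday 00:00). Each ED arrival carries a triage score drawn from
#' `triage_pmf`, an admission indicator drawn from the per-triage admission
#' probability, and, if admitted, a medical/surgical class drawn with
#' `class_split`. Electives are surgical and always admitted.
#'
#' @param config A [hospital_config()].
#' @param horizon_h Horizon in hours (> 0).
#' @param seed Integer seed; identical seed and config give an identical
#'   arrival table.
#' @return A tibble ordered by arrival time with columns `id`, `time_h`,
#'   `stream` (`"ed"`/`"elective"`), `mode` (`"walkin"`/`"ambulance"`/
#'   `"elective"`), `triage` (1-5), `admitted` and `class`
#'   (`"medical"`/`"surgical"`, `NA` for non-admitted ED patients).
#' @export
#' @examples
#' arr <- sample_arrivals(default_config(), horizon_h = 48, seed = 1)
#' head(arr)
sample_arrivals <- function(config, horizon_h, seed = 1L) {
  stopifnot(inherits(config, "hospital_config"))
  if (!is.numeric(horizon_h) || length(horizon_h) != 1L || horizon_h <= 0) {
    abort("`horizon_h` must be a single positive number of hours")
  }
  set.seed(seed)
  sample_arrivals_impl(config, horizon_h)
}

# uses the current RNG state (callers seed once for arrivals + LOS draws)
sample_arrivals_impl <- function(config, horizon_h) {
  horizon_h <- as.integer(ceiling(horizon_h))
  hrs <- seq_len(horizon_h) - 1L
  hod <- hrs %% 24L + 1L
  dow <- (hrs %/% 24L) %% 7L + 1L

  one_stream <- function(grid, stream, mode) {
    lam <- grid[cbind(hod, dow)]
    n_h <- rpois(horizon_h, lam)
    total <- sum(n_h)
    if (total == 0L) {
      return(tibble(time_h = numeric(), stream = character(),
                    mode = character()))
    }
    base <- rep.int(hrs, n_h)
    tibble(time_h = base + runif(total), stream = stream, mode = mode)
  }

  arr <- bind_rows(
    one_stream(config$arrival_rates$walkin, "ed", "walkin"),
    one_stream(config$arrival_rates$ambulance, "ed", "ambulance"),
    one_stream(config$arrival_rates$elective, "elective", "elective")
  ) |>
    arrange(.data$time_h)

  n <- nrow(arr)
  triage <- if (n) {
    sample.int(5L, n, replace = TRUE, prob = config$triage_pmf)
  } else integer()
  is_ed <- arr$stream == "ed"
  admitted <- rep(TRUE, n)
  admitted[is_ed] <- runif(sum(is_ed)) <
    config$admit_probability[triage[is_ed]]
  class <- rep(NA_character_, n)
  class[is_ed & admitted] <- ifelse(
    runif(sum(is_ed & admitted)) < config$class_split, "medical", "surgical")
  class[!is_ed] <- "surgical"

  arr |>
    mutate(id = seq_len(n), triage = triage, admitted = admitted,
           class = class, .before = 1) |>
    select("id", "time_h", "stream", "mode", "triage", "admitted", "class")
}

#' Sample lengths of stay
#'
#' Draws strictly positive, right-skewed (log-normal) durations for a patient
#' class from the configuration's location/scale parameters. With a scale
#' parameter of 0 the draw degenerates to `exp(meanlog)` exactly.
#'
#' @param config A [hospital_config()].
#' @param class One of `"ed_treatment"`, `"amu"`, `"medical"`, `"surgical"`,
#'   `"elective_surgical"`.
#' @param n Number of draws.
#' @return Numeric vector of durations in hours, using the current RNG state
#'   (call `set.seed()` beforehand for reproducibility).
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_los(default_config(), "medical", n = 1000))
sample_los <- function(config, class, n = 1L) {
  stopifnot(inherits(config, "hospital_config"))
  par <- if (identical(class, "ed_treatment")) {
    config$ed_treatment_params
  } else {
    config$los_params[[class]]
  }
  if (is.null(par)) {
    abort(paste0("unknown length-of-stay class: '", class, "'"))
  }
  rlnorm(n, meanlog = par[["meanlog"]], sdlog = par[["sdlog"]])
}

#' Analytic mean length of stay of a class
#'
#' Log-normal moment `exp(meanlog + sdlog^2 / 2)`; useful for calibration and
#' as a test oracle.
#'
#' @inheritParams sample_los
#' @return Mean duration in hours.
#' @export
los_mean <- function(config, class) {
  par <- if (identical(class, "ed_treatment")) {
    config$ed_treatment_params
  } else {
    config$los_params[[class]]
  }
  if (is.null(par)) abort(paste0("unknown length-of-stay class: '", class, "'"))
  exp(par[["meanlog"]] + par[["sdlog"]]^2 / 2)
}

# Full patient table for the engine: arrivals plus every stochastic draw the
# run needs (all randomness lives here; the engine is deterministic).
build_patient_table <- function(config, horizon_h, seed) {
  set.seed(seed)
  arr <- sample_arrivals_impl(config, horizon_h)
  n <- nrow(arr)
  ed_los <- amu_los <- ward_los <- numeric(n)
  is_ed <- arr$stream == "ed"
  ed_los[is_ed] <- sample_los(config, "ed_treatment", sum(is_ed))
  med <- !is.na(arr$class) & arr$class == "medical"
  amu_los[med] <- sample_los(config, "amu", sum(med))
  ward_los[med] <- sample_los(config, "medical", sum(med))
  esurg <- is_ed & !is.na(arr$class) & arr$class == "surgical"
  ward_los[esurg] <- sample_los(config, "surgical", sum(esurg))
  elec <- !is_ed
  ward_los[elec] <- sample_los(config, "elective_surgical", sum(elec))
  arr |> mutate(ed_los = ed_los, amu_los = amu_los, ward_los = ward_los)
}

#' Export an arrival stream as CSV
#'
#' Writes the columns `time_h`, `stream`, `mode`, `triage`, `class`.
#'
#' @param arrivals A tibble from [sample_arrivals()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_arrivals <- function(arrivals, path) {
  readr::write_csv(
    arrivals |> select("time_h", "stream", "mode", "triage", "class"), path)
  invisible(path)
}
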