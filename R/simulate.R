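#' Simulation parameters for a synthetic CLP biotelemetry cohort
#'
#' Bundles and validates every knob of the trace generator. The defaults
#' describe the study conditions the package targets: a cohort of 115 mice of
#' which about 7% never deteriorate within the 24-hour observation horizon,
#' with latent deterioration-onset times drawn from a log-normal whose median
#' is 465 minutes and whose spread reproduces an interquartile range of
#' roughly 422-536 minutes.
#'
#' Each simulated trace follows a ramp-plateau-decline shape: heart rate and
#' core temperature start from a depressed post-anaesthesia baseline, ramp
#' linearly to an individual peak plateau over `ramp_minutes`, and -- unless
#' the mouse is a sampled non-deteriorator -- decline linearly from the
#' mouse's latent onset time at `hr_decline_slope` and `temp_decline_slope`.
#' The shape is deliberately simple so that threshold-crossing times have a
#' closed form (see [detect()]).
#'
#' @param n_mice Number of mice in the cohort.
#' @param onset_meanlog,onset_sdlog Log-location and log-scale of the
#'   log-normal latent onset distribution, in log-minutes.
#' @param onset_min,onset_max Truncation bounds (minutes) of the onset
#'   distribution. Setting both to the same value pins every onset there,
#'   which is useful for noise-free oracle checks.
#' @param non_deteriorator_fraction Probability that a mouse never declines
#'   within the horizon (its trace plateaus indefinitely).
#' @param hr_peak_range,temp_peak_range Ranges (uniform) for the individual
#'   plateau peaks, in bpm and degrees Celsius.
#' @param hr_decline_slope,temp_decline_slope Post-onset decline rates,
#'   bpm/min and degrees Celsius/min; both must be positive.
#' @param noise_sd_hr,noise_sd_temp Gaussian measurement noise SDs (bpm,
#'   degrees Celsius); zero gives noise-free traces.
#' @param sampling_interval Sampling interval in minutes.
#' @param horizon Observation horizon in minutes post-CLP.
#' @param baseline_hr,baseline_temp Post-anaesthesia starting values.
#' @param ramp_minutes Minutes from surgery to plateau peak.
#' @param seed Integer seed; every draw is a deterministic function of
#'   `(seed, mouse index)`.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [simulate_mouse()], [simulate_cohort()], [sample_cohort_truth()]
#' @export
sim_params <- function(n_mice = 115,
                       onset_meanlog = log(465),
                       onset_sdlog = 0.16,
                       onset_min = 240,
                       onset_max = 1440,
                       non_deteriorator_fraction = 0.07,
                       hr_peak_range = c(650, 750),
                       temp_peak_range = c(37, 38.5),
                       hr_decline_slope = 2,
                       temp_decline_slope = 0.02,
                       noise_sd_hr = 10,
                       noise_sd_temp = 0.1,
                       sampling_interval = 1,
                       horizon = 1440,
                       baseline_hr = 500,
                       baseline_temp = 35,
                       ramp_minutes = 120,
                       seed = 1L) {
  if (!is_count(n_mice)) {
    stop_input("`n_mice` must be a non-negative integer")
  }
  if (!is_scalar_num(non_deteriorator_fraction) ||
      non_deteriorator_fraction < 0 || non_deteriorator_fraction > 1) {
    stop_input("`non_deteriorator_fraction` must be in [0, 1]")
  }
  if (!is_scalar_num(hr_decline_slope) || hr_decline_slope <= 0 ||
      !is_scalar_num(temp_decline_slope) || temp_decline_slope <= 0) {
    stop_input("decline slopes must be positive")
  }
  if (!is_scalar_num(horizon) || horizon <= 0) {
    stop_input("`horizon` must be positive")
  }
  if (!is_scalar_num(sampling_interval) || sampling_interval <= 0) {
    stop_input("`sampling_interval` must be positive")
  }
  if (length(hr_peak_range) != 2L || diff(hr_peak_range) < 0 ||
      length(temp_peak_range) != 2L || diff(temp_peak_range) < 0) {
    stop_input("peak ranges must be length-2 and non-decreasing")
  }
  if (!is_scalar_num(onset_min) || !is_scalar_num(onset_max) ||
      onset_min <= 0 || onset_max < onset_min) {
    stop_input("onset truncation bounds must satisfy 0 < onset_min <= onset_max")
  }
  if (noise_sd_hr < 0 || noise_sd_temp < 0) {
    stop_input("noise SDs must be non-negative")
  }
  structure(
    list(
      n_mice = as.integer(n_mice),
      onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
      onset_min = onset_min, onset_max = onset_max,
      non_deteriorator_fraction = non_deteriorator_fraction,
      hr_peak_range = hr_peak_range, temp_peak_range = temp_peak_range,
      hr_decline_slope = hr_decline_slope,
      temp_decline_slope = temp_decline_slope,
      noise_sd_hr = noise_sd_hr, noise_sd_temp = noise_sd_temp,
      sampling_interval = sampling_interval, horizon = horizon,
      baseline_hr = baseline_hr, baseline_temp = baseline_temp,
      ramp_minutes = ramp_minutes,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic CLP cohort parameters\n")
  cat(sprintf("  n_mice: %d (non-deteriorator fraction %.3f)\n",
              x$n_mice, x$non_deteriorator_fraction))
  cat(sprintf("  onset ~ lognormal(meanlog = %.4f, sdlog = %.3f), truncated [%g, %g] min\n",
              x$onset_meanlog, x$onset_sdlog, x$onset_min, x$onset_max))
  cat(sprintf("  decline: %g bpm/min, %g C/min; noise SD %g bpm / %g C\n",
              x$hr_decline_slope, x$temp_decline_slope,
              x$noise_sd_hr, x$noise_sd_temp))
  cat(sprintf("  sampling every %g min over %g min; seed %d\n",
              x$sampling_interval, x$horizon, x$seed))
  invisible(x)
}

# Per-mouse latent draws. Draw order is fixed (non-deteriorator flag, onset,
# peaks) so that sample_cohort_truth() and simulate_mouse() agree exactly.
draw_truth <- function(params, index) {
  with_seed(mouse_seed(params$seed, index), {
    nondet <- stats::runif(1) < params$non_deteriorator_fraction
    f_lo <- stats::plnorm(params$onset_min, params$onset_meanlog, params$onset_sdlog)
    f_hi <- stats::plnorm(params$onset_max, params$onset_meanlog, params$onset_sdlog)
    u <- stats::runif(1)
    onset <- if (f_hi > f_lo) {
      stats::qlnorm(f_lo + u * (f_hi - f_lo), params$onset_meanlog, params$onset_sdlog)
    } else {
      params$onset_min
    }
    list(
      mouse_id = sprintf("m%04d", index),
      nondeteriorator = nondet,
      onset = onset,
      hr_peak = stats::runif(1, params$hr_peak_range[1], params$hr_peak_range[2]),
      temp_peak = stats::runif(1, params$temp_peak_range[1], params$temp_peak_range[2])
    )
  })
}

#' Sample the latent cohort truth without building traces
#'
#' Draws, for each mouse, the non-deteriorator flag, the latent onset time
#' and the individual plateau peaks -- exactly the values
#' [simulate_mouse()] would embed in its trace -- but skips waveform
#' construction. Useful for calibration checks at large `n_mice` where full
#' minute-resolution traces would be wasteful.
#'
#' @param params A [sim_params()] object.
#' @return A data.frame with columns `mouse_id`, `nondeteriorator`,
#'   `onset_min` (latent onset, minutes), `hr_peak_bpm`, `temp_peak_c`.
#' @export
sample_cohort_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_mice == 0L) {
    return(data.frame(
      mouse_id = character(), nondeteriorator = logical(),
      onset_min = numeric(), hr_peak_bpm = numeric(), temp_peak_c = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(seq_len(params$n_mice), function(i) draw_truth(params, i))
  data.frame(
    mouse_id = vapply(rows, `[[`, "", "mouse_id"),
    nondeteriorator = vapply(rows, `[[`, NA, "nondeteriorator"),
    onset_min = vapply(rows, `[[`, 0, "onset"),
    hr_peak_bpm = vapply(rows, `[[`, 0, "hr_peak"),
    temp_peak_c = vapply(rows, `[[`, 0, "temp_peak"),
    stringsAsFactors = FALSE
  )
}

#' Simulate one mouse's post-CLP telemetry trace
#'
#' Builds the ramp-plateau-decline trace for mouse `index` under `params`.
#' The result is bit-identical for identical `(seed, index)` regardless of
#' how many other mice are simulated in between.
#'
#' @param params A [sim_params()] object.
#' @param index Mouse index, `1 <= index <= n_mice`.
#' @return A `telemetry_trace`: a data.frame with columns `time_min`,
#'   `heart_rate_bpm`, `core_temp_c`, `activity`, carrying the mouse id and
#'   the latent truth (onset, peaks, non-deteriorator flag) as attributes.
#' @examples
#' p <- sim_params(n_mice = 1, noise_sd_hr = 0, noise_sd_temp = 0, seed = 7)
#' tr <- simulate_mouse(p, 1)
#' head(tr)
#' @export
simulate_mouse <- function(params, index) {
  stopifnot(inherits(params, "sim_params"))
  if (!is_count(index) || index < 1 || index > params$n_mice) {
    stop_input("`index` must be an integer in [1, n_mice]")
  }
  truth <- draw_truth(params, index)
  times <- seq(0, params$horizon, by = params$sampling_interval)
  n <- length(times)

  ramp <- pmin(times / params$ramp_minutes, 1)
  hr_base <- params$baseline_hr + (truth$hr_peak - params$baseline_hr) * ramp
  temp_base <- params$baseline_temp + (truth$temp_peak - params$baseline_temp) * ramp
  if (!truth$nondeteriorator) {
    past <- pmax(times - truth$onset, 0)
    hr_base <- pmin(hr_base, truth$hr_peak - params$hr_decline_slope * past)
    temp_base <- pmin(temp_base, truth$temp_peak - params$temp_decline_slope * past)
  }
  # physiologic floors: moribund mice level off rather than fall indefinitely
  hr_base <- pmax(hr_base, 250)
  temp_base <- pmax(temp_base, 24)

  noise <- with_seed(mouse_seed(params$seed, index) + 1, {
    list(
      hr = stats::rnorm(n, 0, params$noise_sd_hr),
      temp = stats::rnorm(n, 0, params$noise_sd_temp),
      act = stats::rnorm(n, 0, 0.5)
    )
  })
  hr <- pmax(hr_base + noise$hr, 1)
  temp <- pmin(pmax(temp_base + noise$temp, 20), 42)
  activity <- pmax(5 * exp(-times / 600) + noise$act, 0)

  new_telemetry_trace(
    data.frame(
      time_min = times, heart_rate_bpm = hr,
      core_temp_c = temp, activity = activity
    ),
    mouse_id = truth$mouse_id,
    truth = truth
  )
}

new_telemetry_trace <- function(df, mouse_id, truth = NULL) {
  attr(df, "mouse_id") <- mouse_id
  attr(df, "truth") <- truth
  class(df) <- c("telemetry_trace", "data.frame")
  validate_trace(df)
  df
}

#' Validate a telemetry trace
#'
#' Checks the structural invariants every trace must satisfy: time starts at
#' zero, is strictly increasing and uniformly sampled; heart rate positive;
#' core temperature within 20-42 degrees Celsius; channels of equal length
#' (the `activity` channel is optional).
#'
#' @param trace A `telemetry_trace` or plain data.frame with the trace
#'   columns.
#' @return The trace, invisibly, if valid; otherwise an error.
#' @export
validate_trace <- function(trace) {
  need <- c("time_min", "heart_rate_bpm", "core_temp_c")
  missing_cols <- setdiff(need, names(trace))
  if (length(missing_cols)) {
    stop_input("trace is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  t <- trace$time_min
  if (length(t) == 0L) stop_input("trace is empty")
  if (t[1] != 0) stop_input("trace times must start at 0")
  dt <- diff(t)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-8)) {
    stop_input("trace times must be strictly increasing at a constant interval")
  }
  if (any(trace$heart_rate_bpm <= 0)) stop_input("heart rate must be positive")
  if (any(trace$core_temp_c < 20 | trace$core_temp_c > 42)) {
    stop_input("core temperature must lie within 20-42 C")
  }
  invisible(trace)
}

#' @export
print.telemetry_trace <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("Telemetry trace for mouse %s: %d samples over %g min\n",
              attr(x, "mouse_id") %||% "?", nrow(x), max(x$time_min)))
  if (!is.null(tr)) {
    if (isTRUE(tr$nondeteriorator)) {
      cat("  latent state: non-deteriorator (plateau only)\n")
    } else {
      cat(sprintf("  latent onset %.1f min; peaks %.0f bpm / %.2f C\n",
                  tr$onset, tr$hr_peak, tr$temp_peak))
    }
  }
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full cohort of telemetry traces
#'
#' @param params A [sim_params()] object.
#' @return A `telemetry_cohort`: a list of [simulate_mouse()] traces of
#'   length `n_mice` (possibly empty).
#' @examples
#' coh <- simulate_cohort(sim_params(n_mice = 3, seed = 11))
#' length(coh)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  traces <- lapply(seq_len(params$n_mice), function(i) simulate_mouse(params, i))
  structure(traces, class = "telemetry_cohort")
}

#' @export
print.telemetry_cohort <- function(x, ...) {
  cat(sprintf("Telemetry cohort: %d mice\n", length(x)))
  invisible(x)
}

#' Extract the latent truth table from a simulated cohort
#'
#' @param cohort A `telemetry_cohort`.
#' @return A data.frame as from [sample_cohort_truth()].
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "telemetry_cohort"))
  rows <- lapply(cohort, attr, "truth")
  data.frame(
    mouse_id = vapply(rows, `[[`, "", "mouse_id"),
    nondeteriorator = vapply(rows, `[[`, NA, "nondeteriorator"),
    onset_min = vapply(rows, `[[`, 0, "onset"),
    hr_peak_bpm = vapply(rows, `[[`, 0, "hr_peak"),
    temp_peak_c = vapply(rows, `[[`, 0, "temp_peak"),
    stringsAsFactors = FALSE
  )
}
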