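#' Acute physiologic deterioration criteria
#'
#' The validated conjunctive criterion for acute deterioration after CLP:
#' (1) heart rate has fallen at least `hr_drop_fraction` (default 10%) below
#' its peak value, and (2) core temperature has fallen by at least
#' `temp_drop_fraction` (default 10%) of the difference between its peak and
#' a 25 degree Celsius floor. Both must hold at the same sample.
#'
#' @param hr_drop_fraction Fractional heart-rate drop from peak, in (0, 1).
#' @param temp_drop_fraction Fractional temperature drop toward the floor,
#'   in (0, 1).
#' @param temp_floor Temperature floor in degrees Celsius (default 25).
#' @param horizon Detection horizon in minutes (default 1440); mice not
#'   meeting criteria by then are censored.
#' @return A `deterioration_criteria` object.
#' @export
deterioration_criteria <- function(hr_drop_fraction = 0.10,
                                   temp_drop_fraction = 0.10,
                                   temp_floor = 25,
                                   horizon = 1440) {
  if (!is_scalar_num(hr_drop_fraction) || hr_drop_fraction <= 0 || hr_drop_fraction >= 1 ||
      !is_scalar_num(temp_drop_fraction) || temp_drop_fraction <= 0 || temp_drop_fraction >= 1) {
    stop_input("drop fractions must lie strictly between 0 and 1")
  }
  if (!is_scalar_num(horizon) || horizon <= 0) stop_input("`horizon` must be positive")
  structure(
    list(
      hr_drop_fraction = hr_drop_fraction,
      temp_drop_fraction = temp_drop_fraction,
      temp_floor = temp_floor,
      horizon = horizon
    ),
    class = "deterioration_criteria"
  )
}

#' @export
print.deterioration_criteria <- function(x, ...) {
  cat(sprintf(
    "Deterioration criteria: HR <= %.0f%% of peak AND temp drop >= %.0f%% of (peak - %g C), within %g min\n",
    100 * (1 - x$hr_drop_fraction), 100 * x$temp_drop_fraction,
    x$temp_floor, x$horizon
  ))
  invisible(x)
}

#' Detect acute physiologic deterioration in one trace
#'
#' Returns the earliest sample time `t` (within the horizon) at which both
#' criteria hold simultaneously: heart rate at or below
#' `(1 - hr_drop_fraction)` times its peak, and core temperature at or below
#' `peak - temp_drop_fraction * (peak - temp_floor)`. By default "peak"
#' means the running maximum up to `t` -- the causal definition a live
#' triage system must use; `peak = "global"` instead references the maximum
#' over the whole trace, as a sensitivity variant.
#'
#' @param trace A `telemetry_trace` (see [validate_trace()]).
#' @param criteria A [deterioration_criteria()] object.
#' @param peak `"running"` (causal, default) or `"global"`.
#' @param smooth_window Optional odd integer; if given, both channels are
#'   smoothed with a centred moving average of that many samples before
#'   thresholding. No smoothing by default.
#' @return A `detection_result` list: `mouse_id`, `detected`,
#'   `time_to_criteria` (minutes, `NA` if not detected), and the reference
#'   peaks `hr_peak`, `temp_peak` at the detection sample.
#' @examples
#' p <- sim_params(n_mice = 1, noise_sd_hr = 0, noise_sd_temp = 0,
#'                 onset_min = 465, onset_max = 465, seed = 3)
#' detect(simulate_mouse(p, 1))
#' @export
detect <- function(trace, criteria = deterioration_criteria(),
                   peak = c("running", "global"), smooth_window = NULL) {
  peak <- match.arg(peak)
  stopifnot(inherits(criteria, "deterioration_criteria"))
  validate_trace(trace)

  hr <- trace$heart_rate_bpm
  temp <- trace$core_temp_c
  if (!is.null(smooth_window)) {
    if (!is_count(smooth_window) || smooth_window %% 2 != 1 || smooth_window < 3) {
      stop_input("`smooth_window` must be an odd integer >= 3")
    }
    k <- rep(1 / smooth_window, smooth_window)
    sm <- function(x) {
      y <- stats::filter(x, k, sides = 2)
      y[is.na(y)] <- x[is.na(y)]  # keep edges unsmoothed
      as.numeric(y)
    }
    hr <- sm(hr)
    temp <- sm(temp)
  }

  if (max(temp) <= criteria$temp_floor) {
    stop_input("peak core temperature does not exceed the ", criteria$temp_floor,
               " C floor; temperature criterion undefined")
  }

  if (peak == "running") {
    hr_ref <- cummax(hr)
    temp_ref <- cummax(temp)
  } else {
    hr_ref <- rep(max(hr), length(hr))
    temp_ref <- rep(max(temp), length(temp))
  }

  in_horizon <- trace$time_min <= criteria$horizon
  hit <- in_horizon &
    hr <= (1 - criteria$hr_drop_fraction) * hr_ref &
    temp <= temp_ref - criteria$temp_drop_fraction * (temp_ref - criteria$temp_floor)

  i <- which(hit)[1]
  res <- if (is.na(i)) {
    list(
      mouse_id = attr(trace, "mouse_id") %||% NA_character_,
      detected = FALSE, time_to_criteria = NA_real_,
      hr_peak = max(hr), temp_peak = max(temp)
    )
  } else {
    list(
      mouse_id = attr(trace, "mouse_id") %||% NA_character_,
      detected = TRUE, time_to_criteria = trace$time_min[i],
      hr_peak = hr_ref[i], temp_peak = temp_ref[i]
    )
  }
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("Mouse %s: criteria met at %.1f min (peaks %.0f bpm, %.2f C)\n",
                x$mouse_id, x$time_to_criteria, x$hr_peak, x$temp_peak))
  } else {
    cat(sprintf("Mouse %s: criteria not met within horizon\n", x$mouse_id))
  }
  invisible(x)
}

#' Detect deterioration across a cohort of traces
#'
#' Applies [detect()] to every trace and assembles a [mouse_outcomes()]
#' table; mice not meeting criteria within the horizon are censored
#' (and would be excluded from variability analysis, which uses only
#' uncensored mice). Per-trace failures are re-raised with the mouse id.
#'
#' @param traces A `telemetry_cohort` or plain list of traces.
#' @param criteria A [deterioration_criteria()] object.
#' @param ... Passed on to [detect()] (`peak`, `smooth_window`).
#' @return A `mouse_outcomes` data.frame, one row per trace.
#' @export
detect_cohort <- function(traces, criteria = deterioration_criteria(), ...) {
  results <- lapply(seq_along(traces), function(i) {
    tryCatch(
      detect(traces[[i]], criteria, ...),
      error = function(e) {
        id <- attr(traces[[i]], "mouse_id") %||% paste0("#", i)
        stop_input("mouse ", id, ": ", conditionMessage(e))
      }
    )
  })
  mouse_outcomes(
    mouse_id = vapply(results, function(r) r$mouse_id %||% NA_character_, ""),
    time_to_criteria_min = vapply(results, `[[`, 0, "time_to_criteria"),
    censored = !vapply(results, `[[`, NA, "detected"),
    horizon = criteria$horizon
  )
}

#' Analytic threshold-crossing time for a ramp-plateau-decline trace
#'
#' For the noise-free trace shape produced by [simulate_mouse()], both
#' criteria are crossed at known delays after the latent onset: the heart
#' rate falls to `(1 - f) * peak` after `f * peak / slope` minutes, and the
#' temperature reaches its threshold after
#' `g * (peak - floor) / slope` minutes. Detection, being conjunctive,
#' happens at the later of the two. This closed form serves as the
#' independent oracle against which the sampled detector is checked.
#'
#' @param onset Latent onset time (minutes).
#' @param hr_peak,temp_peak Plateau peaks.
#' @param params A [sim_params()] object (for the decline slopes).
#' @param criteria A [deterioration_criteria()] object.
#' @return Crossing time in minutes (possibly beyond the horizon).
#' @export
analytic_crossing_time <- function(onset, hr_peak, temp_peak,
                                   params, criteria = deterioration_criteria()) {
  hr_delay <- criteria$hr_drop_fraction * hr_peak / params$hr_decline_slope
  temp_delay <- criteria$temp_drop_fraction * (temp_peak - criteria$temp_floor) /
    params$temp_decline_slope
  onset + pmax(hr_delay, temp_delay)
}
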