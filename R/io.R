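# CSV (RFC-4180, UTF-8, '.' decimal) is the single tabular format; JSON for
# summaries. Numerics are written with 17 significant digits so reading a
# file back reproduces the doubles bit-for-bit.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, "")
  out
}

#' Write / read telemetry traces (long CSV)
#'
#' Long format with columns `mouse_id, time_min, heart_rate_bpm,
#' core_temp_c, activity`; the activity column is optional on read. Reading
#' validates each mouse's trace (monotone uniform time axis, physiologic
#' ranges) and reports offending mice and columns.
#'
#' @param cohort A `telemetry_cohort` (list of traces).
#' @param path CSV path.
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns a `telemetry_cohort`.
#' @export
write_traces <- function(cohort, path) {
  stopifnot(is.list(cohort))
  long <- do.call(rbind, lapply(cohort, function(tr) {
    df <- as.data.frame(tr)
    df$mouse_id <- attr(tr, "mouse_id")
    df
  }))
  out <- data.frame(
    mouse_id = long$mouse_id,
    time_min = fmt_num(long$time_min),
    heart_rate_bpm = fmt_num(long$heart_rate_bpm),
    core_temp_c = fmt_num(long$core_temp_c),
    activity = if ("activity" %in% names(long)) fmt_num(long$activity) else ""
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop_input("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "time_min", "heart_rate_bpm", "core_temp_c")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input("trace file ", path, " missing columns: ",
               paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(c("time_min", "heart_rate_bpm", "core_temp_c", "activity"),
                        names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  has_act <- "activity" %in% names(df) && !all(is.na(df$activity))
  traces <- lapply(split(df, df$mouse_id), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    cols <- c("time_min", "heart_rate_bpm", "core_temp_c",
              if (has_act) "activity")
    tr <- g[, cols, drop = FALSE]
    rownames(tr) <- NULL
    tryCatch(
      new_telemetry_trace(tr, mouse_id = g$mouse_id[1]),
      error = function(e) {
        stop_input("mouse ", g$mouse_id[1], " in ", path, ": ",
                   conditionMessage(e))
      }
    )
  })
  structure(unname(traces), class = "telemetry_cohort")
}

#' Write / read a cohort outcome table
#'
#' Columns `mouse_id, time_to_criteria_min, censored, season,
#' ambient_temp_c`; the censoring invariant is validated on read, with
#' offending mouse ids in the error.
#'
#' @param outcomes A [mouse_outcomes()] table.
#' @param path CSV path.
#' @param horizon Horizon (minutes) used for validation on read.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `mouse_outcomes` table.
#' @export
write_cohort <- function(outcomes, path) {
  validate_outcomes(outcomes, horizon = Inf)
  out <- data.frame(
    mouse_id = outcomes$mouse_id,
    time_to_criteria_min = fmt_num(outcomes$time_to_criteria_min),
    censored = outcomes$censored,
    season = ifelse(is.na(outcomes$season), "", outcomes$season),
    ambient_temp_c = fmt_num(outcomes$ambient_temp_c)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, horizon = 1440) {
  if (!file.exists(path)) stop_input("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mouse_id = "character"))
  need <- c("mouse_id", "time_to_criteria_min", "censored")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input("cohort file ", path, " missing columns: ",
               paste(missing_cols, collapse = ", "))
  }
  season <- if ("season" %in% names(df)) {
    ifelse(is.na(df$season) | df$season == "", NA_character_, df$season)
  } else NULL
  amb <- if ("ambient_temp_c" %in% names(df)) df$ambient_temp_c else NULL
  mouse_outcomes(
    mouse_id = df$mouse_id,
    time_to_criteria_min = df$time_to_criteria_min,
    censored = df$censored,
    season = season,
    ambient_temp_c = amb,
    horizon = horizon
  )
}

#' Write a capture table as CSV
#'
#' @param table A [capture_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_capture_table <- function(table, path) {
  stopifnot(inherits(table, "capture_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: obtain a cohort (simulate traces and detect, use the
#' deterministic reference cohort, or read an existing cohort CSV), build
#' the hourly capture table, pick the best window, derive the sample-size
#' plan, and run the cost model at the observed capture proportion. Writes
#' `capture_table.csv`, `cohort.csv`, `equivalency_table.csv` and
#' `summary.json` into `out_dir`; every output carries the seed and a hash
#' of the configuration, and a rerun with the same config is byte-identical.
#'
#' @param config A list with elements:
#'   * `source`: `"simulate"` (default), `"reference"`, or `"file"`;
#'   * `cohort_file`: path, required when `source = "file"`;
#'   * `seed`: integer seed (default 1), used for simulation;
#'   * `sim`: list of [sim_params()] overrides;
#'   * `criteria`: list of [deterioration_criteria()] overrides;
#'   * `tolerance`: capture half-width in minutes (default 30);
#'   * `cost`: list of [cost_parameters()] overrides;
#'   * `q_target`: planned quality mice (default 120);
#'   * `equivalency_costs`: per-mouse costs for the equivalency table
#'     (default `c(50, 100, 150, 200, 250)`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the cohort, capture table, plan,
#'   equivalency table and the summary list written to JSON.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(source = "reference"), tempfile("run"))
#' out$summary$best_window
#' }
#' @export
run_pipeline <- function(config = list(), out_dir) {
  source <- config$source %||% "simulate"
  if (!source %in% c("simulate", "reference", "file")) {
    stop_input("`config$source` must be one of simulate/reference/file")
  }
  if (source == "file") {
    if (is.null(config$cohort_file)) stop_input("`config$cohort_file` is required")
    if (!file.exists(config$cohort_file)) {
      stop_input("cohort file not found: ", config$cohort_file)
    }
  }
  seed <- config$seed %||% 1L
  tolerance <- config$tolerance %||% 30
  criteria <- do.call(deterioration_criteria, config$criteria %||% list())
  cost_par <- do.call(cost_parameters, config$cost %||% list())
  q_target <- config$q_target %||% 120L
  eq_costs <- config$equivalency_costs %||% c(50, 100, 150, 200, 250)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  outcomes <- switch(source,
    simulate = {
      sim_args <- config$sim %||% list()
      sim_args$seed <- seed
      params <- do.call(sim_params, sim_args)
      detect_cohort(simulate_cohort(params), criteria)
    },
    reference = reference_cohort(horizon = criteria$horizon),
    file = read_cohort(config$cohort_file, horizon = criteria$horizon)
  )

  tab <- capture_table(outcomes, tolerance = tolerance)
  best <- best_window(tab)
  p_hat <- tab$window_prop[tab$hour == best]
  plan <- sample_size_plan(p_hat, q_target, n = attr(tab, "n_analyzed"))
  eq_tab <- equivalency_table(eq_costs, p_hat, cost_par)
  inc <- incremental_cost_per_quality_mouse(q_target, cost_par$cost_per_mouse,
                                            p_hat, cost_par)

  write_cohort(outcomes, file.path(out_dir, "cohort.csv"))
  write_capture_table(tab, file.path(out_dir, "capture_table.csv"))
  utils::write.csv(eq_tab, file.path(out_dir, "equivalency_table.csv"),
                   row.names = FALSE, quote = FALSE)

  summary <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    n_mice = nrow(outcomes),
    n_censored = sum(outcomes$censored),
    median_time_to_criteria_min =
      stats::median(outcomes$time_to_criteria_min[!outcomes$censored]),
    best_window = best,
    capture_proportion = p_hat,
    fold_increase = plan$fold_increase,
    required_total = plan$required_total,
    incremental_cost_per_quality_mouse = round_half_up(inc, 2),
    equivalency_cost_at_q_target =
      round_half_up(equivalency_cost(q_target, p_hat, cost_par), 2)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(outcomes = outcomes, capture_table = tab, plan = plan,
                 equivalency_table = eq_tab, summary = summary))
}
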