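#' Hourly capture-window table
#'
#' For each whole hour `h` after CLP, computes the proportion of
#' deteriorating mice whose time-to-criteria falls within `h` plus or minus
#' `tolerance` minutes -- the fraction an investigator treating at the fixed
#' time `h` would "capture" at the point of acute deterioration -- together
#' with the cumulative proportion already at or past criteria and the
#' fraction not yet there. Windows are half-open,
#' `[h*60 - tolerance, h*60 + tolerance)`, so that with the default 30-minute
#' tolerance consecutive hourly windows partition the time axis and every
#' uncensored time falls in exactly one window.
#'
#' Denominators use the uncensored (deteriorating) mice only; censored mice
#' are excluded from the variability analysis.
#'
#' @param outcomes A [mouse_outcomes()] table with at least one uncensored
#'   mouse.
#' @param tolerance Window half-width in minutes (default 30).
#' @param hours Integer hours to tabulate (default 4 to 24).
#' @return A `capture_table` data.frame with columns `hour`, `window_count`,
#'   `window_prop`, `window_pct` (whole percent, half-up),
#'   `cumulative_prop`, `past_prop`, `not_yet_prop`, and attribute
#'   `n_analyzed`.
#' @examples
#' capture_table(reference_cohort())[1:6, ]
#' @export
capture_table <- function(outcomes, tolerance = 30, hours = 4:24) {
  validate_outcomes(outcomes, horizon = Inf)
  if (!is_scalar_num(tolerance) || tolerance <= 0) {
    stop_input("`tolerance` must be positive")
  }
  t <- outcomes$time_to_criteria_min[!outcomes$censored]
  n <- length(t)
  if (n == 0L) stop_input("no uncensored mice to analyze")

  lo <- hours * 60 - tolerance
  hi <- hours * 60 + tolerance
  window_count <- vapply(seq_along(hours),
                         function(i) sum(t >= lo[i] & t < hi[i]), 0L)
  tab <- data.frame(
    hour = hours,
    window_count = window_count,
    window_prop = window_count / n,
    window_pct = round_half_up(100 * window_count / n),
    cumulative_prop = vapply(hi, function(h) sum(t < h), 0L) / n,
    past_prop = vapply(lo, function(l) sum(t < l), 0L) / n,
    not_yet_prop = vapply(hi, function(h) sum(t >= h), 0L) / n
  )
  attr(tab, "n_analyzed") <- n
  attr(tab, "tolerance") <- tolerance
  class(tab) <- c("capture_table", "data.frame")
  tab
}

#' @export
print.capture_table <- function(x, ...) {
  cat(sprintf("Hourly capture table (+/- %g min windows, %d deteriorating mice)\n",
              attr(x, "tolerance"), attr(x, "n_analyzed")))
  df <- data.frame(
    hour = x$hour,
    meeting_pct = x$window_pct,
    cumulative_pct = round_half_up(100 * x$cumulative_prop),
    past_pct = round_half_up(100 * x$past_prop),
    not_yet_pct = round_half_up(100 * x$not_yet_prop)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Best single capture window
#'
#' The hour whose window captures the largest proportion of deteriorating
#' mice; ties are broken in favour of the earliest hour.
#'
#' @param table A [capture_table()].
#' @return The winning hour (integer).
#' @examples
#' best_window(capture_table(reference_cohort()))
#' @export
best_window <- function(table) {
  stopifnot(inherits(table, "capture_table"))
  table$hour[which.max(table$window_prop)]
}

#' Sample-size implications of a capture proportion
#'
#' If a fixed-time-point design captures a fraction `p_hat` of mice at
#' criteria, achieving `q_target` mice treated at deterioration requires
#' `q_target / p_hat` animals: a `1 / p_hat`-fold increase over a
#' physiologically enrolled design.
#'
#' @param p_hat Capture proportion, in (0, 1].
#' @param q_target Required number of quality mice.
#' @param n Optional window denominator; when given, a binomial confidence
#'   interval on `p_hat` (from `round(p_hat * n)` successes) is attached.
#' @param ci_method Passed to [binomial_ci()].
#' @return A `sample_size_plan` list: `p_hat`, `fold_increase` (2 dp),
#'   `required_total` (next whole mouse), `q_target`, and optionally
#'   `ci_low_pct`, `ci_high_pct`.
#' @examples
#' sample_size_plan(0.28, 120, n = 107)
#' @export
sample_size_plan <- function(p_hat, q_target, n = NULL, ci_method = "wald") {
  if (!is_scalar_num(p_hat) || p_hat <= 0 || p_hat > 1) {
    stop_input("`p_hat` must lie in (0, 1]")
  }
  if (!is_count(q_target) || q_target < 1) stop_input("`q_target` must be >= 1")
  plan <- list(
    p_hat = p_hat,
    fold_increase = round_half_up(1 / p_hat, 2),
    required_total = ceiling(round(q_target / p_hat, 9)),
    q_target = q_target
  )
  if (!is.null(n)) {
    ci <- binomial_ci(round_half_up(p_hat * n), n, method = ci_method)
    plan$ci_low_pct <- ci$low_pct
    plan$ci_high_pct <- ci$high_pct
  }
  structure(plan, class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat(sprintf(
    "Capture proportion %.3f: %.2f-fold increase; %d mice for %d at criteria\n",
    x$p_hat, x$fold_increase, x$required_total, x$q_target
  ))
  if (!is.null(x$ci_low_pct)) {
    cat(sprintf("  95%% CI on capture proportion: %g-%g%%\n",
                x$ci_low_pct, x$ci_high_pct))
  }
  invisible(x)
}

#' Binomial confidence interval on a proportion, in percent
#'
#' @param successes,n Counts, `0 <= successes <= n`.
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default), `"wilson"` (score, no continuity
#'   correction) or `"clopper-pearson"` (exact).
#' @return A list with `low`, `high` (proportions, clamped to \[0, 1\]) and
#'   `low_pct`, `high_pct` (whole percent, half-up).
#' @examples
#' binomial_ci(30, 107)
#' binomial_ci(30, 107, method = "clopper-pearson")
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (!is_count(successes) || !is_count(n) || n < 1 || successes > n) {
    stop_input("need 0 <= successes <= n with n >= 1")
  }
  ci <- switch(method,
    wald = {
      p <- successes / n
      half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    wilson = stats::prop.test(successes, n, conf.level = level,
                              correct = FALSE)$conf.int,
    `clopper-pearson` = stats::binom.test(successes, n,
                                          conf.level = level)$conf.int
  )
  ci <- pmin(pmax(as.numeric(ci), 0), 1)
  list(
    low = ci[1], high = ci[2],
    low_pct = round_half_up(100 * ci[1]),
    high_pct = round_half_up(100 * ci[2]),
    method = method
  )
}

#' Exact McNemar test for paired capture comparisons
#'
#' Two capture windows are compared on the same cohort of mice: with
#' disjoint hourly windows, the discordant pairs are exactly the mice
#' captured by one window and not the other, so the discordant counts equal
#' the window counts themselves. The exact two-sided p-value is the binomial
#' sign-test probability
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`. A
#' continuity-corrected chi-squared variant is available for comparison.
#'
#' @param b,c Discordant counts (non-negative integers).
#' @param method `"exact"` (default) or `"chisq"` (continuity-corrected).
#' @return The two-sided p-value. `b = c = 0` returns 1 by convention.
#' @examples
#' mcnemar_exact(30, 13)  # 8 h vs 6 h window counts
#' @export
mcnemar_exact <- function(b, c, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (!is_count(b) || !is_count(c)) stop_input("`b` and `c` must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  if (method == "exact") {
    min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  } else {
    stats::mcnemar.test(matrix(c(0, c, b, 0), 2, 2), correct = TRUE)$p.value
  }
}

#' Pairwise window comparison
#'
#' Convenience wrapper building a `window_comparison` from a capture table:
#' takes the counts of two hours and runs [mcnemar_exact()].
#'
#' @param table A [capture_table()].
#' @param hour_a,hour_b Hours to compare.
#' @return A list with the two counts and the exact p-value.
#' @export
compare_windows <- function(table, hour_a, hour_b) {
  stopifnot(inherits(table, "capture_table"))
  ca <- table$window_count[table$hour == hour_a]
  cb <- table$window_count[table$hour == hour_b]
  if (!length(ca) || !length(cb)) stop_input("hours not present in table")
  structure(
    list(hour_a = hour_a, hour_b = hour_b, count_a = ca, count_b = cb,
         p_value = mcnemar_exact(ca, cb)),
    class = "window_comparison"
  )
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("%d h (%d mice) vs %d h (%d mice): exact McNemar p = %.4f\n",
              x$hour_a, x$count_a, x$hour_b, x$count_b, x$p_value))
  invisible(x)
}

#' Fisher's exact test for a 2 x k table
#'
#' Exact conditional test with fixed margins, used for comparing capture
#' proportions across (up to four) seasonal sub-cohorts. Delegates to the
#' exact network algorithm in [stats::fisher.test()]; a guard rejects tables
#' too large for exact enumeration.
#'
#' @param tab A 2-row matrix of non-negative integer counts, `k <= 4`
#'   columns.
#' @return The exact two-sided p-value.
#' @examples
#' fisher_exact_2xk(matrix(c(1, 11, 9, 3), nrow = 2))
#' @export
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || ncol(tab) < 2L || ncol(tab) > 4L) {
    stop_input("`tab` must be 2 x k with 2 <= k <= 4")
  }
  if (any(tab < 0) || any(tab != trunc(tab))) {
    stop_input("`tab` must hold non-negative integers")
  }
  if (sum(tab) > 500) {
    stop_input("table total exceeds exact-enumeration capability (500)")
  }
  stats::fisher.test(tab)$p.value
}

#' Seasonal stratification of time-to-criteria
#'
#' Splits the deteriorating mice by season of experimentation and reports,
#' per season, the median and IQR of time-to-criteria and the capture
#' proportion at a chosen hour; across seasons, a Kruskal-Wallis test on
#' time-to-criteria and Fisher's exact test on the capture proportions; and,
#' when ambient temperatures are recorded, the Spearman rank correlation of
#' ambient temperature with time-to-criteria.
#'
#' @param outcomes A [mouse_outcomes()] table with `season` filled in (and
#'   optionally `ambient_temp_c`).
#' @param hour Capture hour for the proportion comparison (default 8).
#' @param tolerance Window half-width in minutes (default 30).
#' @return A `seasonal_summary` list: `per_season` data.frame (`season`,
#'   `n`, `median_min`, `iqr_low`, `iqr_high`, `capture_count`,
#'   `capture_prop`), `kruskal_p`, `capture_fisher_p`, and `spearman_rho`,
#'   `spearman_p` (NA when no ambient temperatures are available).
#' @export
seasonal_analysis <- function(outcomes, hour = 8, tolerance = 30) {
  validate_outcomes(outcomes, horizon = Inf)
  d <- outcomes[!outcomes$censored & !is.na(outcomes$season), , drop = FALSE]
  counts <- table(d$season)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop_input("need >= 2 seasons with >= 2 deteriorating mice each")
  }
  d$season <- factor(d$season, levels = intersect(
    c("winter", "spring", "summer", "fall"), unique(d$season)
  ))

  lo <- hour * 60 - tolerance
  hi <- hour * 60 + tolerance
  per <- do.call(rbind, lapply(split(d, d$season), function(g) {
    q <- stats::quantile(g$time_to_criteria_min, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      season = as.character(g$season[1]),
      n = nrow(g),
      median_min = q[2], iqr_low = q[1], iqr_high = q[3],
      capture_count = sum(g$time_to_criteria_min >= lo & g$time_to_criteria_min < hi),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  per$capture_prop <- per$capture_count / per$n

  kw <- stats::kruskal.test(d$time_to_criteria_min, d$season)
  fisher_p <- fisher_exact_2xk(rbind(per$capture_count, per$n - per$capture_count))

  rho <- p_rho <- NA_real_
  has_temp <- !is.na(d$ambient_temp_c)
  if (sum(has_temp) >= 3) {
    ct <- stats::cor.test(d$ambient_temp_c[has_temp],
                          d$time_to_criteria_min[has_temp],
                          method = "spearman", exact = FALSE)
    rho <- unname(ct$estimate)
    p_rho <- ct$p.value
  }

  structure(
    list(per_season = per, kruskal_p = kw$p.value,
         capture_fisher_p = fisher_p,
         spearman_rho = rho, spearman_p = p_rho,
         hour = hour),
    class = "seasonal_summary"
  )
}

#' @export
print.seasonal_summary <- function(x, ...) {
  cat("Seasonal stratification of time-to-criteria\n")
  df <- x$per_season
  df$median_iqr <- sprintf("%.0f (%.0f-%.0f)", df$median_min, df$iqr_low, df$iqr_high)
  df$capture <- sprintf("%d/%d (%.0f%%)", df$capture_count, df$n, 100 * df$capture_prop)
  print.data.frame(df[, c("season", "n", "median_iqr", "capture")], row.names = FALSE)
  cat(sprintf("Kruskal-Wallis p = %.3f; %d-h capture Fisher p = %.3f\n",
              x$kruskal_p, x$hour, x$capture_fisher_p))
  if (!is.na(x$spearman_rho)) {
    cat(sprintf("Spearman (ambient temp vs time): rho = %.3f, p = %.3f\n",
                x$spearman_rho, x$spearman_p))
  }
  invisible(x)
}
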