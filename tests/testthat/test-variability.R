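# Published hourly capture column (% of deteriorating mice per whole-hour
# window, hours 4-23) that the reference cohort must reproduce.
published_window_pct <- c(0, 2, 12, 24, 28, 10, 5, 4, 2, 3, 3, 1, 1, 1,
                          0, 0, 0, 0, 1, 2)

test_that("capture table on the reference cohort reproduces the published column", {
  tab <- capture_table(reference_cohort())
  expect_equal(attr(tab, "n_analyzed"), 107)
  expect_equal(tab$window_pct[tab$hour %in% 4:23], published_window_pct)
  i8 <- tab$hour == 8
  expect_equal(tab$window_count[i8], 30)
  expect_equal(tab$window_pct[i8], 28)
  expect_true(all(diff(tab$cumulative_prop) >= 0))
  expect_true(all(tab$cumulative_prop <= 1))
})

test_that("window, past and not-yet fractions partition the analyzable cohort", {
  for (oc in list(reference_cohort(),
                  detect_cohort(simulate_cohort(sim_params(n_mice = 40, seed = 8))))) {
    tab <- capture_table(oc)
    expect_equal(tab$window_prop + tab$past_prop + tab$not_yet_prop,
                 rep(1, nrow(tab)))
    # contiguous half-open hourly windows: each time in exactly one window
    t <- oc$time_to_criteria_min[!oc$censored]
    in_range <- t >= 210 & t < 1470
    expect_equal(sum(tab$window_count), sum(in_range))
  }
})

test_that("degenerate cohorts are handled", {
  one_time <- mouse_outcomes(sprintf("m%d", 1:107), rep(480, 107),
                             rep(FALSE, 107))
  tab <- capture_table(one_time)
  expect_equal(tab$window_pct[tab$hour == 8], 100)
  expect_true(all(tab$window_pct[tab$hour != 8] == 0))

  all_cen <- mouse_outcomes(c("a", "b"), c(NA, NA), c(TRUE, TRUE))
  expect_error(capture_table(all_cen), "no uncensored")
})

test_that("best_window picks the maximal hour with earliest-hour tie-breaking", {
  expect_equal(best_window(capture_table(reference_cohort())), 8)

  # uniform proportions tie -> earliest hour wins
  flat <- mouse_outcomes(sprintf("m%d", 1:21), (4:24) * 60, rep(FALSE, 21))
  expect_equal(best_window(capture_table(flat)), 4)

  spike <- mouse_outcomes(sprintf("m%d", 1:3), c(415, 420, 425), rep(FALSE, 3))
  expect_equal(best_window(capture_table(spike)), 7)
})

test_that("sample-size plan reproduces the fold increase and required totals", {
  plan <- sample_size_plan(0.28, 120, n = 107)
  expect_equal(plan$fold_increase, 3.57)
  expect_equal(plan$required_total, 429)
  expect_equal(plan$ci_low_pct, 20)

  expect_equal(sample_size_plan(1, 120)$fold_increase, 1)
  expect_equal(sample_size_plan(1, 120)$required_total, 120)
  expect_equal(sample_size_plan(0.5, 101)$required_total, 202)
  expect_error(sample_size_plan(0, 120), "0, 1")
})

test_that("binomial CI lower bound is 20% for 30/107 under all three methods", {
  for (m in c("wald", "wilson", "clopper-pearson")) {
    ci <- binomial_ci(30, 107, method = m)
    expect_equal(ci$low_pct, 20)
    expect_true(ci$high_pct %in% c(36, 37, 38))
  }
  expect_equal(binomial_ci(0, 50)$low_pct, 0)
  expect_equal(unlist(binomial_ci(107, 107)[c("low_pct", "high_pct")]),
               c(low_pct = 100, high_pct = 100))
})

test_that("Clopper-Pearson interval holds nominal coverage at p = 0.28, n = 107", {
  set.seed(4242)
  x <- rbinom(10000, 107, 0.28)
  lo <- qbeta(0.025, x, 107 - x + 1)
  hi <- qbeta(0.975, x + 1, 107 - x)
  lo[x == 0] <- 0
  hi[x == 107] <- 1
  coverage <- mean(lo <= 0.28 & 0.28 <= hi)
  expect_gte(coverage, 0.95)
  # and the package's interval agrees with the beta quantile form
  ci <- binomial_ci(30, 107, method = "clopper-pearson")
  expect_equal(ci$low, qbeta(0.025, 30, 78), tolerance = 1e-8)
})

test_that("exact McNemar reproduces published and derived comparisons", {
  # 8 h vs 6 h windows: 30 vs 13 discordant captures
  expect_equal(round(mcnemar_exact(30, 13), 2), 0.01)
  # symmetric counts give p = 1, as does the empty case
  expect_equal(mcnemar_exact(5, 5), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  # 8 h vs 7 h: exact value from the binomial-tail oracle
  expect_equal(mcnemar_exact(30, 26), 0.6888798, tolerance = 1e-6)
  expect_equal(mcnemar_exact(30, 26), mcnemar_brute(30, 26), tolerance = 1e-12)
  # symmetry in (b, c)
  expect_equal(mcnemar_exact(30, 13), mcnemar_exact(13, 30))
})

test_that("exact McNemar equals brute-force enumeration for all b + c <= 16", {
  for (n in 1:16) {
    for (b in 0:n) {
      expect_equal(mcnemar_exact(b, n - b), mcnemar_brute(b, n - b),
                   tolerance = 1e-12)
    }
  }
})

test_that("continuity-corrected chi-squared variant is available", {
  p_exact <- mcnemar_exact(30, 13)
  p_chi <- mcnemar_exact(30, 13, method = "chisq")
  expect_true(p_chi > 0 && p_chi < 0.05)
  expect_false(identical(p_exact, p_chi))
})

test_that("window comparisons read counts from the capture table", {
  tab <- capture_table(reference_cohort())
  cmp <- compare_windows(tab, 8, 6)
  expect_equal(cmp$count_a, 30)
  expect_equal(cmp$count_b, 13)
  expect_equal(round(cmp$p_value, 2), 0.01)
})

test_that("Fisher 2xk matches hypergeometric enumeration", {
  tab22 <- matrix(c(1, 11, 9, 3), nrow = 2)
  expect_equal(fisher_exact_2xk(tab22), 0.002759456, tolerance = 1e-6)
  expect_equal(fisher_exact_2xk(tab22), fisher_brute_2xk(tab22),
               tolerance = 1e-6)

  tab23 <- matrix(c(4, 2, 1, 6, 5, 3), nrow = 2)
  expect_equal(fisher_exact_2xk(tab23), fisher_brute_2xk(tab23),
               tolerance = 1e-6)

  expect_equal(fisher_exact_2xk(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2xk(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin
  expect_error(fisher_exact_2xk(matrix(1000L, 2, 2)), "capability|enumeration")
  expect_error(fisher_exact_2xk(matrix(1, 3, 2)), "2 x k")
})

make_seasonal <- function(n_per = 30, shift = c(0, 0, 0, 0), seed = 1) {
  seasons <- c("winter", "spring", "summer", "fall")
  set.seed(seed)
  times <- unlist(lapply(seq_along(seasons), function(i) {
    rlnorm(n_per, log(465) + shift[i] / 465, 0.16)
  }))
  mouse_outcomes(
    sprintf("s%03d", seq_len(4 * n_per)),
    pmin(times, 1440), rep(FALSE, 4 * n_per),
    season = rep(seasons, each = n_per),
    ambient_temp_c = rep(21, 4 * n_per) + rnorm(4 * n_per, 0, 1)
  )
}

test_that("seasonal analysis under the null shows no effect", {
  s <- seasonal_analysis(make_seasonal(seed = 99))
  expect_equal(nrow(s$per_season), 4)
  expect_gt(s$kruskal_p, 0.01)
  expect_lt(abs(s$spearman_rho), 0.35)
  expect_true(all(s$per_season$n == 30))
})

test_that("a 120-minute seasonal shift is detected in at least 80% of replicates", {
  hits <- vapply(1:500, function(s) {
    oc <- make_seasonal(shift = c(120, 0, 0, 0), seed = s)
    seasonal_analysis(oc)$kruskal_p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("a perfectly monotone temperature-time relation gives Spearman rho 1", {
  oc <- mouse_outcomes(
    sprintf("m%d", 1:20), 300 + (1:20) * 10, rep(FALSE, 20),
    season = rep(c("winter", "summer"), each = 10),
    ambient_temp_c = 15 + (1:20) * 0.3
  )
  s <- seasonal_analysis(oc)
  expect_equal(s$spearman_rho, 1)
})

test_that("seasonal analysis demands at least two populated seasons", {
  oc <- mouse_outcomes(c("a", "b", "c"), c(400, 450, 500), rep(FALSE, 3),
                       season = rep("winter", 3))
  expect_error(seasonal_analysis(oc), "seasons")
})
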