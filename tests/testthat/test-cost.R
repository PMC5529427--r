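par <- cost_parameters()

test_that("setup cost steps by one battery set per 120-mouse cycle", {
  expect_equal(setup_cost(1, par), 35946.50)
  expect_equal(setup_cost(120, par), 35946.50)
  expect_equal(setup_cost(240, par), 38351.50)
  expect_equal(setup_cost(121, par) - setup_cost(120, par), 2405)
  # non-decreasing step function with jumps exactly at cycle multiples
  q <- 1:600
  sc <- setup_cost(q, par)
  jumps <- diff(sc)
  expect_true(all(jumps >= 0))
  expect_equal(which(jumps > 0), c(120, 240, 360, 480))
  expect_true(all(jumps[jumps > 0] == 2405))
  expect_error(setup_cost(0, par), ">= 1")
})

test_that("fixed-time-point animal requirement keeps fractional and integer forms", {
  s <- standard_mice_needed(120, 0.28)
  expect_equal(s$count, 429)
  expect_equal(s$fractional, 120 / 0.28)
  expect_equal(standard_mice_needed(120, 1)$count, 120)
  expect_equal(standard_mice_needed(317, 0.28)$fractional, 1132.142857,
               tolerance = 1e-6)
  expect_error(standard_mice_needed(120, 0), "0, 1")
})

test_that("incremental cost per quality mouse matches the closed form", {
  expect_equal(round(incremental_cost_per_quality_mouse(120, 25, 0.28, par), 2),
               235.27)
  # with free animals the increment is pure equipment amortisation
  expect_equal(incremental_cost_per_quality_mouse(120, 0, 0.28, par),
               35946.50 / 120)
  # at the equivalency cost the increment is zero by definition
  c_eq <- equivalency_cost(120, 0.28, par)
  expect_equal(incremental_cost_per_quality_mouse(120, c_eq, 0.28, par), 0,
               tolerance = 1e-10)
})

test_that("equivalency cost-per-mouse reproduces the break-even points", {
  expect_equal(round(equivalency_cost(120, 0.28, par), 2), 116.49)
  expect_equal(round(equivalency_cost(240, 0.28, par), 2), 62.14)
  expect_equal(round(equivalency_cost(360, 0.28, par), 2), 44.03)
  expect_error(equivalency_cost(120, 1, par), "p = 1|0, 1")
})

test_that("equivalency cost strictly decreases in Q within a battery tier", {
  for (tier_q in list(10:120, 121:240, 241:360)) {
    ec <- equivalency_cost(tier_q, 0.28, par)
    expect_true(all(diff(ec) < 0))
  }
})

test_that("the tier-consistent solver reproduces the published equivalency rows", {
  r50 <- equivalency_quality_mice(50, 0.28, par)
  expect_equal(r50$quality_mice, 317)
  expect_equal(r50$battery_replacements, 2)

  r250 <- equivalency_quality_mice(250, 0.28, par)
  expect_equal(r250$quality_mice, 56)
  expect_equal(r250$standard_mice, 200)
  expect_equal(r250$mice_spared, 144)
  expect_equal(r250$battery_replacements, 0)
})

test_that("without battery steps the solver collapses to the closed form", {
  p0 <- cost_parameters(battery_set_cost = 0)
  for (cv in c(40, 80, 160, 320)) {
    r <- equivalency_quality_mice(cv, 0.28, p0)
    expect_equal(r$quality_mice,
                 round(35946.50 / (cv * (1 / 0.28 - 1))))
  }
})

test_that("solve and evaluate round-trip at tier-interior points", {
  for (q in c(60, 110, 150, 230, 290, 350)) {
    c_eq <- equivalency_cost(q, 0.28, par)
    r <- equivalency_quality_mice(c_eq, 0.28, par)
    expect_lte(abs(r$quality_mice - q), 1)
  }
})

test_that("mice spared plus quality mice always equals the standard requirement", {
  for (cv in c(30, 50, 116.49, 150, 250, 400)) {
    r <- equivalency_quality_mice(cv, 0.28, par)
    expect_equal(r$mice_spared + r$quality_mice, r$standard_mice)
    expect_gte(r$standard_mice, r$quality_mice)
  }
})

test_that("the incremental difference curve is exactly linear with the stated slope", {
  cv <- seq(0, 500, by = 12.5)
  curve <- incremental_cost_difference_curve(cv, 120, 0.28, par)
  fit <- lm(difference ~ cost_per_mouse, data = curve)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[2]), 120 - 120 / 0.28, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), setup_cost(120, par))
  # zero crossing at the equivalency cost
  c_eq <- equivalency_cost(120, 0.28, par)
  at_eq <- incremental_cost_difference_curve(c_eq, 120, 0.28, par)
  expect_equal(at_eq$difference, 0, tolerance = 1e-9)
})

test_that("two-way sensitivity grid flips sign across the equivalency boundary", {
  g <- two_way_sensitivity(c(10, 116.4933, 500), c(120, 240, 360), 0.28, par)
  on_boundary <- g$grid[g$grid$Q == 120 & g$grid$cost_per_mouse == 116.4933, ]
  expect_equal(on_boundary$difference, 0, tolerance = 0.1)
  cheap <- g$grid[g$grid$cost_per_mouse == 10, ]
  dear <- g$grid[g$grid$cost_per_mouse == 500, ]
  expect_true(all(cheap$favors == "standard"))
  expect_true(all(dear$favors == "biotelemetry"))
  # boundary is non-increasing across these tier-interior Q values
  expect_true(all(diff(g$boundary$equivalency_cost) < 0))
  # sign flips exactly once along the cost axis for fixed Q
  cv <- seq(1, 500, by = 1)
  d <- incremental_cost_difference_curve(cv, 240, 0.28, par)$difference
  expect_equal(sum(diff(sign(d)) != 0), 1)
})

test_that("cost parameter validation", {
  expect_error(cost_parameters(system_cost = -1), "non-negative")
  expect_error(cost_parameters(capture_proportion = 0), "0, 1")
  expect_error(equivalency_quality_mice(-5, 0.28, par), "positive")
})
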