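#' Cost parameters for the biotelemetry vs fixed-time-point comparison
#'
#' Equipment economics of an implanted-biotelemetry CLP programme: a one-off
#' monitoring system, an initial set of four implantable devices, and a
#' battery-refurbishment set purchased after each block of
#' `mice_per_cycle` single-day experiments (four devices times roughly
#' thirty 24-hour experiments per battery). `capture_proportion` is the
#' fraction of mice a fixed-time-point design treats at the point of acute
#' deterioration (0.28 for the best single hour in the reference cohort).
#'
#' @param system_cost Monitoring system, initial purchase (USD).
#' @param device_set_cost Set of four implantable devices (USD).
#' @param battery_set_cost Battery replacement, set of four (USD).
#' @param mice_per_cycle Monitored experiments per battery cycle.
#' @param cost_per_mouse Default per-animal cost (purchase, husbandry,
#'   veterinary care, drugs, sample analysis), USD.
#' @param capture_proportion Default fixed-time-point capture proportion.
#' @return A `cost_parameters` object.
#' @export
cost_parameters <- function(system_cost = 24336.50,
                            device_set_cost = 11610,
                            battery_set_cost = 2405,
                            mice_per_cycle = 120,
                            cost_per_mouse = 25,
                            capture_proportion = 0.28) {
  if (any(c(system_cost, device_set_cost, battery_set_cost, cost_per_mouse) < 0)) {
    stop_input("costs must be non-negative")
  }
  if (!is_count(mice_per_cycle) || mice_per_cycle < 1) {
    stop_input("`mice_per_cycle` must be >= 1")
  }
  if (!is_scalar_num(capture_proportion) ||
      capture_proportion <= 0 || capture_proportion > 1) {
    stop_input("`capture_proportion` must lie in (0, 1]")
  }
  structure(
    list(system_cost = system_cost, device_set_cost = device_set_cost,
         battery_set_cost = battery_set_cost,
         mice_per_cycle = as.integer(mice_per_cycle),
         cost_per_mouse = cost_per_mouse,
         capture_proportion = capture_proportion),
    class = "cost_parameters"
  )
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Biotelemetry cost parameters (USD)\n")
  cat(sprintf("  system %.2f + devices %.2f; battery set %.2f per %d mice\n",
              x$system_cost, x$device_set_cost, x$battery_set_cost, x$mice_per_cycle))
  cat(sprintf("  cost per mouse %.2f; fixed-time capture proportion %.2f\n",
              x$cost_per_mouse, x$capture_proportion))
  invisible(x)
}

#' Stepped equipment setup cost
#'
#' Equipment cost of monitoring `Q` quality mice: system plus initial device
#' set, plus one battery set per additional block of `mice_per_cycle`
#' experiments beyond the first (the initial purchase covers the first
#' block). A non-decreasing step function of `Q` with jumps of exactly the
#' battery-set cost at multiples of the cycle size.
#'
#' @param Q Number of quality (monitored) mice; vectorised.
#' @param params A [cost_parameters()] object.
#' @return Setup cost(s) in USD.
#' @examples
#' setup_cost(c(1, 120, 121, 240), cost_parameters())
#' @export
setup_cost <- function(Q, params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  if (any(Q < 1)) stop_input("`Q` must be >= 1")
  params$system_cost + params$device_set_cost +
    params$battery_set_cost * (ceiling(Q / params$mice_per_cycle) - 1)
}

#' Fixed-time-point animals needed for Q quality mice
#'
#' A design treating at a fixed time point captures only a proportion `p`
#' of animals at criteria, so `Q / p` animals are required. The fractional
#' value is retained for cost algebra; the integer report rounds up to the
#' next whole mouse.
#'
#' @param Q Quality mice required.
#' @param p Capture proportion, in (0, 1].
#' @return A list with `fractional` (`Q / p`) and `count`
#'   (`ceiling(Q / p)`).
#' @examples
#' standard_mice_needed(120, 0.28)
#' @export
standard_mice_needed <- function(Q, p) {
  if (!is_scalar_num(p) || p <= 0 || p > 1) stop_input("`p` must lie in (0, 1]")
  if (any(Q < 1)) stop_input("`Q` must be >= 1")
  frac <- Q / p
  list(fractional = frac, count = ceiling(round(frac, 9)))
}

#' Incremental cost per quality mouse of the biotelemetry model
#'
#' Difference between the biotelemetry model's total cost (equipment plus
#' `Q` animals at `c` each) and the fixed-time-point model's total cost
#' (`Q / p` animals at `c` each), per quality mouse. Positive values mean
#' biotelemetry costs more per quality mouse at these inputs.
#'
#' @param Q Quality mice.
#' @param c Cost per mouse (USD); defaults to the value in `params`.
#' @param p Capture proportion; defaults to the value in `params`.
#' @param params A [cost_parameters()] object.
#' @return USD per quality mouse.
#' @examples
#' incremental_cost_per_quality_mouse(120, 25, 0.28)
#' @export
incremental_cost_per_quality_mouse <- function(Q, c = NULL, p = NULL,
                                               params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  c <- c %||% params$cost_per_mouse
  p <- p %||% params$capture_proportion
  ((setup_cost(Q, params) + Q * c) - (Q / p) * c) / Q
}

#' Cost-per-mouse at which the two models cost the same
#'
#' The equipment premium of biotelemetry is offset by the extra `Q/p - Q`
#' animals the fixed-time-point design must purchase; the break-even
#' per-animal cost is `setup_cost(Q) / (Q/p - Q)`. It decreases in `Q`
#' within a battery tier: the more quality mice a programme plans, the
#' cheaper the animal may be and biotelemetry still pays for itself.
#'
#' @param Q Quality mice; vectorised.
#' @param p Capture proportion, strictly below 1 (at `p = 1` the
#'   fixed-time design wastes no animals and no break-even exists).
#' @param params A [cost_parameters()] object.
#' @return Break-even cost-per-mouse in USD.
#' @examples
#' equivalency_cost(c(120, 240, 360), 0.28)
#' @export
equivalency_cost <- function(Q, p = NULL, params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  p <- p %||% params$capture_proportion
  if (!is_scalar_num(p) || p <= 0 || p >= 1) {
    stop_input("`p` must lie in (0, 1); at p = 1 no equivalency exists")
  }
  setup_cost(Q, params) / (Q / p - Q)
}

#' Quality-mouse count at cost equivalency for a given cost-per-mouse
#'
#' Solves `equivalency_cost(Q) = c` under the stepped battery schedule. For
#' each battery tier `k` (number of replacement sets), the within-tier
#' solution is `Q_k = (system + devices + k * battery) / (c * (1/p - 1))`;
#' the accepted tier is the one whose solution actually lies inside it,
#' `Q_k` in `(k * cycle, (k + 1) * cycle]`. The accepted `Q` is rounded to
#' the nearest mouse, and the fixed-time-point requirement and animals
#' spared follow.
#'
#' @param c Cost per mouse (USD), positive.
#' @param p Capture proportion in (0, 1).
#' @param params A [cost_parameters()] object.
#' @param max_tiers Search bound on battery tiers.
#' @return An `equivalency_result` list: `quality_mice`,
#'   `cost_per_mouse`, `standard_mice`, `mice_spared`,
#'   `battery_replacements`.
#' @examples
#' equivalency_quality_mice(50, 0.28)
#' equivalency_quality_mice(250, 0.28)
#' @export
equivalency_quality_mice <- function(c, p = NULL, params = cost_parameters(),
                                     max_tiers = 1000L) {
  stopifnot(inherits(params, "cost_parameters"))
  p <- p %||% params$capture_proportion
  if (!is_scalar_num(c) || c <= 0) stop_input("`c` must be positive")
  if (!is_scalar_num(p) || p <= 0 || p >= 1) stop_input("`p` must lie in (0, 1)")

  waste <- c * (1 / p - 1)  # extra standard-model spend per quality mouse
  cycle <- params$mice_per_cycle
  for (k in 0:max_tiers) {
    q_k <- (params$system_cost + params$device_set_cost +
              k * params$battery_set_cost) / waste
    if (q_k > k * cycle && q_k <= (k + 1) * cycle) {
      q <- round_half_up(q_k)
      std <- round_half_up(q / p)
      return(structure(
        list(quality_mice = q, cost_per_mouse = c,
             standard_mice = std, mice_spared = std - q,
             battery_replacements = k,
             quality_mice_exact = q_k),
        class = "equivalency_result"
      ))
    }
  }
  stop_input("no self-consistent battery tier within ", max_tiers,
             " tiers; equivalency unreachable at c = ", c)
}

#' @export
print.equivalency_result <- function(x, ...) {
  cat(sprintf(
    "Cost equivalency at $%.2f per mouse: %d biotelemetry mice (%d battery sets)\n",
    x$cost_per_mouse, x$quality_mice, x$battery_replacements
  ))
  cat(sprintf("  vs %d fixed-time-point mice -> %d mice spared\n",
              x$standard_mice, x$mice_spared))
  invisible(x)
}

#' Incremental cost difference as a function of cost-per-mouse
#'
#' Total biotelemetry cost minus total fixed-time-point cost for a fixed
#' `Q`, across a grid of per-animal costs. Exactly linear in `c` with slope
#' `Q - Q/p` (negative): the difference starts at the equipment premium at
#' `c = 0` and crosses zero at [equivalency_cost()].
#'
#' @param c_values Numeric vector of per-mouse costs.
#' @param Q Quality mice.
#' @param p Capture proportion.
#' @param params A [cost_parameters()] object.
#' @return A data.frame with `cost_per_mouse` and `difference` (USD).
#' @export
incremental_cost_difference_curve <- function(c_values, Q, p = NULL,
                                              params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  p <- p %||% params$capture_proportion
  data.frame(
    cost_per_mouse = c_values,
    difference = setup_cost(Q, params) + (Q - Q / p) * c_values
  )
}

#' Two-way sensitivity analysis: cost-per-mouse vs quality mice
#'
#' Evaluates the incremental cost difference over the full grid
#' `c_grid x Q_grid` and marks which model is cheaper in each cell; the
#' equivalency boundary is the curve `c = equivalency_cost(Q)`. Cells with
#' per-mouse cost above the boundary favour biotelemetry.
#'
#' @param c_grid,Q_grid Non-empty numeric vectors.
#' @param p Capture proportion in (0, 1).
#' @param params A [cost_parameters()] object.
#' @return A `sensitivity_grid` list: `grid` (data.frame `Q`,
#'   `cost_per_mouse`, `difference`, `favors` in
#'   `c("biotelemetry", "standard", "equivalent")`) and `boundary`
#'   (data.frame `Q`, `equivalency_cost`).
#' @export
two_way_sensitivity <- function(c_grid, Q_grid, p = NULL,
                                params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  p <- p %||% params$capture_proportion
  if (!length(c_grid) || !length(Q_grid)) stop_input("grids must be non-empty")
  g <- expand.grid(Q = Q_grid, cost_per_mouse = c_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$difference <- setup_cost(g$Q, params) + (g$Q - g$Q / p) * g$cost_per_mouse
  g$favors <- ifelse(g$difference < 0, "biotelemetry",
                     ifelse(g$difference > 0, "standard", "equivalent"))
  structure(
    list(
      grid = g,
      boundary = data.frame(Q = Q_grid,
                            equivalency_cost = equivalency_cost(Q_grid, p, params))
    ),
    class = "sensitivity_grid"
  )
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  n_bio <- sum(x$grid$favors == "biotelemetry")
  cat(sprintf("Two-way sensitivity grid: %d cells, %d favor biotelemetry\n",
              nrow(x$grid), n_bio))
  invisible(x)
}

#' Equivalency table across per-mouse costs
#'
#' Solves [equivalency_quality_mice()] for each cost-per-mouse and stacks
#' the results -- the animal-sparing summary across the plausible range of
#' per-animal costs.
#'
#' @param c_values Per-mouse costs (USD).
#' @param p Capture proportion in (0, 1).
#' @param params A [cost_parameters()] object.
#' @return A data.frame with one row per cost: `cost_per_mouse`,
#'   `quality_mice`, `standard_mice`, `mice_spared`,
#'   `battery_replacements`.
#' @examples
#' equivalency_table(c(50, 250), 0.28)
#' @export
equivalency_table <- function(c_values, p = NULL, params = cost_parameters()) {
  rows <- lapply(c_values, function(cv) {
    r <- equivalency_quality_mice(cv, p, params)
    data.frame(
      cost_per_mouse = cv,
      quality_mice = r$quality_mice,
      standard_mice = r$standard_mice,
      mice_spared = r$mice_spared,
      battery_replacements = r$battery_replacements
    )
  })
  do.call(rbind, rows)
}
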