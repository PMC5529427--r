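# Hand-built traces and brute-force statistical oracles used across tests.

# Trace with constant channels.
constant_trace <- function(hr = 700, temp = 37, horizon = 1440, by = 1,
                           id = "const") {
  t <- seq(0, horizon, by = by)
  df <- data.frame(time_min = t, heart_rate_bpm = rep(hr, length(t)),
                   core_temp_c = rep(temp, length(t)))
  attr(df, "mouse_id") <- id
  class(df) <- c("telemetry_trace", "data.frame")
  df
}

# Step trace: channels drop from their initial values to (hr_to, temp_to)
# at `at` minutes and stay there.
step_trace <- function(hr_from = 700, hr_to = 600, temp_from = 37,
                       temp_to = 35, at = 300, horizon = 1440, id = "step") {
  t <- seq(0, horizon, by = 1)
  df <- data.frame(
    time_min = t,
    heart_rate_bpm = ifelse(t < at, hr_from, hr_to),
    core_temp_c = ifelse(t < at, temp_from, temp_to)
  )
  attr(df, "mouse_id") <- id
  class(df) <- c("telemetry_trace", "data.frame")
  df
}

# Piecewise-linear decline trace: plateau at (hr_peak, temp_peak) until
# `onset`, then linear decline at the given slopes.
decline_trace <- function(onset, hr_peak = 700, temp_peak = 37.5,
                          hr_slope = 2, temp_slope = 0.02,
                          horizon = 1440, by = 1, id = "dec") {
  t <- seq(0, horizon, by = by)
  past <- pmax(t - onset, 0)
  df <- data.frame(
    time_min = t,
    heart_rate_bpm = pmax(hr_peak - hr_slope * past, 250),
    core_temp_c = pmax(temp_peak - temp_slope * past, 24)
  )
  attr(df, "mouse_id") <- id
  class(df) <- c("telemetry_trace", "data.frame")
  df
}

# Brute-force exact McNemar: enumerate the binomial(n, 1/2) distribution of
# the number of discordant pairs falling on one side and sum the probability
# of outcomes at least as extreme (two-sided by symmetry).
mcnemar_brute <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  m <- min(b, c)
  k <- 0:n
  probs <- choose(n, k) / 2^n
  sum(probs[k <= m | k >= n - m])
}

# Exact conditional p for a 2 x k table by complete enumeration of tables
# with the observed margins, weighting by the multivariate hypergeometric
# probability. Small tables only.
fisher_brute_2xk <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  k <- length(cs)
  prob_of <- function(top) {
    exp(sum(lchoose(cs, top)) - lchoose(sum(cs), rs[1]))
  }
  tops <- expand.grid(lapply(cs, function(m) 0:m))
  tops <- tops[rowSums(tops) == rs[1], , drop = FALSE]
  p_obs <- prob_of(as.numeric(tab[1, ]))
  total <- 0
  for (i in seq_len(nrow(tops))) {
    p <- prob_of(as.numeric(tops[i, ]))
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}
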