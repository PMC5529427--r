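# Internal helpers shared across modules.

# Round half away from zero (commercial rounding). Base round() uses
# banker's rounding, which would report 2.5% as 2%; reported percentages
# and p-values follow the half-up convention instead.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic per-mouse substream seed; keeps results independent of the
# order in which individual mice are simulated. Kept below 2^31.
mouse_seed <- function(seed, index) {
  (as.double(seed) %% 1e6) * 2038 + index * 7 + 1
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
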