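# Independent oracles used to freeze expected values. These never call the
# implementation paths they check.

# Exhaustive grid search over (a, p50) minimizing the sigmoid SSE.
grid_search_sigmoid <- function(pressure, percent,
                                a_range = c(0.2, 3), p50_range = c(-8, -1),
                                n_grid = 121L) {
  a_grid <- seq(a_range[1L], a_range[2L], length.out = n_grid)
  p_grid <- seq(p50_range[1L], p50_range[2L], length.out = n_grid)
  best <- list(sse = Inf)
  for (a in a_grid) {
    for (p in p_grid) {
      sse <- sum((percent - 100 / (1 + exp(a * (pressure - p))))^2)
      if (sse < best$sse) best <- list(a = a, p50 = p, sse = sse)
    }
  }
  best
}

# Brute-force hydraulic diameter, written as an explicit loop.
brute_force_dh <- function(d) {
  num <- 0; den <- 0
  for (x in d) {
    num <- num + x^5
    den <- den + x^4
  }
  num / den
}

# Closed-form pressure at a response level (hand inversion of the model).
closed_form_pressure <- function(a, p50, level) {
  p50 + log(100 / level - 1) / a
}
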