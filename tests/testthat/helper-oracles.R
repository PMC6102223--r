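# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Closed-form probability that a given cell of a two-cell droplet is
# IFN-positive by time T under the early-responder mechanism: both cells
# start at hazard a; when the first activates (rate 2a), the other's
# hazard becomes pi*a. Derived by conditioning on the first event time:
#   P(inactive) = e^(-2aT) + (1/2) Int_0^T 2a e^(-2at) e^(-pi a (T-t)) dt
pair_early_responder_prob <- function(a, pi_mult, T) {
  if (abs(pi_mult - 2) < 1e-12) {
    p_in <- exp(-2 * a * T) * (1 + a * T)
  } else {
    p_in <- exp(-2 * a * T) +
      exp(-pi_mult * a * T) * (1 - exp(-(2 - pi_mult) * a * T)) / (2 - pi_mult)
  }
  1 - p_in
}

# Brute-force time-discretised simulation of n two-cell droplets under the
# early-responder mechanism; returns the fraction of IFN-positive cells.
sim_pairs_discretized <- function(a, pi_mult, T, dt, n_pairs) {
  p_base <- 1 - exp(-a * dt)
  p_boost <- 1 - exp(-pi_mult * a * dt)
  act1 <- logical(n_pairs)
  act2 <- logical(n_pairs)
  steps <- round(T / dt)
  for (s in seq_len(steps)) {
    new1 <- !act1 & stats::runif(n_pairs) <
      ifelse(act2, p_boost, p_base)
    new2 <- !act2 & stats::runif(n_pairs) <
      ifelse(act1, p_boost, p_base)
    act1 <- act1 | new1
    act2 <- act2 | new2
  }
  (sum(act1) + sum(act2)) / (2 * n_pairs)
}

# One-parameter grid search for the early-responder fraction.
grid_search_e <- function(p, y, step = 1e-4, upper = 100) {
  grid <- seq(0, upper, by = step)
  w <- 1 + p / 100
  sse <- vapply(grid, function(e) sum((y - e * w)^2), numeric(1))
  grid[which.min(sse)]
}

# Straight-line least squares via explicitly written normal equations.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# 3-standard-error bound for a binomial fraction
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
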