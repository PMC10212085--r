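# Fixtures and independent closed-form oracles used across tests.

# exact exponential trace with no divisions
make_exp_trace <- function(g = 0.01, n = 10L, dt = 10, L0 = 2, F0 = 100,
                           id = "exp") {
  times <- seq(0, by = dt, length.out = n)
  lineage_trace(id, times, L0 * exp(g * times), rep(F0, n))
}

# noiseless deterministic simulation config (no expression noise sources)
noiseless_config <- function(...) {
  sim_config("regulated",
             expression = list(noise_cv = 0, beta_cv = 0),
             division = list(cv_div = 0.08, ratio_sd = 0.04),
             ...)
}

# closed-form oracles for a rectangular on-pulse with constant dilution
# rate r = g + delta, baseline F0, production beta:
#   frame-averaged maximal slope starting from the floored baseline F0
pulse_max_rate_oracle <- function(beta, r, F0, dt) {
  (beta / r - F0) * (1 - exp(-r * dt)) / dt
}
#   amplitude after an on-duration tau starting from F0
pulse_amplitude_oracle <- function(beta, r, F0, tau) {
  F0 * exp(-r * tau) + (beta / r) * (1 - exp(-r * tau))
}
#   time for A*exp(-r t) to fall to F0 + (A - F0)/2 (baseline-relative)
pulse_half_time_oracle <- function(A, r, F0) {
  log(2 * A / (A + F0)) / r
}
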