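# The mother-machine generator: reproducibility, degenerate limits,
# construction invariants, and agreement with telegraph-model theory.

test_that("identical (config, seed) pairs reproduce bit-identical traces", {
  cfg <- sim_config("regulated", n_traps = 15, t_total = 800, seed = 42)
  expect_identical(simulate_mother_machine(cfg), simulate_mother_machine(cfg))
  # a different seed must differ
  cfg2 <- sim_config("regulated", n_traps = 15, t_total = 800, seed = 43)
  expect_false(identical(simulate_mother_machine(cfg),
                         simulate_mother_machine(cfg2)))
})

test_that("disabling measurement noise does not perturb the other streams", {
  base <- list(n_traps = 10, t_total = 800, seed = 5)
  noisy <- simulate_mother_machine(do.call(sim_config, base))
  clean <- simulate_mother_machine(do.call(sim_config, c(
    base, list(expression = list(noise_cv = 0)))))
  for (k in seq_along(noisy)) {
    expect_identical(clean[[k]]$lengths, noisy[[k]]$lengths)
    expect_identical(clean[[k]]$division_flags, noisy[[k]]$division_flags)
  }
})

test_that("activation-impossible and production-free configs stay at baseline", {
  cfg <- sim_config("regulated", n_traps = 20, t_total = 1000, seed = 2,
                    expression = list(k_on = 0))
  traces <- simulate_mother_machine(cfg)
  cap <- cfg$expression$F0 * (1 + 5 * cfg$expression$noise_cv)
  expect_true(all(vapply(traces, function(tr) max(tr$fluorescence), 0) < cap))
  fpt <- fraction_positive_over_time(traces, 1000)
  expect_true(all(fpt$fraction == 0))

  cfg0 <- sim_config("regulated", n_traps = 5, t_total = 500, seed = 2,
                     expression = list(noise_cv = 0, beta_median = 0))
  for (tr in simulate_mother_machine(cfg0))
    expect_equal(tr$fluorescence, rep(cfg0$expression$F0, length(tr$times)))
})

test_that("trace construction invariants hold in noiseless mode", {
  cfg <- noiseless_config(n_traps = 30, seed = 9)
  traces <- simulate_mother_machine(cfg)
  expect_length(traces, 30)
  for (tr in traces) {
    expect_true(all(tr$lengths > 0))
    expect_true(all(tr$fluorescence >= 0))
    expect_false(tr$division_flags[1L])
    n <- length(tr$times)
    ratio <- tr$lengths[-1L] / tr$lengths[-n]
    div <- tr$division_flags[-1L]
    # division frames drop sharply; growth frames never shrink
    expect_true(all(ratio[div] < 0.75))
    expect_true(all(ratio[div] >= 0.5 - 3 * cfg$division$ratio_sd - 1e-12))
    expect_true(all(ratio[div] <= 0.5 + 3 * cfg$division$ratio_sd + 1e-12))
    expect_true(all(ratio[!div] >= 1))
  }
})

test_that("fluorescence is conserved with no production, loss or noise", {
  cfg <- sim_config("regulated", n_traps = 3, t_total = 500, seed = 1,
                    growth = list(g_fresh = 0, g_cond = 0, tau_relax = 1),
                    expression = list(noise_cv = 0, beta_median = 0,
                                      delta = 0, k_on = 0.05, lag = 0))
  for (tr in simulate_mother_machine(cfg))
    expect_equal(tr$fluorescence, rep(cfg$expression$F0, length(tr$times)))
})

test_that("permanently-on fluorescence converges to beta/(g + delta)", {
  g <- 0.004; delta <- 0.001; beta <- 40
  cfg <- sim_config("regulated", n_traps = 3, t_switch = 0,
                    t_total = ceiling(10 / (g + delta) / 10) * 10, seed = 3,
                    growth = list(g_fresh = g, g_cond = g, tau_relax = 1),
                    expression = list(noise_cv = 0, beta_cv = 0,
                                      beta_median = beta, delta = delta,
                                      k_on = 1e6, k_off = 0, lag = 0))
  for (tr in simulate_mother_machine(cfg)) {
    terminal <- tr$fluorescence[length(tr$fluorescence)]
    expect_lt(abs(terminal - beta / (g + delta)) / (beta / (g + delta)), 0.02)
  }
})

test_that("stationary on-fraction matches k_on/(k_on + k_off)", {
  k_on <- 0.003; k_off <- 0.007
  p_stat <- k_on / (k_on + k_off)
  cfg <- sim_config("regulated", n_traps = 300, t_total = 3000, t_switch = 0,
                    seed = 7,
                    growth = list(g_fresh = 0.004, g_cond = 0.004,
                                  tau_relax = 1),
                    expression = list(k_on = k_on, k_off = k_off, lag = 0,
                                      delta = 0.3, beta_median = 3000))
  traces <- simulate_mother_machine(cfg)
  fpt <- fraction_positive_over_time(traces, 1000)
  terminal <- fpt$fraction[nrow(fpt)]
  se <- sqrt(p_stat * (1 - p_stat) / 300)
  expect_lt(abs(terminal - p_stat), 3 * se)
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config("regulated", frame_interval = -1), "frame_interval")
  expect_error(sim_config("regulated", t_switch = 2000, t_total = 1800),
               "t_switch")
  expect_error(sim_config("regulated", expression = list(k_on = -0.1)),
               "k_on")
  expect_error(sim_config("regulated", growth = list(g_fresh = NaN)),
               "g_fresh")
  expect_error(as_sim_config(list(bogus = 1)), "bogus")
})

test_that("flow-population sampler respects the mixture and its errors", {
  expect_error(sample_flow_population(0.5, mu_neg = 4, mu_pos = 2),
               "modes not ordered")
  expect_error(sample_flow_population(1.5), "f_positive")

  neg <- sample_flow_population(0, n_cells = 20000, n_replicates = 3,
                                seed = 1)
  expect_lte(gate_fraction_positive(neg, 1000)$mean_fraction, 0.001)

  pos <- sample_flow_population(1, n_cells = 5000, n_replicates = 1, seed = 1)
  expect_gt(mean(pos[[1]]$fluorescence >= 1000), 0.999)

  # binomial oracle at f = 0.46: 3 x 50,000 cells
  f <- 0.46
  pops <- sample_flow_population(f, n_cells = 50000, n_replicates = 3,
                                 seed = 11)
  est <- gate_fraction_positive(pops, 1000)$mean_fraction
  se <- sqrt(f * (1 - f) / (3 * 50000))
  expect_lt(abs(est - f), 3 * se)

  # replicates are independent but reproducible
  pops2 <- sample_flow_population(f, n_cells = 50000, n_replicates = 3,
                                  seed = 11)
  expect_identical(pops, pops2)
  expect_false(identical(pops[[1]]$fluorescence, pops[[2]]$fluorescence))
})

test_that("deterministic pulse traces follow the closed-form pulse", {
  beta <- 40; g <- 0.004; F0 <- 100; tau <- 300
  tr <- simulate_pulse_traces(1, beta_median = beta, g = g, F0 = F0,
                              t_on = 100, on_duration = tau,
                              t_total = 1200, seed = 1)[[1]]
  expect_equal(max(tr$fluorescence),
               pulse_amplitude_oracle(beta, g, F0, tau), tolerance = 1e-8)
  expect_equal(tr$fluorescence[tr$times <= 100],
               rep(F0, sum(tr$times <= 100)))
})
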