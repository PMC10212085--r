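# Population bimodality: gated fractions, mixture decomposition, auto-gate.

test_that("gated fractions summarize replicates as mean +/- SEM", {
  # three replicates engineered to gate at exactly 0.10, 0.12, 0.14
  mk <- function(f, id) {
    n <- 1000
    population_sample(id, c(rep(10, n * (1 - f)), rep(2000, n * f)))
  }
  s <- gate_fraction_positive(list(mk(0.10, "r1"), mk(0.12, "r2"),
                                   mk(0.14, "r3")), gate = 1000)
  expect_equal(s$per_replicate_fractions, c(0.10, 0.12, 0.14))
  expect_equal(s$mean_fraction, 0.12)
  expect_equal(s$sem, sd(c(0.10, 0.12, 0.14)) / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n_replicates, 3)
  # single replicate: SEM 0
  expect_equal(gate_fraction_positive(mk(0.1, "r1"), 1000)$sem, 0)
  expect_error(gate_fraction_positive(list(), 1000), "insufficient data")
  expect_error(gate_fraction_positive(mk(0.1, "r1"), gate = -5), "gate")
})

test_that("gated fraction is monotone non-increasing in the gate", {
  pops <- sample_flow_population(0.3, n_cells = 5000, n_replicates = 2,
                                 seed = 5)
  gates <- c(50, 200, 1000, 5000, 20000)
  fr <- vapply(gates, function(g)
    gate_fraction_positive(pops, g)$mean_fraction, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  pop <- sample_flow_population(0.4, n_cells = 5000, n_replicates = 1,
                                seed = 8)[[1]]
  fit <- fit_two_component_mixture(pop)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  expect_lte(fit$means[1], fit$means[2])
})

test_that("a single Gaussian is never called bimodal", {
  for (s in 1:20) {
    streams_seed <- 100 + s
    set.seed(streams_seed)
    pop <- population_sample("r", 10^rnorm(2000, 2.5, 0.3))
    fit <- fit_two_component_mixture(pop)
    expect_false(fit$bimodal)
  }
})

test_that("mixture parameters are recovered, down to a 6% minority", {
  pop <- sample_flow_population(0.5, n_cells = 50000, n_replicates = 1,
                                seed = 2)[[1]]
  fit <- fit_two_component_mixture(pop)
  expect_true(fit$bimodal)
  expect_lt(max(abs(fit$means - c(2, 4))), 0.05)
  expect_lt(max(abs(fit$weights - c(0.5, 0.5))), 0.02)
  expect_lt(max(abs(fit$sds - 0.25)), 0.05)

  pop6 <- sample_flow_population(0.06, n_cells = 50000, n_replicates = 1,
                                 seed = 3)[[1]]
  fit6 <- fit_two_component_mixture(pop6)
  expect_true(fit6$bimodal)
  expect_lt(abs(fit6$weights[2] - 0.06), 0.02)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  pop <- sample_flow_population(0.3, n_cells = 20000, n_replicates = 1,
                                seed = 9)[[1]]
  fit <- fit_two_component_mixture(pop)
  mc <- mclust::Mclust(log10(pop$fluorescence), G = 2, modelNames = "V",
                       verbose = FALSE)
  expect_lt(max(abs(sort(as.numeric(mc$parameters$mean)) - fit$means)), 0.02)
  expect_lt(max(abs(sort(mc$parameters$pro) - sort(fit$weights))), 0.01)
})

test_that("auto-gate sits at the posterior-equality point", {
  # symmetric 50/50 mixture: gate at the midpoint, 1e3 AU
  pop <- sample_flow_population(0.5, n_cells = 50000, n_replicates = 1,
                                seed = 2)[[1]]
  expect_lt(abs(log10(auto_gate(pop)) - 3), 0.05)
  # unimodal sample: fixed fallback
  set.seed(1)
  uni <- population_sample("r", 10^rnorm(2000, 2.5, 0.3))
  expect_equal(auto_gate(uni, fallback_gate = 1234), 1234)
  # skewed weights: gate shifts toward the minority mode, and matches a
  # brute-force grid search for equal posterior density
  pop9 <- sample_flow_population(0.1, n_cells = 50000, n_replicates = 1,
                                 seed = 4)[[1]]
  fit <- fit_two_component_mixture(pop9)
  g <- auto_gate(pop9, fit = fit)
  expect_gt(log10(g), 3)  # midpoint is 3; minority is the high mode
  grid <- seq(fit$means[1], fit$means[2], by = 1e-5)
  diffs <- abs(fit$weights[1] * dnorm(grid, fit$means[1], fit$sds[1]) -
               fit$weights[2] * dnorm(grid, fit$means[2], fit$sds[2]))
  # restrict to the between-modes region where both densities decay
  gstar <- grid[which.min(diffs)]
  expect_lt(abs(log10(g) - gstar), 1e-3)
})

test_that("non-positive readings are dropped with a message", {
  x <- c(10^rnorm(500, 2, 0.2), -1, 0)
  expect_message(fit_two_component_mixture(x), "dropping 2")
  expect_error(fit_two_component_mixture(rep(100, 50)), "insufficient data")
})

test_that("summarize_population combines gate and mixture results", {
  pops <- sample_flow_population(0.46, n_cells = 20000, n_replicates = 3,
                                 seed = 6)
  s_fixed <- summarize_population(pops, gate = 1000)
  s_auto <- summarize_population(pops, use_auto_gate = TRUE)
  expect_true(s_fixed$bimodal)
  expect_lt(abs(s_fixed$mean_fraction - 0.46), 0.02)
  expect_lt(abs(s_auto$mean_fraction - 0.46), 0.02)
  expect_equal(s_fixed$n_replicates, 3)
})
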