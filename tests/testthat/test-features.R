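# Induction features: crossing time, maximal rate, first peak, decay
# half-time, censoring bookkeeping.

make_fluor_trace <- function(f, dt = 10, id = "f") {
  lineage_trace(id, seq(0, by = dt, length.out = length(f)),
                rep(2, length(f)), f)
}

test_that("threshold crossing is the first frame at or above threshold", {
  tr <- make_fluor_trace(c(500, 800, 1200))
  expect_equal(threshold_crossing_time(tr), 20)
  expect_true(is.na(threshold_crossing_time(make_fluor_trace(c(10, 20, 30)))))
  # already positive at the start (loaded from stationary-phase culture)
  expect_equal(threshold_crossing_time(make_fluor_trace(c(1500, 900, 800))), 0)
  expect_error(threshold_crossing_time(tr, threshold = -1), "threshold")
})

test_that("max induction rate is the largest forward difference", {
  tr <- make_fluor_trace(c(0, 100, 300, 350))
  expect_equal(max_induction_rate(tr, threshold = 50), 20)
  # censored without a crossing, and without any rise
  expect_true(is.na(max_induction_rate(make_fluor_trace(c(1, 2, 3)))))
  expect_true(is.na(max_induction_rate(make_fluor_trace(c(2000, 1500, 1200)))))
  # smoothing averages neighbouring frames
  tr2 <- make_fluor_trace(c(1000, 1000, 4000, 1000, 1000))
  expect_equal(max_induction_rate(tr2, smooth_window = 3),
               max(diff(c(1000, 2000, 2000, 2000, 1000))) / 10)
})

test_that("first peak requires prominence and reports absolute amplitude", {
  rise_fall <- make_fluor_trace(c(100, 100, 2000, 5000, 3000, 1500))
  pk <- first_peak_amplitude(rise_fall)
  expect_equal(pk$peak_amplitude, 5000)
  expect_equal(pk$peak_time, 30)
  # monotone rise to the end: censored
  pk2 <- first_peak_amplitude(make_fluor_trace(c(100, 1200, 2000, 3000)))
  expect_identical(pk2$censored, "no_peak")
  # a small noise blip below the prominence floor is skipped
  blip <- make_fluor_trace(c(100, 1200, 1210, 1190, 3000, 5000, 2000))
  pk3 <- first_peak_amplitude(blip, prominence_fraction = 0.1)
  expect_equal(pk3$peak_amplitude, 5000)
  # never crossed
  pk4 <- first_peak_amplitude(make_fluor_trace(c(10, 20, 10)))
  expect_identical(pk4$censored, "never_crossed")
})

test_that("decay half-time matches the exponential half-life", {
  k <- log(2) / 60  # half-life 60 min
  times <- seq(0, 200, 10)
  f <- 5000 * exp(-k * times)
  tr <- make_fluor_trace(f)
  ht <- decay_half_time(tr, peak_time = 0, peak_amplitude = 5000,
                        baseline = 0)
  expect_lt(abs(ht - 60), 10)  # within one interpolation step
  # truncated right after the peak: censored
  tr2 <- make_fluor_trace(c(100, 5000, 4800))
  expect_true(is.na(decay_half_time(tr2, 10, 5000, 100)))
  expect_error(decay_half_time(tr, 0, 5000, baseline = 6000), "baseline")
})

test_that("noiseless pulse features recover their closed-form oracles", {
  beta <- 40; g <- 0.004; F0 <- 100; tau <- 300
  traces <- simulate_pulse_traces(200, beta_median = beta, g = g, F0 = F0,
                                  t_on = 100, on_duration = tau,
                                  t_total = 1500, seed = 1)
  feats <- extract_trace_features(traces)
  expect_true(all(feats$censor_reasons == ""))
  expect_lt(abs(median(feats$max_rate) -
                pulse_max_rate_oracle(beta, g, F0, 10)) /
            pulse_max_rate_oracle(beta, g, F0, 10), 0.10)
  A <- pulse_amplitude_oracle(beta, g, F0, tau)
  expect_lt(abs(median(feats$peak_amplitude) - A) / A, 0.10)
  ht <- pulse_half_time_oracle(A, g, F0)
  expect_lt(abs(median(feats$decay_half_time) - ht) / ht, 0.10)
  # spec-level sanity: crossing precedes the peak, amplitude above gate
  expect_true(all(feats$crossing_time <= feats$peak_time))
  expect_true(all(feats$peak_amplitude >= 1000))
  expect_true(all(feats$decay_half_time > 0))
})

test_that("every trace contributes once: observed + censored = total", {
  cfg <- sim_config("regulated", n_traps = 80, seed = 6)
  feats <- extract_trace_features(simulate_mother_machine(cfg))
  expect_equal(nrow(feats), 80)
  for (fn in c("crossing_time", "max_rate", "peak_amplitude",
               "decay_half_time")) {
    n_obs <- sum(is.finite(feats[[fn]]))
    expect_lte(n_obs, 80)
  }
  # censored features always carry a reason
  miss_peak <- is.na(feats$peak_amplitude)
  expect_true(all(feats$censor_reasons[miss_peak] != ""))
  # decay absent whenever the peak is absent
  expect_true(all(is.na(feats$decay_half_time[is.na(feats$peak_amplitude)])))
  # never-crossed traces have no features at all
  nc <- grepl("never_crossed", feats$censor_reasons)
  expect_true(all(is.na(feats$max_rate[nc])))
  expect_true(all(is.na(feats$crossing_time[nc])))
})

test_that("fraction positive over time counts threshold exceedances", {
  lo <- make_fluor_trace(c(10, 10, 10), id = "lo")
  hi <- make_fluor_trace(c(10, 2000, 2000), id = "hi")
  fpt <- fraction_positive_over_time(list(lo, hi), 1000)
  expect_equal(fpt$fraction, c(0, 0.5, 0.5))
  expect_equal(fpt$n_cells, c(2, 2, 2))
  fpt0 <- fraction_positive_over_time(list(lo), 1000)
  expect_true(all(fpt0$fraction == 0))
})
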