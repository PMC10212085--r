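# Synthetic mother-machine generator.
#
# Growth: specific elongation rate g(t) = g_cond + (g_fresh - g_cond) *
# exp(-max(0, t - t_switch)/tau_relax); length grows exponentially and is
# reset at division to ratio * length (ratio ~ N(0.5, ratio_sd), truncated
# at 3 s.d.).  Expression: two-state telegraph process, off -> on allowed
# only after t_switch + lag, with a fresh production rate beta drawn per
# activation pulse.  Fluorescence: dF/dt = beta*[on] - (g + delta)*F,
# integrated exactly over each frame with the frame-averaged g, floored at
# the baseline F0.  Multiplicative lognormal measurement noise is applied
# last, to fluorescence only.

# integral of g(t) dt over [a, b] (absolute times)
growth_log_integral <- function(a, b, growth, t_switch) {
  g_f <- growth$g_fresh; g_c <- growth$g_cond; tau <- growth$tau_relax
  pre <- max(0, min(b, t_switch) - a)
  post_a <- max(a, t_switch); post_b <- max(b, t_switch)
  post <- g_c * (post_b - post_a) +
    (g_f - g_c) * tau * (exp(-(post_a - t_switch) / tau) -
                         exp(-(post_b - t_switch) / tau))
  g_f * pre + post
}

# exact one-frame update of dF/dt = beta - rate*F
fluor_step <- function(f, beta, rate, dt) {
  if (rate > 0) {
    a <- exp(-rate * dt)
    f * a + beta * (1 - a) / rate
  } else {
    f + beta * dt
  }
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a mother-machine experiment
#'
#' Generates one [lineage_trace()] per trap according to the stochastic
#' model described in [sim_config()].  All randomness derives from
#' `config$seed` through named substreams (division, expression,
#' measurement noise), so the same configuration and seed reproduce
#' bit-identical traces, and disabling one noise source does not perturb
#' the others.
#'
#' @param config a [sim_config()] object (or a list coercible via
#'   [as_sim_config()]).
#' @return A list of [lineage_trace()] objects, one per trap.
#' @export
#' @examples
#' traces <- simulate_mother_machine(sim_config("regulated", n_traps = 5,
#'                                              t_total = 600, seed = 1))
#' length(traces)
simulate_mother_machine <- function(config) {
  config <- as_sim_config(config)
  times <- frame_times(config)
  n <- length(times)
  dt <- config$frame_interval
  gr <- config$growth; dv <- config$division; ex <- config$expression
  streams <- rng_streams(config$seed, c("division", "expression", "noise"))

  # per-frame growth increments are shared by all traps (growth is
  # deterministic given the medium program)
  g_int <- vapply(seq_len(n - 1L), function(i)
    growth_log_integral(times[i], times[i + 1L], gr, config$t_switch), 0)
  g_bar <- g_int / dt

  lengths_mat <- matrix(NA_real_, n, config$n_traps)
  div_mat <- matrix(FALSE, n, config$n_traps)
  with_stream(streams, "division", {
    for (k in seq_len(config$n_traps)) {
      L <- rtrunc_norm(1L, dv$L_birth_mean, dv$cv_div * dv$L_birth_mean,
                       0.5 * dv$L_birth_mean, 1.5 * dv$L_birth_mean)
      thr <- max(rtrunc_norm(1L, dv$L_div_mean, dv$cv_div * dv$L_div_mean,
                             0, 2 * dv$L_div_mean), 1.05 * L)
      lens <- numeric(n); divs <- logical(n)
      lens[1L] <- L
      for (i in 2L:n) {
        Lg <- L * exp(g_int[i - 1L])
        if (Lg >= thr) {
          ratio <- rtrunc_norm(1L, 0.5, dv$ratio_sd,
                               0.5 - 3 * dv$ratio_sd, 0.5 + 3 * dv$ratio_sd)
          L <- ratio * L   # division mid-frame; post-division regrowth folded
          divs[i] <- TRUE  # into the next frame
          thr <- max(rtrunc_norm(1L, dv$L_div_mean, dv$cv_div * dv$L_div_mean,
                                 0, 2 * dv$L_div_mean), 1.05 * L)
        } else {
          L <- Lg
        }
        lens[i] <- L
      }
      lengths_mat[, k] <- lens
      div_mat[, k] <- divs
    }
  })

  # telegraph expression states; beta drawn once per activation pulse
  beta_mat <- matrix(0, n, config$n_traps)  # production during frame i-1 -> i
  on_mat <- matrix(FALSE, n, config$n_traps)
  p_on <- 1 - exp(-ex$k_on * dt)
  p_off <- 1 - exp(-ex$k_off * dt)
  sd_beta <- lnorm_sdlog(ex$beta_cv)
  with_stream(streams, "expression", {
    for (k in seq_len(config$n_traps)) {
      u <- runif(n - 1L)
      on <- FALSE; beta_cur <- 0
      for (i in 2L:n) {
        t0 <- times[i - 1L]
        if (!on) {
          if (t0 > config$t_switch + ex$lag && u[i - 1L] < p_on) {
            on <- TRUE
            beta_cur <- if (ex$beta_median > 0)
              rlnorm(1L, meanlog = log(ex$beta_median), sdlog = sd_beta) else 0
          }
        } else if (u[i - 1L] < p_off) {
          on <- FALSE; beta_cur <- 0
        }
        on_mat[i, k] <- on
        beta_mat[i, k] <- if (on) beta_cur else 0
      }
    }
  })

  # deterministic fluorescence integration given states
  fluor_mat <- matrix(NA_real_, n, config$n_traps)
  for (k in seq_len(config$n_traps)) {
    f <- ex$F0
    fluor_mat[1L, k] <- f
    for (i in 2L:n) {
      f <- fluor_step(f, beta_mat[i, k], g_bar[i - 1L] + ex$delta, dt)
      f <- max(f, ex$F0)
      fluor_mat[i, k] <- f
    }
  }

  if (ex$noise_cv > 0) {
    sdl <- lnorm_sdlog(ex$noise_cv)
    with_stream(streams, "noise", {
      for (k in seq_len(config$n_traps)) {
        fac <- exp(rnorm(n, -sdl^2 / 2, sdl))  # mean-1 multiplicative noise
        fluor_mat[, k] <- fluor_mat[, k] * fac
      }
    })
  }

  ids <- sprintf("trap_%03d", seq_len(config$n_traps))
  lapply(seq_len(config$n_traps), function(k)
    lineage_trace(ids[k], times, lengths_mat[, k], fluor_mat[, k],
                  div_mat[, k], config$strain_label))
}

#' Simulate deterministic single-pulse traces
#'
#' A controlled companion to [simulate_mother_machine()]: each trace
#' carries exactly one rectangular on-pulse of the expression state
#' (on from `t_on` for `on_duration` minutes), with a constant dilution
#' rate `g` and optional per-trace lognormal variation of the production
#' rate.  Cell length is held constant; these traces exercise the
#' fluorescence-feature estimators against closed-form expectations.
#'
#' @param n_traces number of traces.
#' @param beta_median median production rate in the on state, AU/min.
#' @param beta_cv lognormal cell-to-cell CV of the production rate
#'   (0 = identical pulses).
#' @param g constant dilution rate (growth), 1/min.
#' @param delta reporter degradation rate, 1/min.
#' @param F0 baseline fluorescence, AU.
#' @param t_on pulse start time, minutes.
#' @param on_duration pulse length, minutes.
#' @param t_total,frame_interval trace extent and frame spacing, minutes.
#' @param noise_cv multiplicative lognormal measurement noise CV.
#' @param seed integer RNG seed.
#' @param strain_label label stored on the traces.
#' @return A list of [lineage_trace()] objects.
#' @export
simulate_pulse_traces <- function(n_traces = 200, beta_median = 40,
                                  beta_cv = 0, g = 0.004, delta = 0,
                                  F0 = 100, t_on = 100, on_duration = 300,
                                  t_total = 1200, frame_interval = 10,
                                  noise_cv = 0, seed = 1L,
                                  strain_label = "pulse") {
  stopifnot(n_traces >= 1, beta_median >= 0, g >= 0, delta >= 0, F0 > 0,
            t_on >= 0, on_duration > 0, t_total > t_on,
            frame_interval > 0, noise_cv >= 0, beta_cv >= 0)
  times <- seq(0, t_total, by = frame_interval)
  n <- length(times)
  streams <- rng_streams(seed, c("expression", "noise"))
  betas <- with_stream(streams, "expression", {
    if (beta_cv > 0)
      rlnorm(n_traces, log(beta_median), lnorm_sdlog(beta_cv))
    else rep(beta_median, n_traces)
  })
  on_frame <- times >= t_on & times < t_on + on_duration
  rate <- g + delta
  lapply(seq_len(n_traces), function(k) {
    f <- numeric(n); f[1L] <- F0
    for (i in 2L:n) {
      beta_i <- if (on_frame[i - 1L]) betas[k] else 0
      f[i] <- max(fluor_step(f[i - 1L], beta_i, rate, frame_interval), F0)
    }
    if (noise_cv > 0) {
      sdl <- lnorm_sdlog(noise_cv)
      f <- f * with_stream(streams, "noise", exp(rnorm(n, -sdl^2 / 2, sdl)))
    }
    lineage_trace(sprintf("pulse_%03d", k), times,
                  lengths = rep(2, n), fluorescence = f,
                  strain_label = strain_label)
  })
}

#' Construct a flow-cytometry-like population sample
#'
#' @param replicate_id identifier of the biological replicate.
#' @param fluorescence per-cell fluorescence values, AU; all > 0.
#' @param strain_label free-text strain label.
#' @return A list of class `population_sample` with fields `replicate_id`,
#'   `strain_label`, `fluorescence`, `n_cells`.
#' @export
population_sample <- function(replicate_id, fluorescence,
                              strain_label = "unknown") {
  if (length(fluorescence) < 1L)
    stop("insufficient data: empty population sample", call. = FALSE)
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0))
    stop("invalid sample: fluorescence must be finite and > 0 (log-representable)",
         call. = FALSE)
  structure(
    list(replicate_id = as.character(replicate_id),
         strain_label = as.character(strain_label),
         fluorescence = as.numeric(fluorescence),
         n_cells = length(fluorescence)),
    class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat("<population_sample>", x$replicate_id, sprintf("(%s)", x$strain_label),
      x$n_cells, "cells, median", sprintf("%.3g AU\n", median(x$fluorescence)))
  invisible(x)
}

#' Sample endpoint fluorescence populations from a two-component mixture
#'
#' Emulates flow-cytometry snapshots of a bimodal culture: each cell is
#' curli-positive with probability `f_positive`, and its log10 fluorescence
#' is drawn from the corresponding normal component.  Replicates use
#' independent substreams of `seed`.
#'
#' @param f_positive fraction of positive cells, in \[0, 1\].
#' @param mu_neg,sigma_neg log10-AU mean and s.d. of the negative component.
#' @param mu_pos,sigma_pos log10-AU mean and s.d. of the positive component;
#'   `mu_pos` must exceed `mu_neg`.
#' @param n_cells cells per replicate (default 50,000, a typical
#'   cytometry acquisition).
#' @param n_replicates number of biological replicates.
#' @param seed integer RNG seed.
#' @param strain_label label stored on the samples.
#' @return A list of [population_sample()] objects.
#' @export
#' @examples
#' pops <- sample_flow_population(0.46, n_cells = 1000, n_replicates = 3,
#'                                seed = 1)
#' sapply(pops, function(p) mean(p$fluorescence >= 1000))
sample_flow_population <- function(f_positive, mu_neg = 2.0, sigma_neg = 0.25,
                                   mu_pos = 4.0, sigma_pos = 0.25,
                                   n_cells = 50000L, n_replicates = 3L,
                                   seed = 1L, strain_label = "sample") {
  if (!is.finite(f_positive) || f_positive < 0 || f_positive > 1)
    stop("configuration error: field 'f_positive' must be in [0, 1]",
         call. = FALSE)
  if (sigma_neg <= 0 || sigma_pos <= 0)
    stop("configuration error: sigmas must be > 0", call. = FALSE)
  if (mu_pos <= mu_neg)
    stop("configuration error: modes not ordered (mu_pos must exceed mu_neg)",
         call. = FALSE)
  stopifnot(n_cells >= 1, n_replicates >= 1)
  streams <- rng_streams(seed, sprintf("replicate_%d", seq_len(n_replicates)))
  lapply(seq_len(n_replicates), function(r) {
    with_stream(streams, sprintf("replicate_%d", r), {
      pos <- runif(n_cells) < f_positive
      lf <- numeric(n_cells)
      lf[pos] <- rnorm(sum(pos), mu_pos, sigma_pos)
      lf[!pos] <- rnorm(sum(!pos), mu_neg, sigma_neg)
      population_sample(sprintf("rep_%d", r), 10^lf, strain_label)
    })
  })
}
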