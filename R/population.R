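# Population-level bimodality: fixed-gate fractions with replicate
# summaries, and a two-component Gaussian mixture on log10 fluorescence as
# a reproducible surrogate for manual cytometry gating.

#' Gated fraction of curli-positive cells with replicate summary
#'
#' Per replicate, the fraction of cells with fluorescence at or above the
#' gate; across replicates, the mean and SEM (the conventional
#' "mean of biological replicates +/- SEM").
#'
#' @param samples a list of [population_sample()] objects (or a single
#'   sample).
#' @param gate gate position in AU (> 0); default 1000, matching the
#'   conventional microfluidics threshold.
#' @return Object of class `fraction_positive_summary`: list with `gate`,
#'   `per_replicate_fractions`, `mean_fraction`, `sem`, `n_replicates`.
#' @export
#' @examples
#' pops <- sample_flow_population(0.3, n_cells = 2000, n_replicates = 3,
#'                                seed = 1)
#' gate_fraction_positive(pops, gate = 1000)
gate_fraction_positive <- function(samples, gate = 1000) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  if (gate <= 0) stop("gate must be > 0", call. = FALSE)
  if (length(samples) < 1L)
    stop("insufficient data: need at least 1 replicate", call. = FALSE)
  fr <- vapply(samples, function(s) {
    stopifnot(inherits(s, "population_sample"))
    if (s$n_cells < 1L)
      stop("insufficient data: empty replicate", call. = FALSE)
    mean(s$fluorescence >= gate)
  }, 0)
  ms <- replicate_sem(fr)
  structure(list(gate = gate,
                 per_replicate_fractions = fr,
                 mean_fraction = ms$mean,
                 sem = ms$sem,
                 n_replicates = length(fr)),
            class = "fraction_positive_summary")
}

#' @export
print.fraction_positive_summary <- function(x, ...) {
  cat(sprintf("Fraction positive at gate %g AU: %.4f +/- %.4f SEM (n = %d replicates)\n",
              x$gate, x$mean_fraction, x$sem, x$n_replicates))
  invisible(x)
}

#' Two-component Gaussian mixture fit on log10 fluorescence
#'
#' Expectation-maximization fit of a two-component Gaussian mixture to the
#' log10-transformed fluorescence of one sample, initialized from the 25th
#' and 75th percentiles.  Convergence is declared when the log-likelihood
#' improves by less than `tol`.  The sample is called bimodal when both
#' weights are at least `min_weight` and the component means are separated
#' by at least `min_separation_sd` times the larger standard deviation.
#'
#' @param sample a [population_sample()] (or a numeric vector of AU
#'   values).
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @param min_weight minimum component weight for the bimodal call
#'   (default 0.02).
#' @param min_separation_sd minimum mean separation in units of the larger
#'   component s.d. (default 2).
#' @return Object of class `mixture_fit`: list with `weights`, `means`,
#'   `sds` (log10-AU, means ascending), `loglik`, `loglik_trace`,
#'   `converged`, `bimodal`, `n_cells`.
#' @export
#' @examples
#' pop <- sample_flow_population(0.4, n_cells = 5000, n_replicates = 1,
#'                               seed = 1)[[1]]
#' fit_two_component_mixture(pop)
fit_two_component_mixture <- function(sample, max_iter = 500L, tol = 1e-8,
                                      min_weight = 0.02,
                                      min_separation_sd = 2) {
  x <- if (inherits(sample, "population_sample")) sample$fluorescence
       else as.numeric(sample)
  dropped <- sum(!is.finite(x) | x <= 0)
  if (dropped > 0) {
    message("dropping ", dropped, " non-positive/non-finite reading(s)")
    x <- x[is.finite(x) & x > 0]
  }
  if (length(x) < 100L)
    stop("insufficient data: need at least 100 cells for a mixture fit",
         call. = FALSE)
  lx <- log10(x)
  n <- length(lx)
  # init from the 25th/75th percentiles
  mu <- unname(quantile(lx, c(0.25, 0.75)))
  if (mu[2L] - mu[1L] < 1e-6) mu <- mu + c(-0.05, 0.05)
  s <- rep(max(sd(lx) / 2, 1e-3), 2L)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * dnorm(lx, mu[1L], s[1L])
    d2 <- w[2L] * dnorm(lx, mu[2L], s[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * lx) / n1, sum(r2 * lx) / n2)
    s <- sqrt(c(sum(r1 * (lx - mu[1L])^2) / n1,
                sum(r2 * (lx - mu[2L])^2) / n2))
    s <- pmax(s, 1e-4)  # guard against component collapse
  }
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; w <- w[ord]
  bimodal <- all(w >= min_weight) &&
    (mu[2L] - mu[1L]) >= min_separation_sd * max(s)
  structure(list(weights = w, means = mu, sds = s,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 converged = converged, bimodal = bimodal, n_cells = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component mixture (n = %d): w = %.3f/%.3f, mu = %.3f/%.3f, sd = %.3f/%.3f (log10 AU)\n",
    x$n_cells, x$weights[1], x$weights[2], x$means[1], x$means[2],
    x$sds[1], x$sds[2]))
  cat(sprintf("  loglik = %.2f, converged = %s, bimodal = %s\n",
              x$loglik, x$converged, x$bimodal))
  invisible(x)
}

# equal-posterior point between two weighted normal components, in the
# open interval (m1, m2); NA when no such point exists
posterior_equality_point <- function(w, mu, s) {
  a <- 1 / (2 * s[1L]^2) - 1 / (2 * s[2L]^2)
  b <- mu[2L] / s[2L]^2 - mu[1L] / s[1L]^2
  cc <- mu[1L]^2 / (2 * s[1L]^2) - mu[2L]^2 / (2 * s[2L]^2) +
    log((w[2L] * s[1L]) / (w[1L] * s[2L]))
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(NA_real_)
    x <- -cc / b
    return(if (x > mu[1L] && x < mu[2L]) x else NA_real_)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu[1L] & roots < mu[2L]]
  if (length(inside)) inside[1L] else NA_real_
}

#' Automatic gate placement from a mixture fit
#'
#' If the sample's two-component mixture fit is bimodal, the gate is the
#' fluorescence at which the posterior responsibilities of the two
#' components are equal (the minimum-misclassification boundary), mapped
#' back from log10 to AU.  Otherwise the configured fixed gate is
#' returned.
#'
#' @param sample a [population_sample()] or numeric AU vector.
#' @param fallback_gate gate in AU used when the sample is not bimodal
#'   (default 1000).
#' @param fit an optional pre-computed [fit_two_component_mixture()]
#'   result for the same sample.
#' @param ... passed to [fit_two_component_mixture()].
#' @return Gate position in AU.
#' @export
auto_gate <- function(sample, fallback_gate = 1000, fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_two_component_mixture(sample, ...)
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$bimodal) return(fallback_gate)
  xstar <- posterior_equality_point(fit$weights, fit$means, fit$sds)
  if (is.na(xstar)) return(fallback_gate)
  10^xstar
}

#' Per-strain population summary
#'
#' Combines the fixed-gate (or auto-gate) fraction-positive summary with
#' the mixture fit of the pooled replicates.
#'
#' @param samples list of [population_sample()] replicates of one strain.
#' @param gate fixed gate in AU.
#' @param use_auto_gate if `TRUE`, place the gate with [auto_gate()] on
#'   the pooled replicates.
#' @param ... passed to [fit_two_component_mixture()].
#' @return A one-row data frame with gate, per-replicate fractions
#'   (comma-joined), mean, SEM, mixture parameters and the bimodal flag.
#' @export
summarize_population <- function(samples, gate = 1000, use_auto_gate = FALSE,
                                 ...) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  pooled <- population_sample(
    "pooled", unlist(lapply(samples, `[[`, "fluorescence")),
    samples[[1L]]$strain_label)
  fit <- fit_two_component_mixture(pooled, ...)
  g <- if (use_auto_gate) auto_gate(pooled, fallback_gate = gate, fit = fit)
       else gate
  fp <- gate_fraction_positive(samples, g)
  data.frame(strain = samples[[1L]]$strain_label,
             gate = g,
             per_replicate_fractions = paste(
               sprintf("%.6f", fp$per_replicate_fractions), collapse = ","),
             mean_fraction = fp$mean_fraction,
             sem = fp$sem,
             n_replicates = fp$n_replicates,
             weight_low = fit$weights[1L], weight_high = fit$weights[2L],
             mean_low = fit$means[1L], mean_high = fit$means[2L],
             sd_low = fit$sds[1L], sd_high = fit$sds[2L],
             bimodal = fit$bimodal,
             stringsAsFactors = FALSE)
}
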