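# curlipulse

Quantitative single-cell analysis of **bimodal and pulsatile curli reporter
activation** in *Escherichia coli*.

Curli amyloid fibers are a major component of the *E. coli* biofilm
extracellular matrix, and expression of the curli structural operon
(*csgBAC*) is all-or-none: under nutrient depletion only a stochastically
chosen subpopulation of cells activates the genes, producing a bimodal
fluorescence distribution in a reporter strain. In mother-machine
microfluidics, where single mother cells are followed for tens of hours
across a switch from fresh to conditioned (spent) medium, the curli-on
state turns out to be *metastable*: individual cells switch the reporter on
after a delay, hold it for a few generations, and switch it off again, so
lineage traces show transient fluorescence pulses.

`curlipulse` implements the complete desk-scale analysis of such data, for
microbiologists and systems biologists working with mother-machine traces
or flow-cytometry snapshots:

* **Synthetic data generator** — a stochastic telegraph-model simulator of
  mother-machine lineage traces (exponential elongation with a medium-switch
  growth-rate drop, stochastic division, delayed on/off reporter switching,
  exact fluorescence integration, multiplicative measurement noise) and a
  two-component lognormal sampler of flow-cytometry-like endpoint
  populations. Every analysis stage is testable without any experimental
  download.
* **Trace features** — instantaneous growth rate (least-squares slope of
  log length within division segments), threshold-crossing time, maximal
  induction rate, first-peak amplitude, post-peak decay half-time, each
  with explicit censoring; threshold-aligned median ± interquartile
  expression profiles; time-resolved positive fractions; log-fluorescence
  kernel density estimates.
* **Population bimodality** — fixed-gate and mixture-model ("auto-gate")
  estimates of the curli-positive fraction, with replicate mean ± SEM and a
  two-component Gaussian EM fit on log10 fluorescence as a reproducible
  surrogate for manual cytometry gating.
* **Statistics** — Welch's unequal-variance two-sample *t*-test for
  between-strain comparisons of feature distributions.
* **Pipeline** — `run_pipeline()` ties simulation → features → population
  → report together with a reproducibility manifest; a thin CLI lives in
  `inst/cli/curlipulse.R`.

## The model in brief

Expression follows a two-state telegraph process: a cell switches
off → on at rate *k*<sub>on</sub> (only after the medium switch plus a lag)
and on → off at rate *k*<sub>off</sub>, so pulse durations are exponential
and the stationary on-fraction is *k*<sub>on</sub>/(*k*<sub>on</sub> +
*k*<sub>off</sub>). In the on state the reporter is produced at rate β
(drawn per pulse from a lognormal with cell-to-cell CV) and diluted by
growth and degradation:

&nbsp;&nbsp;&nbsp;&nbsp;d*F*/d*t* = β·[on] − (*g* + δ)·*F*

so a pulse rises toward the plateau β/(*g* + δ), and after switch-off
decays with half-time ln 2/(*g* + δ). Growth relaxes exponentially from
*g*<sub>fresh</sub> to *g*<sub>cond</sub> after the switch. These closed
forms are the oracles the test suite checks the estimators against.

## Worked example

```r
library(curlipulse)

## simulate a wild-type-like mother-machine experiment:
## 4 h fresh medium, then conditioned medium, 10-min frames, 30 h total
traces <- simulate_mother_machine(sim_config("regulated", n_traps = 140, seed = 1))

feats <- extract_trace_features(traces, threshold = 1000)
sum(!is.na(feats$crossing_time))
#> [1] 131
feats[1:4, c("trap_id", "crossing_time", "max_rate", "peak_amplitude",
             "decay_half_time", "censor_reasons")]
#>    trap_id crossing_time max_rate peak_amplitude decay_half_time   censor_reasons
#> 1 trap_001           760 138.6171       7844.538              NA decay_unfinished
#> 2 trap_002           420 160.2114       8188.002              NA decay_unfinished
#> 3 trap_003            NA       NA             NA              NA    never_crossed
#> 4 trap_004           790 186.0481       9332.104        483.6608
```

131 of 140 lineages crossed the 10^3-AU activation threshold; each row
holds one lineage's induction features, and censored values (a lineage that
never activated, or whose pulse had not decayed halfway by the movie's end)
are `NA` with an explicit reason, so they can be counted but never
contaminate a histogram.

```r
## endpoint cytometry: three replicates of 50,000 cells, 46% positive
pops <- sample_flow_population(0.46, n_cells = 50000, n_replicates = 3, seed = 1)
gate_fraction_positive(pops, gate = 1000)
#> Fraction positive at gate 1000 AU: 0.4603 +/- 0.0011 SEM (n = 3 replicates)
fit_two_component_mixture(pops[[1]])
#> Two-component mixture (n = 50000): w = 0.542/0.458, mu = 1.999/4.001, sd = 0.249/0.250 (log10 AU)
#>   loglik = -36027.41, converged = TRUE, bimodal = TRUE

## strain contrast: deregulated preset (c-di-GMP network removed) induces faster
fd <- extract_trace_features(simulate_mother_machine(
  sim_config("deregulated", n_traps = 245, seed = 1001)))
welch_t_test(fd$max_rate[is.finite(fd$max_rate)],
             feats$max_rate[is.finite(feats$max_rate)])
#> Welch two-sample t-test: t = 14.06, df = 310.81, p = 4.418e-35 (n = 231, 131)
```

The gated fraction recovers the generating 46% within sampling error, the
mixture fit recovers the component means (10^2 and 10^4 AU) and weights,
and the deregulated strain's maximal induction rates are significantly
larger — the package's analogue of the published strain contrast.

The full pipeline, with plots and a run manifest:

```r
run_pipeline(NULL, "results/run1", seed = 1)
```

or from a shell:

```sh
Rscript inst/cli/curlipulse.R pipeline --out results/run1 --seed 1
```

## Vignette

`vignettes/curli-pulse-analysis.Rmd` documents the model, the estimator
definitions and their numerical choices, what the synthetic generator does
and does not emulate, and known limitations.
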