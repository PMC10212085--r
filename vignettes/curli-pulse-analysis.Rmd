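---
title: "Quantifying bimodal and pulsatile curli activation in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bimodal and pulsatile curli activation in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curlipulse)
```

## The biological setting

Expression of the curli structural operon (*csgBAC*) in *E. coli* is
bimodal: at entry into stationary phase, or during growth in conditioned
(spent) medium, only a stochastically chosen subpopulation of cells turns
the operon on. At the single-cell level — mother-machine microfluidics,
where one "mother" cell per dead-end trap is imaged for tens of hours —
activation is also *transient*: a cell switches the reporter on after a
delay of several slow-growth generations, holds it for a few generations,
and switches it off again, producing a fluorescence pulse. The c-di-GMP
regulatory network (the DgcE/PdeH and DgcM/PdeR cyclase/phosphodiesterase
pairs) is not required for the bimodality itself, but shapes the pulse
dynamics: without it, induction is faster and more heterogeneous.

This package provides the quantitative machinery for that kind of data:
a synthetic generator with the same statistical structure, the single-trace
feature estimators, population-level bimodality quantification, and the
inferential statistics for strain comparisons.

## The synthetic generator

`simulate_mother_machine()` draws one lineage per trap under four
ingredients, each on its own RNG substream (L'Ecuyer-CMRG, split from one
root seed) so that toggling one noise source never perturbs the others.

**Growth.** The specific elongation rate follows the medium program
$$g(t) = g_\mathrm{cond} + (g_\mathrm{fresh} - g_\mathrm{cond})\,
          e^{-\max(0,\,t - t_\mathrm{switch})/\tau_\mathrm{relax}},$$
and length grows as $L(t+\Delta t) = L(t)\exp\!\int g\,dt$ with the
integral taken in closed form, so a noiseless trace is exactly
log-linear within a division cycle. Defaults: $g_\mathrm{fresh} =
0.02\,\mathrm{min^{-1}}$ (a ~35-min doubling time, typical for rich medium
at 30 °C), $g_\mathrm{cond} = 0.004\,\mathrm{min^{-1}}$ (the "strongly
reduced" post-switch growth, a ~3-h doubling), $\tau_\mathrm{relax} =
30$ min. The experiment timeline defaults mirror the reference protocol:
10-min frames, a switch at 240 min (4 h of fresh medium), 1800 min total,
300 traps.

**Division.** A cell divides when its length reaches a per-cycle threshold
drawn from $\mathcal N(L_\mathrm{div}, (c_v L_\mathrm{div})^2)$; the
retained daughter keeps a fraction drawn from $\mathcal N(0.5,
\sigma_r^2)$ truncated at $\pm 3\sigma_r$. On a division frame the
recorded length is `ratio * previous length`; regrowth within that frame
is folded into the next one. This convention makes the observed
frame-to-frame drop equal the drawn ratio, so division detection by a 25%
length drop (`detect_divisions()`) recovers the simulator's ground truth
exactly in noiseless mode. Defaults $L_\mathrm{birth} = 2\,\mu m$,
$L_\mathrm{div} = 4\,\mu m$, $c_v = 0.08$, $\sigma_r = 0.04$ are ordinary
*E. coli* morphology values.

**Expression.** A two-state telegraph process: off → on at rate
$k_\mathrm{on}$, allowed only after $t_\mathrm{switch} + \mathrm{lag}$;
on → off at rate $k_\mathrm{off}$. Per activation pulse a production rate
$\beta$ is drawn from a lognormal with median $\beta_\mathrm{med}$ and
coefficient of variation $c_\beta$. Fluorescence integrates
$$\frac{dF}{dt} = \beta\,[\mathrm{on}] - (g + \delta)\,F$$
exactly over each frame (with the frame-averaged $g$), floored at the
baseline $F_0$. Defaults for the `"regulated"` preset:
$k_\mathrm{on} = k_\mathrm{off} = 0.002\,\mathrm{min^{-1}}$ (mean dwell
times of ~8 h, i.e. pulses lasting a few slow-growth generations, with
~94% of lineages activating within the movie), lag 120 min,
$\beta_\mathrm{med} = 40$ AU/min, $c_\beta = 0.25$, $\delta = 0$ (stable
GFP: decay is by dilution only), $F_0 = 100$ AU, measurement noise CV
0.05. The `"deregulated"` preset doubles $\beta_\mathrm{med}$ and
$c_\beta$ and changes nothing else — the minimal encoding of "faster but
more heterogeneous induction without the c-di-GMP network". The AU scale
is a convention: the off-state baseline sits near $10^2$ AU and the
on-state plateau $\beta/(g+\delta)$ near $10^4$ AU, so the conventional
$10^3$-AU threshold separates the modes.

**Measurement noise** is multiplicative lognormal with mean 1, applied to
fluorescence only, last. Lengths are emitted noise-free; growth-rate
estimates from the generator are therefore cleaner than segmentation-based
ones from real images (see *Limitations*).

These closed forms double as test oracles: the pulse plateau
$\beta/(g+\delta)$, the amplitude after an on-time $\tau$,
$F_0 e^{-(g+\delta)\tau} + \frac{\beta}{g+\delta}(1 - e^{-(g+\delta)\tau})$,
the frame-averaged maximal slope
$(\beta/(g+\delta) - F_0)\,(1 - e^{-(g+\delta)\Delta t})/\Delta t$,
the baseline-relative half-decay $\ln\!\big(2A/(A + F_0)\big)/(g+\delta)$,
and the telegraph stationary on-fraction
$k_\mathrm{on}/(k_\mathrm{on} + k_\mathrm{off})$.

`simulate_pulse_traces()` is a deterministic companion: one rectangular
on-pulse per trace at a fixed time and duration, constant dilution.
It exists to exercise the feature estimators against the closed forms
above without the confounds of stochastic switching (in particular,
re-activation during the decay phase, which the telegraph process
produces by design — and which real lineages also show as second pulses).

`sample_flow_population()` emulates endpoint cytometry as a two-component
mixture on log10 fluorescence (defaults: negative mode $10^2$ AU, positive
mode $10^4$ AU, both with $\sigma = 0.25$ log10 units, 50,000 cells per
replicate), with independent per-replicate substreams.

## Feature estimators and their numerical choices

**Instantaneous growth rate** (`instantaneous_growth_rate()`): the
least-squares slope of log length over a centered window of 3 frames,
computed strictly within one division segment; windows clipped at a
division or the trace boundary become one-sided, and a single-frame
segment is undefined (`NA`). A 3-frame window is the shortest centered
window, trading noise suppression for responsiveness around the medium
switch; it is a parameter. The log-slope makes the estimator exactly
invariant to length rescaling, and exact on noiseless exponential growth.

**Threshold crossing** (`threshold_crossing_time()`): the time of the
first frame at or above the threshold (default $10^3$ AU), with *no*
interpolation — crossing times are conventionally reported at frame
resolution (10 min). Cells already above threshold at frame 1 (loaded
from stationary-phase culture) cross at the first frame time.

**Maximal induction rate** (`max_induction_rate()`): the maximum forward
difference divided by the frame interval, for threshold-crossing traces
only; non-positive maxima are censored. Whether published rates were
computed on raw or smoothed traces is not stated in the protocols this
mirrors; the default is raw, with an odd centered moving-average
`smooth_window` exposed. On noisy traces smoothing matters: with 5%
multiplicative noise, consecutive-frame differences near a $10^4$-AU
plateau have a noise standard deviation of ~50 AU/min, and the maximum
over a movie of such differences dominates a ~40 AU/min true slope. A
5-frame window reduces that noise about seven-fold (averaging plus
differencing across a 5-frame span) and restores the estimate to within a
few percent of the closed form, which is how the package's own recovery
checks analyze noisy pulses.

**First peak** (`first_peak_amplitude()`): the first local maximum at or
after the crossing whose topographic prominence reaches 10% of the
dynamic range (trace maximum minus the pre-crossing median). Prominence
filtering is what keeps a noise blip on the rising flank from being
mistaken for the pulse peak; 0.1 is a parameter. A trace still rising at
the end is censored (`no_peak`). Plateau frames of exactly equal value
count once, at the first frame of the run.

**Decay half-time** (`decay_half_time()`): time from the peak until
fluorescence first reaches halfway between the peak and the
*pre-induction baseline*, linearly interpolated between the bracketing
frames. Baseline-relative halving is deliberate: a stable reporter
diluted at $g \approx 0.004\,\mathrm{min^{-1}}$ never returns to zero
within a movie, so absolute halving would censor nearly everything; the
flag is exposed through the `baseline` argument.

**Censoring bookkeeping**: `extract_trace_features()` emits one row per
trace with reasons (`never_crossed`, `no_peak`, `decay_unfinished`,
`trace_too_short`, `no_rise`); censored values are `NA`, excluded from
summaries but always countable, so reported *n* values per histogram stay
interpretable.

**Aligned profiles** (`align_traces()`): traces shifted so the crossing
frame is relative time 0 (the crossing frame itself, not an interpolated
instant), medians and quartiles per relative time over traces with data
there, and per-bin counts. Quartiles use the default quantile definition;
with a single contributing trace the quartiles collapse onto the median.

**KDE** (`expression_kde()`): Gaussian kernel on log10 values with
Silverman's rule-of-thumb bandwidth (`bw.nrd0`), evaluated on a uniform
grid and renormalized to unit trapezoid mass over that grid, so truncated
grids still integrate to 1.

## Population bimodality

`gate_fraction_positive()` is the fixed-gate estimator (default
$10^3$ AU, for comparability with the trace threshold), summarized as
mean ± SEM over replicates with the $(n-1)$ sample standard deviation and
SEM 0 for a single replicate.

`fit_two_component_mixture()` is a plain EM on log10 fluorescence:
means initialized at the 25th/75th percentiles, both standard deviations
at half the pooled SD, weights at 0.5; convergence when the
log-likelihood improves by less than `tol` ($10^{-8}$); standard
deviations floored at $10^{-4}$ log10 units against component collapse;
non-positive readings dropped with a message (instrument artifacts, not
modeled). The per-iteration log-likelihood trace is returned and asserted
non-decreasing in the tests. A sample is called *bimodal* when both
weights are at least 0.02 and the means are separated by at least twice
the larger standard deviation. The weight floor means a ~1% minority
subpopulation is not flagged bimodal; in that regime `auto_gate()` falls
back to the fixed gate, which is the better estimator there anyway.

`auto_gate()` places the gate at the point of equal posterior
responsibility between the two components — the root of the implied
quadratic lying between the means, solved in closed form (degenerate
equal-variance case handled linearly; no valid root falls back to the
fixed gate). For a symmetric 50/50 mixture this is the midpoint,
$10^3$ AU at the default calibration; skewed weights shift it toward the
minority mode, matching a brute-force grid search in the tests.

Both estimators are provided because manual cytometry gating is typically
not specified precisely enough to reproduce; the fixed gate is the
default for comparability, the mixture gate is the reproducible
data-driven alternative.

## Statistics

`welch_t_test()` implements the unpaired unequal-variance *t*-test
(Welch–Satterthwaite degrees of freedom, two-sided *p*) used for all
between-strain feature comparisons; two-sided is the conservative choice
where sidedness is unstated. Conventions: identical degenerate samples
give $t = 0$, $p = 1$. No multiple-testing correction is applied across
the four feature comparisons, matching how such panels are conventionally
reported; the four *p*-values are emitted side by side in
`feature_report()` and a user who wants a correction can apply
`p.adjust`. The test suite verifies the implementation against both a
hand-computed fixture and `stats::t.test`, and calibrates its type-I
error on equal lognormal feature sets.

## The pipeline

`run_pipeline()` runs simulate → features → population → report for each
configured preset, writing tidy CSVs (traces, features, growth-rate and
positive-fraction series, aligned profiles, population samples and
summaries, Welch report), a base-graphics plot book, and a JSON manifest
with the MD5 of the resolved configuration and the root seed. All
randomness descends from that one seed; identical configuration and seed
give byte-identical CSVs (doubles are serialized with 17 significant
digits, which round-trips IEEE doubles exactly). The CLI at
`inst/cli/curlipulse.R` wraps the same functions; flags override the
config file, which overrides defaults.

## Problem sizes

The packaged checks run at desk scale, chosen to mirror the study design
while keeping the full suite fast: 140 and 245 traps for the
preset-contrast checks (yielding on the order of 130 and 230
threshold-crossing lineages, the reported analyzed-trace counts), 300
traps for stationarity checks, 200 pulses for estimator recovery,
3 × 50,000 cells per cytometry condition, 1000 replications for type-I
calibration. The complete test suite runs in well under a minute.

## What the generator does not emulate, and other limitations

* No images and no segmentation: the pipeline starts from segmented
  length/fluorescence traces, so segmentation errors (merged cells,
  tracking jumps) are out of scope, and simulated lengths carry no
  measurement noise. Passing tests demonstrate estimator correctness on
  the assumed trace structure, not robustness to segmentation artifacts.
* The telegraph model is phenomenological. It reproduces delayed,
  transient, re-initiating pulses and stationary on-fractions, but no
  mechanistic c-di-GMP network dynamics: `k_on` is constant after the
  lag, whereas in reality the activation propensity presumably tracks the
  cell's physiological state.
* Fluorescence is a single per-cell AU value; whether it represents total
  integrated or mean pixel intensity is left to the user's calibration.
* The cytometry sampler draws i.i.d. mixtures — no forward/side-scatter
  structure, no aggregates, no compensation; inputs are assumed
  singlet-gated. FCS files are not read directly; export the measured
  channel to the CSV interchange format.
* Only the retained mother cell is tracked; daughters are discarded at
  division, matching what the trace analysis consumes, so no lineage
  trees can be reconstructed.
* The bimodality call is threshold-based (weights ≥ 0.02, separation ≥ 2
  SD) rather than a formal test; the thresholds are configurable, and
  borderline calls should be inspected with `expression_kde()`.
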