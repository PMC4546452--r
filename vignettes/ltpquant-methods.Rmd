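---
title: "Methods: how ltpquant measures slice plasticity experiments"
author: "ltpquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how ltpquant measures slice plasticity experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltpquant)
```

# Scope and data model

`ltpquant` quantifies extracellular field-potential experiments in acute
hippocampal slices (Schaffer-collateral/CA1 type protocols), together with
the two companion read-outs that usually accompany them: dendritic-spine
shape tables and per-cell fluorescence (FISH) tables. The unit of signal
analysis is a `FieldTrace` — one uniformly sampled voltage sweep (mV) with
its stimulus times; a full experiment is a `SweepSet`, an ordered collection
of sweeps labelled by protocol epoch (`io_pre`, `ppf`, `baseline`, `hfs`,
`post`, `io_post`).

Time conventions: seconds inside traces and for stimulus/sweep times, minutes
for LTP time courses and the post-tetanic decay constant, milliseconds for
latencies, kinetic constants and analysis windows. Voltages are mV,
stimulus intensities µA, fluorescence arbitrary units.

# fEPSP feature extraction

## Baseline and fiber volley

The pre-stimulus baseline is the mean over the window 5 ms to 0.5 ms before
the stimulus (both ends configurable); its standard deviation provides the
per-sweep noise floor. Samples within 0.5 ms after each stimulus are blanked
as artifact — acquisition systems differ in artifact shape, so nothing inside
that window is ever interpreted.

The fiber volley is the first baseline-subtracted negative extremum in a
1–3 ms post-stimulus window. Because the volley is only a few samples wide at
10 kHz, the extremum is refined by parabolic interpolation through the
minimum and its two neighbours; without the refinement, a volley whose peak
falls between samples is underestimated by up to ~3%. A deflection must
exceed three baseline standard deviations, otherwise the amplitude is
reported as 0 with `detected = FALSE`.

## Maximal slope between 20% and 80% of the peak

The slope definition is the conventional one: the maximal slope of the
descending phase between 20% and 80% of the negative peak response. The
implementation:

1. A pilot smoothing spline (generalized cross-validation) fitted to the
   response window (default 3–30 ms post-stimulus) locates the negative peak
   and estimates the residual noise level (median absolute deviation of the
   residuals).
2. On the limb falling toward the peak, the 20% and 80% crossings of the
   smoothed magnitude define the slope span; amplitude ties break toward the
   earlier sample.
3. The reported slope is the most negative first derivative inside the span.
   If the pilot residuals are below 0.5% of the peak the sweep is treated as
   effectively noise-free and the derivative is taken by central differences
   of the raw samples (error well below 0.5% against a 10x-oversampled
   reference). Otherwise the derivative comes from a local-quadratic kernel
   regression (`KernSmooth::locpoly`, Gaussian kernel) whose bandwidth
   follows the noise level.
4. If the span holds fewer than three samples, the slope falls back to the
   two-point secant across the span and the result is flagged `"secant"`.

The bandwidth rule deserves a note. Taking the *minimum* of a noisy
derivative over a span is an extremum statistic: its bias grows like
$\sigma h^{-3/2}$ (less smoothing, more spurious extremes) while the
kernel-smoothing bias of the derivative grows like $h^2$. Balancing the two
gives $h^\ast \propto (\sigma/\text{peak})^{2/7}$; the prefactor (0.95 ms at
unit noise-to-peak ratio, clamped to [0.25, 1] ms) was calibrated on
synthetic fEPSP waveforms so that the two biases cancel across noise levels.
A fixed small window — the obvious alternative — fails dramatically: at 5%
peak-relative noise a 0.5 ms local-polynomial derivative misestimates the
maximal slope by 30–50% because the span minimum rides on derivative noise.
With the adaptive rule the median slope error at 5% noise is about 4%, and
baseline-normalized quantities (percent-of-baseline time courses, paired
pulse ratios) are nearly bias-free because residual multiplicative bias
cancels in ratios.

## Paired-pulse facilitation

`computePPF` measures both responses of a two-stimulus sweep and reports
slope2/slope1. Two corrections matter at a 50 ms interstimulus interval:
the first response's window is truncated before the second stimulus, and the
first response's decaying tail is subtracted under the second response. The
tail is modelled as an exponential estimated from the 12 ms preceding the
second stimulus by a two-segment-mean fit (noise-robust; falls back to a
constant when the segment is not a clean monotone decay). Without the
subtraction the ratio is biased low by 1–3%; with it, noise-free ratios are
exact to three decimals. At the experiment level the paired-pulse index is
the mean of per-sweep ratios over the paired-pulse sweeps of the protocol.

# Experiment-level quantities

* **Input-output curves** (`buildIOCurve`): sweeps grouped by intensity;
  mean ± SEM of fiber-volley amplitude and slope, ordered by intensity.
  Undetectable responses enter as zero slope and are counted in `n_flagged`.
  `selectBasalIntensity` returns the intensity at which the mean slope
  magnitude reaches a fraction (default 0.35, the midpoint of the usual
  30–40% convention) of its maximum, optionally linearly interpolated.
* **Normalized time course** (`normalizeTimecourse`): per-sweep slopes
  divided by the mean of the baseline bin means and expressed in percent, so
  the baseline bins average exactly 100% by construction. Bin width defaults
  to 1 min. PTP is the first post-induction bin — the protocol has no
  separate "PTP window", so the first bin after the last train is the natural
  operationalization. The late plateau at time *t* is the mean normalized
  slope over the preceding 5 min (so a 90-min read-out averages 85–90 min),
  matching how late LTP is reported from binned traces.
* **Train metrics** (`analyzeHfsTrains`): the depolarizing envelope is the
  trapezoidal integral of the voltage relative to 0 mV over
  [first stimulus, first stimulus + 1 s], negative for depolarizing
  envelopes; integration from the absolute zero line follows the reporting
  convention for this quantity, and an `envelopeFromBaseline` flag provides
  the DC-offset-robust alternative. The afterpositivity is the maximal
  positive deflection, relative to the pre-tetanus baseline mean, 50–100 ms
  after the last train stimulus, read from a 10 ms moving-average-smoothed
  trace: the AFP is a slow bump, and the raw maximum over a 500-sample
  window would carry a +0.05 mV extremum bias at typical noise. Relative AFP
  values are normalized to the first train.
* **LTP–PPF correlation** (`correlateLtpPpf`): Pearson r with a two-sided
  p across slices.

# Statistics and reporting

`compareGroups` wraps the standard tests (unpaired equal-variance t-test,
one-way ANOVA with pairwise post-hoc t-tests, two-way ANOVA) around base R's
`t.test`/`aov`. The Holm–Šidák step-down adjustment is implemented natively
(`holmSidak`): order the m p-values ascending, adjust the i-th as
$1-(1-p_i)^{m-i+1}$, enforce monotonicity, restore order. For input-output
comparisons the two-way design is `value ~ group * intensity` with the group
main effect reported; published degrees of freedom for such comparisons are
rarely reconstructable from text, so the design is explicit and configurable
rather than guessed. Significance stars follow the common convention
(p ≤ 0.05 / 0.01 / 0.005). `reportTables` renders whatever analyses are
supplied into a deterministic plain-text report.

Two-sample Kolmogorov–Smirnov comparisons (`ksCompare`) compute D exactly as
the maximal ECDF distance over the pooled observed points and use the
asymptotic Kolmogorov series with Stephens' effective-sample-size correction
for the p-value.

# Spine morphometry

The shape statistic is the length-to-width ratio. Group summaries average
within slices first and report mean ± SEM across slices, because sample sizes
in this field count slices; a pooled-spine mode (`perSlice = FALSE`) exists
for cumulative-distribution analyses, which pool spines. The
binned-subpopulation comparison uses 0.5-wide bins on [0, 6) plus an overflow
bin (figure-style histograms of this parameter typically span that range),
two-proportion z-tests per bin and Holm–Šidák correction across bins; bins
with fewer than five pooled spines are not tested, as the normal
approximation is invalid there. Spine density is count/length per dendrite,
averaged across dendrites.

# What the generators emulate — and what they do not

`simulateSweep`/`simulateExperiment` build sweeps from parametric kernels:

* fEPSP: $(1-e^{-t/\tau_r})^2 e^{-t/\tau_d}$, negative, peak-normalized.
  The squared-exponential onset makes the waveform smooth at response start.
  A plain difference of exponentials was rejected because its derivative is
  discontinuous at onset, which puts the "maximal slope in the 20–80% span"
  exactly on a kink that no smoother can measure — and real fEPSPs rise
  sigmoidally.
* fiber volley: a narrow negative Gaussian (0.3 ms sd, 2 ms latency);
  artifact: one biphasic sine period (0.5 ms), blanked by the analysis;
  afterpositivity: a positive alpha function peaking 70 ms after the last
  train stimulus, inside the conventional 50–100 ms window, scaled per train.
* input-output gain: a saturating exponential over 25–300 µA, non-decreasing
  and normalized to 1 at the maximum; responses scale linearly with
  gain x potentiation.
* plasticity: the post-induction potentiation follows
  plateau + (PTP − plateau)·exp(−t/τ) with τ in minutes; paired stimuli
  scale by the facilitation factor; within-train responses run down
  exponentially (default τ = 50 ms, which reproduces realistic first-train
  envelope areas of tens of mV·ms); `calibrateTrainEnvelope` sets the
  amplitude so the closed-form first-train envelope
  (`trainEnvelopeAreaTheory`) hits a target exactly, independently of the
  measurement path.
* noise: additive white Gaussian. Defaults represent the young-animal
  parameterization (PTP 206.1%, plateau 160.2%, PPF 1.58, AFP 0.19 mV with
  1/1.35/1.55/1.61 train scaling).

Paced epochs are represented by sweep timestamps (0.1 Hz) rather than one
continuous 90-min trace, keeping a full experiment around 4 MB. Every
generated object carries its ground truth (per-stimulus component amplitudes
in the trace metadata, protocol parameters in the `SweepSet`), so recovery
tests close the loop from generator to pipeline.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real recordings: correlated (1/f, line-frequency) noise,
electrode drift and DC offsets, population spikes contaminating the fEPSP,
stimulation artifacts longer than the blanking window, slice-to-slice
waveform heterogeneity, and any coupling between late LTP and paired-pulse
change across slices (the biological correlation is not built in, so the
correlation analysis can only be validated for its null behaviour).

Spine populations are correlated bivariate lognormals: the ratio is then
lognormal with log-variance
$\sigma_L^2+\sigma_W^2-2\rho\sigma_L\sigma_W$, and
`spineConfigForMeanRatio` places the mean ratio by the lognormal moment
formula. The default log-sds (0.5/0.5, ρ = 0.103) give a ratio log-sd of
0.67, chosen a priori so that the two morphometry conditions studied in the
tests (mean ratios 2.87 vs 1.84) sit at a distribution-level KS distance of
0.26 — i.e. realistic overlap, not separated toy distributions. Cell
fluorescence is background + fold-change x control signal + per-cell noise;
the recorded `background` column carries the per-slice background estimate
while the realized background fluctuates around it, which is exactly what
makes downstream percent-of-control estimates consistent rather than
degenerate.

# FISH quantification

`correctBackground` subtracts the recorded background and clips negative
values at zero (counting the clips). `percentOfControl` defines 100% per
cell type as the mean corrected control fluorescence, expresses each cell as
a percentage of that mean, and summarizes per (condition, cell type) as
mean ± SEM over cells — sample sizes in this assay count cells; a slice-level
mode exists behind `perCell = FALSE`. The normalization is idempotent and
invariant to rescaling of the intensity units, and these properties are
tested to machine precision.

# Numerical choices and degenerate inputs

* Flat or sub-threshold responses are flagged (`no_response`, fiber volley
  `detected = FALSE`) rather than propagated as numbers; input-output curves
  report them as zeros with a flag count.
* 20%/80% crossing ties break toward the earlier sample.
* Envelope integration uses the trapezoid rule at the native sampling rate;
  on a rectangle this is exact, on smooth trains it agrees with 10x
  fine-grid integration to well under 0.1%.
* Trace files round-trip bit-exactly at the printed precision (six
  decimals); all CSV/JSON outputs are deterministic given a seed, which the
  test suite verifies byte-for-byte, including through the command-line
  interface.
* Generators reset R's RNG deterministically from `config@seed`; identical
  seed and configuration give bit-identical output.

# Problem sizes used by the tests

The packaged tests validate the slope estimator against a 10x-oversampled
derivative oracle on 100 noise-free waveforms spanning rise/decay constants
of 1.5–4 ms and 10–30 ms; recover PTP/plateau/PPF/AFP scaling from 20
simulated experiments at 5% peak-relative noise (tolerances ±5 / ±3
percentage points, ±0.05, ±0.05); check null behaviour on 16 pooled
no-plasticity experiments (every bin within 3 SEM of 100%) and 1000
null correlations; compare the KS statistic with brute force on 500 random
sample pairs; and estimate the family-wise error of the binned spine
comparison from 1000 null simulations of 300-spine groups. These sizes give
Monte-Carlo margins comfortably below the stated tolerances while keeping
the full suite around three minutes on one core.

# Known limitations

* The slope estimator's bandwidth calibration targets fEPSP-like kinetics
  (milliseconds); signals with much faster descending phases approach the
  secant fallback.
* The paired-pulse tail correction assumes a monotone exponential tail at
  the second stimulus; intervals short enough that the second response rides
  the *rising* phase of the first are not supported.
* The asymptotic KS p-value is approximate for very small samples (the D
  statistic itself is always exact); heavy ties make it conservative.
* The two-way ANOVA treats intensity as a factor, not a covariate; no
  repeated-measures or mixed-effects machinery is provided.
* Percent-of-control SEMs over cells treat cells as independent; with few
  slices per condition the slice-level mode is the safer summary.
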