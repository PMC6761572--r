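---
title: "Decoding pulsatile transcription-factor dynamics at target promoters"
author: "pulsedecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pulsatile transcription-factor dynamics at target promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedecode)
```

## The scientific setting

p53 responds to stress with pulses whose amplitude, duration and frequency
carry information. Experimentally, those pulse features can be controlled
independently of DNA damage by exchanging growth medium with and without an
MDM2 inhibitor (Nutlin-3) on a microfluidic device: the drug blocks
MDM2-mediated p53 degradation, so a square-wave drug schedule produces a
train of p53 pulses whose shape follows the schedule. Single cells carrying
a p53-Venus fusion and a promoter--mCherry transcriptional reporter are
imaged every 20 min, and the question is how a target promoter *decodes*
the p53 input: what amplitude threshold it has, how sensitive it is to pulse
duration, and which pulse frequencies it passes.

`pulsedecode` implements this analysis end to end on synthetic data so that
every stage is testable without any download: dosing regimens, a single-cell
trace generator, the post-segmentation trace-processing pipeline, the
promoter-activation model and its dose--response fit, activation metrics,
trace clustering, frequency-filter classification, and geminin-based
cell-cycle scoring.

## The promoter-activation model

Reporter protein accumulation is modelled by a delayed Hill equation,

$$\frac{d[\mathrm{mCherry}]}{dt} \;=\;
  k_{\max}\,\frac{p53(t-\tau_d)^h}{K^h + p53(t-\tau_d)^h}
  \;-\; \gamma\,[\mathrm{mCherry}],$$

with $k_{\max}$ the maximal production rate (AU/h), $h$ the Hill
coefficient, $K$ the p53 level at which production is half-maximal
(normalized AU), $\tau_d$ a fixed 2-h delay absorbing transcription,
translation and fluorophore maturation, and $\gamma$ the reporter protein
decay rate. The default $\gamma$ is $6.7\times10^{-4}\,\mathrm{min}^{-1}$
($0.0402\,\mathrm{h}^{-1}$, a PEST-tagged reporter's measured turnover);
internally all rates are in hours. Because that half-life (about 17 h) is
long compared with the 15-h dose--response window, decay is ignored when the
dose--response is *constructed* (`build_dose_response()` pairs the delayed
input with the raw production rate), while the forward simulator
(`simulate_reporter()`) always integrates the full equation.

The dose--response is built frame by frame: for each time $t$ in the window
with $t \ge \tau_d$, the point $(p53(t-\tau_d),\; d[\mathrm{mCherry}]/dt)$
is emitted, the derivative estimated by central finite differences
(one-sided at the ends). `fit_hill()` then minimizes the squared deviation
from the Hill curve over $(k_{\max}, h, K)$ with Levenberg--Marquardt
iterations multi-started from a coarse grid (three $k_{\max}$ scales, four
$h$ values, three $K$ quantiles), under box bounds
$k_{\max} \in (0, 10\max r]$, $h \in [0.5, 20]$,
$K \in (0, 2\max p]$. The best-of-starts fit is returned as a classed model
object with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
`plot` and `simulate` methods. A trajectory-space fit
(`fit_hill_trajectory()`, Nelder--Mead on log-parameters against the
simulated trajectory) is provided as an independent cross-check; the test
suite verifies the two routes agree on clean data, and compares `fit_hill()`
against a dense brute-force grid search refined once.

Whether the published analysis paired the rate at $t$ with the input at
$t-\tau_d$ or binned by input level is not documented; frame-paired points
were chosen because they keep the construction local and invertible.
Likewise the original optimizer and loss are unstated, so $h$ is treated as
a free bounded parameter.

## Dosing regimens

`make_regimen()` provides the six canonical schedules (natural 10 uM
3 h/2.5 h; low frequency 3 h/8 h; high frequency 2.5 h/2 h; long duration
8 h/3 h; low and high amplitude 5 and 15 uM with natural timing) as
square-wave inputs, right-continuous at switch times so sampling on the
20-min frame grid is unambiguous. A final cycle running past the experiment
span is truncated. Regimens are data, not code: they serialize to a
key/value config format bit-exactly, and custom schedules (e.g. a 40-h
two-pulse run) are expressed the same way.

## What the synthetic generator emulates -- and what it does not

`generate_p53_traces()` is a phenomenological pulse-train emulator, not a
mechanistic p53 model. Per on-phase, a pulse rises linearly and decays
exponentially after washout; its peak is
$A \cdot \min(t_{on}, t_{rise})/t_{rise}$ with $A$ lognormal per pulse
(mean 1, CV 0.70 by default -- the documented cell-to-cell variability of
p53 pulse amplitudes). Defaults were fixed once as the study conditions:

* `n_cells = 50` (at least 45 usable cells per condition);
* `basal = 50`, `pulse_amp_mean = 650` AU, placing the half-activation
  thresholds of the two reference promoters (407 and 490 normalized AU)
  inside the swept range;
* `amp_cv = 0.70`;
* `rise_time = 4` h: a natural 3-h exposure does not quite saturate p53
  accumulation, so amplitude orders high-frequency < natural <
  long-duration, reproducing why the long-duration condition gives the
  broadest input range and is used for dose--response construction;
* `decay_halflife = 1` h after washout (no published value; exposed in the
  config);
* `noise_sd = 10` AU additive measurement noise; 20-min frames.

All randomness flows through one seed recorded in the output metadata;
identical configs reproduce identical traces bit for bit.

The generator reproduces the period, duration and amplitude statistics the
downstream analysis consumes. It does **not** reproduce promoter-intrinsic
temporal selection, and this has a consequence worth stating plainly: a
memoryless Hill promoter driven by this open-loop input cannot robustly
prefer the natural frequency over the high frequency once per-pulse
amplitudes fluctuate with CV 0.70, because the lognormal amplitude lottery
equalizes the *expected* above-threshold exposure between those regimens
(more, weaker pulses vs fewer, stronger ones). In the deterministic limit
the band-pass preference is present; under the realistic amplitude
variability it is washed out. The band-pass/low-pass classification of real
promoters therefore reflects biology beyond the Hill model (e.g. promoter
recovery times), and passing the synthetic filter-classification tests
should not be expected from the Hill model alone. The package still
provides the full filter-classification machinery (`frequency_profile()`,
`classify_filter()`), and the directional claims that *do* follow from the
model -- duration sensitivity and matched-cumulative-input rate ordering --
are asserted in the test suite.

Similarly, the per-cell `timing` metric (time to half of the cell's own
dynamic range) makes small responses look fast: a low-frequency trace
reaches its (low) half-max during its first pulse. Direction-of-change
claims about timing across regimens are therefore not asserted on synthetic
data.

`simulate_feedback()` adds a deliberately minimal p53--MDM2 negative
feedback loop (drug inhibits MDM2-mediated p53 degradation; p53 drives MDM2
production through a Hill term). It is qualitative by design: only
directions are meaningful, and the suite asserts exactly three -- elevated
MDM2 at 5.5 h and 11 h under long-duration input relative to natural, a
suppressed second p53 pulse under long-duration input (the refractory
period), and a low p53 fixed point without drug.

`generate_geminin_traces()` emulates cell-cycle reporter traces over 40 h in
three classes (arrested basal; progressing sustained; progressing pulsatile
with division events at geminin drops), with episode layouts chosen so that
ground-truth labels always agree with the published ">25 h basal" arrest
rule -- the generator is constructed to be separable, so classifier tests
measure the classifier, not boundary luck.

## Trace processing

The processing chain mirrors a post-segmentation microscopy pipeline:

* `subtract_background()`: the mode of an intensity histogram (tallest-bin
  centre, bins centred on the data) is subtracted, flooring at zero.
* `interpolate_gaps()`: linear interpolation of interior missing frames;
  leading/trailing gaps take the nearest measured value (the published
  pipeline says only "surrounding frames"). Division-frame spikes are
  handled by marking frames missing and interpolating. Idempotent.
* `smooth_traces()`: the published pipeline names a smoothing function that
  does not correspond to any documented filter, so the default here is a
  centred moving average (window 3 frames = 1 h) with symmetric edge
  shrinkage; the method is pluggable for users who want to substitute their
  own.
* `normalize_to_t0()`: division by the cross-cell mean at the first frame
  (illumination correction); afterwards that mean is exactly 1.
* `count_pulses()` / `qc_select()`: a pulse is a local maximum whose
  topographic prominence exceeds 20% of the trace's dynamic range (the
  prominence criterion is unpublished; 0.2 is the package default and a
  config knob). QC keeps cells whose pulse count equals the number of
  completed on-phases and rejects traces whose largest frame-to-frame jump
  exceeds 50% of the dynamic range (spike rule, also a config knob).
* `cumulative_signal()`: trapezoidal integration, e.g. cumulative p53 over
  the 24-h movie for amplitude-modulation analysis.

## Metrics and comparisons

A cell *responds* when its final reporter level is at least twice its trace
minimum; when background subtraction has produced a non-positive minimum the
ratio is undefined and an absolute-increase fallback (1 AU by default) is
used and flagged. For responders, `compute_metrics()` reports `timing`
(first crossing of baseline + half the dynamic range, linearly
interpolated), `magnitude` (that half-max level) and `rate` (least-squares
slope between activation onset -- 10% of the dynamic range -- and timing).
Baseline is the mean of the first three frames (1 h). The onset fraction
and baseline window are configurable; robustness of direction-of-change
conclusions to these choices is exercised in the tests.

`matched_rate()` compares regimens at equal cumulative p53 exposure: the
reference (long-duration) cumulative input at its first pulse peak defines
a target $C^\*$; the comparison regimen's activation rate is measured from
its first pulse peak to $t_X + \tau$, where $t_X$ is when its cumulative
input reaches $C^\*$ (found by inverting the trapezoidal integral) and
$\tau = 5.5$ h is the natural pulse period. Anchoring $C^\*$ at the
reference's first-pulse peak is a package choice -- the published schematic
fixes the interval endpoints but not the equality reference. Note the two
distinct time constants kept deliberately separate: the 2-h reporter delay
(`tau_d`) and the 5.5-h pulse period (`tau_period`).

Group differences use the equal-variance two-sample t-test with the
conventional 0.05 significance threshold (`compare_groups()`).

## Clustering and filter classes

`kmeans_traces()` clusters per-cell activation traces (default $k = 4$,
five restarts) under the correlation distance $1 - r$. Traces are
standardized per cell first -- the representation in which correlation
distance is a scaled Euclidean distance -- and standardization is on by
default precisely because the metric demands it. Determinism is taken
seriously: assignments break ties toward the lowest-index centroid, an
emptied cluster is re-seeded with the farthest member of the largest
cluster, and the seeded restart loop makes the best-of-restarts result
reproducible.

`classify_filter()` maps a metric profile at (low, natural, high) pulse
frequency to all-pass / band-pass / low-pass with a relative margin
(default 0.2, a package invention since the published classification was by
inspection); the margin is a parameter and the classification is
scale-invariant.

## Cell-cycle scoring

`classify_cellcycle()` uses a relative elevation threshold (1.5x the cell's
own first-hour baseline; no absolute threshold is published) and the
published arrest rule: basal geminin for more than 25 h of the 40-h movie.
Progressing cells split into pulsatile (the signal returns to basal before
the end -- geminin is degraded at mitosis) and sustained. Divisions are
counted from annotations only; inferring divisions from trace drops is
deliberately out of scope since divisions were tracked visually.

## Numerical choices

* ODE integration: fixed-step classical Runge--Kutta with 10 sub-steps per
  20-min frame (2-min step); halving the step changes trajectories by less
  than 0.1%, which the suite asserts. The delayed input is linearly
  interpolated between frames and clamped to the $t=0$ value for
  $t < \tau_d$ (no published pre-history).
* The parameter-recovery verification (and the acceptance script) runs the
  long-duration simulation on a 5-min grid. On the 20-min microscope grid
  the central-difference derivative smears the steep post-washout sweep
  through the Hill transition and biases the recovered $h$ by several
  percent; grid resolution is a property of the numerical verification
  experiment, not of the model, and the 20-min path is still exercised by
  the integration tests. Problem sizes used by the verification suite: one
  synthetic cell for deterministic recoveries, 40--60 cells per regimen for
  directional comparisons, 500 cells for the amplitude-CV law-of-large-
  numbers check, 1000 cells for the arrest-fraction recovery.
* Degenerate inputs fail loudly: flat dose--response curves are declared
  unidentifiable rather than fitted; constant traces are rejected by the
  correlation distance; an all-missing trace cannot be interpolated.

## Known limitations

The generator's pulse shape (linear rise, exponential decay) and its
dose-to-amplitude linearity are conveniences, not measurements; the
feedback emulator is qualitative; the filter-classification and timing
caveats above mean that synthetic-data tests validate the *machinery* and
the model-implied directions, not every published phenomenological
observation. Reproducing the published fold-changes requires the deposited
single-cell datasets, which users can feed in as long-format tables via
`read_traces()`.

## A complete run

```{r, eval = FALSE}
cfg <- list(
  seed = 1,
  regimen = "long_duration",
  generator = list(n_cells = 50),
  model = list(k_max = 135, h = 7.5, K = 407),
  reporter_noise_sd = 5,
  cellcycle = list(frac_arrested = 0.42, n_cells = 200)
)
bundle <- run_pipeline(cfg, out_dir = "run1")
coef(bundle$fit)
bundle$summary
```
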