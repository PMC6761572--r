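# pulsedecode

Single cells decode the *dynamics* of the tumor suppressor p53 — pulse
amplitude, duration and frequency — into distinct target-gene responses.
`pulsedecode` is an R package for analyzing that decoding in single-cell
fluorescence time-lapse data, built around the experimental design in which
square-wave schedules of an MDM2 inhibitor (Nutlin-3) impose p53 pulse
trains of chosen amplitude, duration and frequency while a promoter–mCherry
reporter reads out target promoter activation, and a geminin–mCherry
reporter reads out cell-cycle progression.

It is aimed at systems biologists who want a tested, reproducible pipeline
for this class of experiment: everything runs on synthetic data generated
in-package, and real data can be supplied as long-format trace tables.

## The model at the core

Promoter activation is a delayed Hill function of the transcription-factor
input; reporter protein obeys

    d[mCherry]/dt = k_max * p53(t − τ_d)^h / (K^h + p53(t − τ_d)^h) − γ [mCherry]

with maximal production rate `k_max` (AU/h), Hill coefficient `h`,
half-activation threshold `K` (normalized AU), delay `τ_d = 2 h`, and
reporter decay `γ = 6.7e-4 /min`. The package forward-simulates this model,
constructs the dose–response (delayed p53 level vs reporter production
rate) over the first 15 h of a long-duration treatment, and fits
`(k_max, h, K)` by multi-start nonlinear least squares, returning a classed
model object (`hill_fit`) with the usual `coef`/`predict`/`plot`/
`simulate`/`residuals` methods.

Around the model sit the rest of the analysis stages: dosing-regimen
construction (`make_regimen`), synthetic single-cell trace generation
(`generate_p53_traces`, `generate_reporter_traces`,
`generate_geminin_traces`, `simulate_feedback`), trace processing
(`subtract_background`, `interpolate_gaps`, `smooth_traces`,
`normalize_to_t0`, `qc_select`, `cumulative_signal`), activation metrics
(`classify_responder`, `compute_metrics`, `matched_rate`,
`compare_groups`), clustering and frequency-filter classification
(`kmeans_traces`, `classify_filter`), cell-cycle scoring
(`classify_cellcycle_set`, `summarize_population`), and an end-to-end
driver (`run_pipeline`). The methods vignette
(`vignettes/promoter-pulse-decoding.Rmd`) documents the model, the
generator's assumptions, and every tunable default.

## Worked example: recovering promoter parameters

Simulate a noiseless single-cell response to the long-duration regimen with
the MDM2-promoter parameters, rebuild the dose–response, and refit:

```r
library(pulsedecode)

reg <- make_regimen("long_duration")
reg
#> Pulse regimen 'long_duration': 10 uM, 8 h on / 3 h off (period 11 h) over 24 h

p53 <- generate_p53_traces(reg, generator_config(n_cells = 1, amp_cv = 0,
                                                 noise_sd = 0, dt = 1/12))
pars <- hill_params(k_max = 135, h = 7.5, K = 407, gamma = 0,
                    gamma_units = "per_h")
mch <- generate_reporter_traces(p53, pars)
curve <- build_dose_response(p53, mch, tau_d = 2, window = c(0, 15))
curve
#> <dose_response> 157 points over window [0, 15] h (delay 2 h)
#>   input range [50, 700] AU, rate range [3.89e-05, 133] AU/h

fit <- fit_hill(curve)
summary(fit)
#> Hill fit (rate-space), 157 points, RSS = 0.33737
#>         estimate  std. error
#> k_max 135.056655 0.008013558
#> h       7.451956 0.002316447
#> K     407.048795 0.019580809
#> 36 of the multi-start fits converged
```

The fitted maximal activity (135.06 AU/h), Hill coefficient (7.45) and
threshold (407.05 AU) recover the generating values — the promoter's
amplitude threshold `K` is the p53 level at which production runs at half
speed, and the steep `h` means activation is nearly switch-like around it.
`plot(fit)` overlays the fitted curve and marks `K` and `k_max/2`.

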