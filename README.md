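# pamdown

Can broadband dolphin echolocation clicks, normally recorded at 192 kHz, be
captured by cheaper recorders sampling at 48 or 96 kHz (Nyquist frequencies
of 24 and 48 kHz)? `pamdown` implements the two standard evaluations of that
question for passive acoustic monitoring (PAM) of odontocetes, end to end,
on synthetic soundscapes with exact ground truth:

1. **Spectrogram census** — every click in a full-rate recording is judged
   for spectral occurrence below the 24 and 48 kHz thresholds against a
   local noise floor, yielding paired per-sample proportions (clicks seen
   below each threshold / all clicks).
2. **Downsample–detect–match** — recordings pass through an anti-aliasing
   chain (4th-order Butterworth 15 kHz high-pass, linear-phase FIR low-pass,
   decimation) to 96 and 48 kHz; an envelope-threshold detector (grid-
   optimised for sensitivity and precision on annotated 5-s subsamples) runs
   at every rate; a 0.2 s inter-detection interval filter strips isolated
   (snap-like) detections; and 1-s presence bins are matched across rates.

Both approaches feed the same statistics: a binomial logit-link GLMM per
sample unit *i*,

    k_i ~ Binomial(n_i, p_i)
    logit(p_i) = x_i' b + u_rec(i) + v_sample(i)

with frequency threshold × environment fixed effects and sample pairs nested
in recordings as random intercepts; AICc model selection with Akaike
weights, AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1); theoretical marginal/conditional
R²_GLMM (logit distribution variance π²/3); estimated marginal means
back-transformed from the logit scale; and simulation-based quantile-residual
diagnostics with a Kolmogorov–Smirnov uniformity test.

The synthetic soundscape generator renders 192 kHz recordings of click
trains (inter-click intervals 20–150 ms, trains separated by >0.2 s gaps)
whose per-click spectral support below 24/48 kHz is drawn with stated
probabilities, over white or pink noise, optionally with snapping-shrimp-like
impulsive interference — so every pipeline stage is testable without field
recordings.

## Worked example

Census two synthetic open-water recordings (truths: 86% of clicks below
24 kHz, 99.6% below 48 kHz) and fit the paired-proportion model:

```r
library(pamdown)

scs <- lapply(c(42, 43), function(s) render_soundscape(
  synth_config(duration_s = 20, click_rate = 15, snr_db = 25,
               environment = "open", seed = s)))

counts <- do.call(rbind, lapply(scs, function(sc) {
  clicks <- echolocation_filter(sc$truth$clicks)   # drop buzz-regime clicks
  censused <- census_clicks(clicks, spectrogram(sc$recording))
  units <- segment_samples(sc$recording, unit_s = 5)
  do.call(rbind, lapply(seq_len(nrow(units)), function(u)
    census_sample(units[u, , drop = FALSE], censused)))
}))
head(counts, 4)
#>        recording_id index n_total n_below24 n_below48
#> 1 synth_open_seed42     1      35        26        35
#> 2 synth_open_seed42     2      46        37        45
#> 3 synth_open_seed42     3      38        37        38
#> 4 synth_open_seed42     4      29        28        29

props <- census_to_proportions(counts)
fit  <- fit_binomial_glmm(props, fixed = ~ freq)
null <- fit_binomial_glmm(props, fixed = ~ 1)
model_comparison(list(candidate = fit, null = null))
#>      model df    loglik      aicc delta_aicc       weight
#>  candidate  4 -24.31538  60.26713    0.00000 1.000000e+00
#>       null  3 -48.45630 104.91260   44.64547 2.020036e-10

estimated_marginal_means(fit)
#>  freq      prob  se_logit       lcl       ucl
#>    24 0.8770964 0.2751525 0.8062660 0.9244571
#>    48 0.9944621 0.7543391 0.9761565 0.9987320

residual_diagnostics(fit, n_sim = 1000, seed = 1)$p_value
#> [1] 0.678
```

The census recovers the generator's truths: the estimated marginal mean at
the 24 kHz threshold (0.877, CI 0.806–0.924) brackets the simulated 0.86,
and at 48 kHz (0.994) the simulated 0.996; the frequency effect is decisive
(ΔAICc ≈ 45, candidate weight ≈ 1), and the uniform quantile residuals
(KS p = 0.68) show no misfit.

`run_experiment()` orchestrates the full two-environment experiment — both
approaches, detector optimisation, both model comparisons, estimated
marginal means, CSV outputs and a provenance manifest — from a single
`experiment_config()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end synthetic experiment from scratch at the
given seed — soundscape generation for both environments, the spectrogram
census, the downsample/detect/filter/match pipeline, detector-grid
optimisation, and both GLMM model comparisons with estimated marginal
means — printing the comparison and EMM tables it computes and writing the
JSON report to `--out`.
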