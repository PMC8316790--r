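---
title: "Evaluating reduced sampling rates for echolocation click recording"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reduced sampling rates for echolocation click recording}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Bottlenose dolphin echolocation clicks are broadband transients reaching well
beyond 100 kHz, so passive acoustic monitoring (PAM) conventionally records at
192 kHz or more. Recorders limited to 48 or 96 kHz sampling rates (Nyquist
frequencies of 24 and 48 kHz) are far cheaper. If clicks routinely carry
energy below those thresholds — as off-axis recordings of broadband clicks
do — presence/absence studies could use the cheaper devices. `pamdown`
implements the two standard ways to quantify that, end to end, on synthetic
soundscapes whose ground truth is known exactly:

1. **Spectrogram census.** Every annotated click in a full-rate recording is
   judged for spectral occurrence below 24 and below 48 kHz, and each 1-min
   sample yields paired proportions (clicks seen below each threshold, out of
   all clicks).
2. **Downsample–detect–match.** Recordings are downsampled through an
   anti-aliasing chain to 96 and 48 kHz, an envelope-threshold detector (with
   parameters optimised against annotated 5-s subsamples) runs at every rate,
   detections are cleaned by a 0.2 s inter-detection interval filter, and 1-s
   presence bins are matched across rates: of the seconds with detections at
   the original rate, how many still show detections at the reduced rate?

Both approaches produce paired per-sample proportions analysed with the same
mixed-model machinery.

## The statistical model

For sample unit $i$ with $k_i$ successes out of $n_i$ (clicks below a
threshold out of all clicks; or matched presence bins out of original-rate
presence bins):

$$k_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = \mathbf{x}_i^\top \beta + u_{r(i)} + v_{s(i)},$$

with fixed effects for frequency threshold, environment (lagoon vs open
water) and their interaction, and random intercepts for recording
($u_r \sim N(0, \sigma_r^2)$) and sample pair nested within recording
($v_s \sim N(0, \sigma_s^2)$). The pairing — the same sample contributes one
row per frequency level — is what the sample-level intercept absorbs.
Estimation is by Laplace-approximate maximum likelihood (`lme4::glmer`); this
package owns the model construction, contrasts, model comparison and all
derived quantities.

Model selection compares the candidate against an intercept-only null by the
small-sample-corrected Akaike information criterion,

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1},$$

with Akaike weights $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. We take
$n$ = the number of proportion rows (samples × frequency levels); the
reference analyses never state their $n$, and this choice reproduces their
printed AICc values from their printed log-likelihoods exactly at integer
rounding.

Fit quality is summarised by the theoretical marginal/conditional
$R^2_{GLMM}$ with the logit distribution-specific variance $\pi^2/3$:
marginal $= \sigma_f^2 / (\sigma_f^2 + \sigma_r^2 + \sigma_s^2 + \pi^2/3)$,
conditional adds the random-effect variances to the numerator. Cell
probabilities are reported as estimated marginal means: the fixed-effect
linear predictor averaged on the logit scale over the factorial grid with
equal cell weights, Wald 95% intervals formed on the logit scale, both
inverse-logit transformed (so intervals are asymmetric and never leave
$(0,1)$). Where the design is unbalanced this equal-weight grid averaging is
a documented convention; the reference analyses do not state theirs.

Model adequacy uses simulation-based quantile residuals: simulate `n_sim`
response datasets from the fitted model (unconditionally — random effects
redrawn), take each observation's randomised rank among its simulations
(ties broken uniformly, seeded), and test the residuals against
Uniform(0, 1) with a Kolmogorov–Smirnov test. A well-specified model gives
uniform residuals; overdispersion piles them at the extremes. The reference
uses 10 000 simulations; the test suite scales down to 250, which the
calibration test shows is already accurate at the 5% level.

## The synthetic soundscape: the stated world

The generator (`synth_config()`, `render_soundscape()`) emulates exactly the
statistical structure the two approaches assume:

* **Click trains.** Onsets in trains of 10–30 clicks with independent
  uniform inter-click intervals in [20, 150] ms (echolocation regime:
  ICI > 10 ms, < 0.2 s), separated by 0.4–1.5 s gaps. Buzz-regime clicks
  (ICI ≤ 10 ms) are excluded by definition and by `echolocation_filter()`.
* **Clicks.** Gaussian-spectrum components: a main component at 70 kHz
  (6σ support 52–88 kHz, always present, so every click is "above 48"), a
  mid-band component at 36 kHz (support 27–45 kHz) present when the click is
  "below 48", and a low-band component at 19 kHz (support ≈ 13–25 kHz)
  present when "below 24". The low band sits at 19 kHz so that it survives
  the 15 kHz high-pass of the downsampling chain; at 15 kHz it would
  straddle the filter's −3 dB point and the two approaches would disagree by
  construction. The mid and low components trail the main pulse by 1/8 and
  1/4 of the click duration (default 400 µs), as off-axis low-frequency
  content does; this also prevents peak normalisation from diluting any
  band's amplitude (superposed components cost up to ~9.5 dB of per-band
  SNR).
* **Band flags.** `below48 ~ Bernoulli(p_below48)`, then
  `below24 | below48 ~ Bernoulli(p_below24 / p_below48)`, so the marginal
  probabilities are honoured and `below24 ⇒ below48` holds click by click.
  Environment defaults (lagoon 0.99/0.9999, open 0.86/0.996) are simulation
  truths chosen once — the field recordings behind the reference analyses
  were not deposited, so no spectral statistics exist to copy.
* **Interference.** Snapping-shrimp-like snaps: 120 µs broadband impulses
  (spectral support straddling 48 kHz), Poisson-placed, never within 5 ms of
  a true click so detector specificity is identifiable.
* **Noise and level.** White (default) or pink ambient noise; clicks scaled
  so that peak amplitude over the 15–90 kHz band RMS of the noise equals
  `snr_db` (peak SNR — the quantity an envelope detector responds to). Full
  scale is 1.0. `noise_spectrum = "none"` renders noiseless detector
  fixtures.

**What the generator does not emulate** — and hence what a green test does
not establish: propagation physics (absorption, multipath, Lloyd's mirror),
directional beam patterns and the on-/off-axis spectral continuum, whistles
and burst pulses, vessel noise, non-stationary soundscapes, and clock drift.
Green tests establish that the *pipeline* measures what it claims on data
with the assumed structure, not that real recordings have that structure.

## Numerical and design choices

* **Census criterion.** "Occurrence below a threshold" is visual in the
  reference protocol and never quantified. Our surrogate: within any single
  spectrogram frame covering the click, at least 5 consecutive band bins
  (~1.9 kHz at 192 kHz/512-point frames) must exceed their local per-bin
  noise floors (median level of frames within ±0.5 s, excluding the click)
  by ≥ 6 dB. The naive "any bin exceeds by 6 dB" rule is the extreme order
  statistic of ~10² near-Rayleigh draws and fires on pure noise almost
  surely; the contiguous-run rule captures the vertical stripe an analyst
  actually keys on (measured at SNR 20 dB: true low-band clicks light ≥ 12
  contiguous bins, noise runs stay ≤ 3). The margin (6 dB), lower band edge
  (5 kHz, keeping ambient low-frequency noise out of the judgement) and run
  length are exposed parameters.
* **Census inputs.** In synthetic mode the census consumes ground-truth
  annotations (emulating manual selection), not detector output — matching
  the reference's manual first approach.
* **Downsampling chain.** Causal (forward-only) 4th-order Butterworth
  15 kHz high-pass — zero-phase filtering is not claimed by the reference —
  then a linear-phase Kaiser-windowed-sinc FIR low-pass at the target
  Nyquist (transition band 0.9–1.05 × Nyquist, ~70 dB stopband, passband
  ripple ≪ 0.5 dB, group delay compensated), then keep every k-th sample
  starting at index 0 (deterministic decimation phase). The 15 kHz high-pass
  belongs to the *downsampling* approach only; the census approach sees the
  unfiltered recording. That asymmetry follows the reference protocol and
  limits comparability of the two sets of proportions — deliberately
  retained.
* **Detector.** Envelope = moving-average-smoothed magnitude of the analytic
  signal; threshold is *relative* to each recording's maximum envelope
  (per-recording normalisation, so thresholds transfer across gain
  settings); crossings merged across sub-`merge_gap_ms` gaps; duration
  gates. "Specificity" is operationalised as precision (detections
  overlapping a reference / all detections): true negatives are undefined
  for point events. The optimiser is an exhaustive grid search maximising
  mean(sensitivity + precision) across subsamples with first-in-grid-order
  tie-breaking.
* **Interval filter.** A detection is kept iff its onset-to-onset gap to the
  previous *or* next detection is ≤ 0.2 s ("clicks occur in trains, not
  isolated"; the either-neighbour reading). Single pass on the original
  gaps — no fixpoint iteration, so a pair whose only neighbours were
  removed still survives; this mirrors a one-shot exclusion rule and is
  tested as such.
* **Matching.** Only original-rate detections are buffer-expanded (each by
  its own duration on both sides), because detections in downsampled
  recordings tend to be longer; downsampled detections are used raw. Bins
  are indexed from each sample unit's start; partial trailing bins count.
  Bins present only at the reduced rate (possible false positives there) are
  counted and reported but not used.
* **Sub-minute remainders.** Recordings are fractionated into 60-s units
  plus one trailing remainder (the reference keeps sub-minute samples but
  does not state their alignment; we take the trailing remainder).
* **Degenerate fits.** Complete separation (all responses at a boundary) is
  flagged, never silent; boundary estimated marginal means carry a warning
  rather than being clipped. Exactly-constant responses can break the nested
  random-effect fit's inner iteration; the fit then falls back to a single
  recording-level intercept and records that in its convergence messages.
  Quantile-residual ties are randomised with the run's seed.

## Limitations

The acceptance-level checks run at desk scale: simulations are scaled down
(e.g. 250 rather than 10 000 residual simulations per replicate, minutes of
audio rather than hours) and the headline field probabilities of the
reference analyses are not reproducible — they depend on recordings that
were never deposited. Every number this package reports is computed at run
time from synthetic data with stated parameters; the package's claims are
about the measurement machinery, not about any dolphin population.
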