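Package: pamdown
Title: Evaluating Reduced Sampling Rates for Recording Echolocation Clicks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether broadband odontocete echolocation clicks
    recorded at a 192 kHz sampling rate survive at reduced rates (96 and 48 kHz,
    i.e. Nyquist frequencies of 48 and 24 kHz). Implements two complementary
    approaches on synthetic soundscapes with known ground truth: (i) a per-click
    spectrogram census of spectral occurrence below 24 and 48 kHz, and (ii) a
    downsample-detect-filter-match pipeline (Butterworth high-pass, FIR
    anti-aliasing, decimation, envelope-threshold click detection with
    sensitivity/specificity parameter optimisation, inter-click-interval
    filtering, one-second presence binning and cross-rate bin matching). Both
    feed paired-proportion binomial mixed models with AICc model selection,
    marginal/conditional R-squared, back-transformed estimated marginal means
    and simulation-based quantile-residual diagnostics. Includes a synthetic
    soundscape generator (click trains, snapping-shrimp-like interference,
    ambient noise), WAV and Raven-style selection-table input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
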