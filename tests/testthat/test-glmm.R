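test_that("aicc implements the small-sample correction exactly", {
  # worked examples from the frequency-range model comparison: printed
  # log-likelihoods and parameter counts reproduce the printed AICc values
  # at integer rounding (n = 196 samples x 2 thresholds = 392 rows)
  expect_equal(round(aicc(-1404, 6, 392)), 2820)
  expect_equal(round(aicc(-8435, 3, 392)), 16876)
  # large-n limit: correction vanishes
  expect_equal(aicc(-100, 4, 1e9), -2 * -100 + 2 * 4, tolerance = 1e-6)
  # n <= k + 1 undefined
  expect_error(aicc(-10, 5, 6), "n > k")
  # formula identity against a literal transcription
  for (ll in c(-50.5, -1291.51)) for (k in c(3, 6)) for (n in c(100, 427)) {
    expect_equal(aicc(ll, k, n),
                 -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
})

test_that("akaike_weights normalise relative evidence", {
  w <- akaike_weights(c(2820, 2820 + 14056))
  expect_equal(round(w, 3), c(1, 0))
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  # random triples vs the direct summation formula
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3, 100, 120)
    w <- akaike_weights(a)
    d <- a - min(a)
    expect_equal(w, exp(-d / 2) / sum(exp(-d / 2)), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(akaike_weights(2820), "length")
})

test_that("r2_glmm follows the theoretical (logit) formulation", {
  # hand-set variance components against the closed form
  r2 <- r2_glmm(list(var_fixed = 1, var_random = 2))
  expect_equal(unname(r2["marginal"]), 1 / (3 + pi^2 / 3))
  expect_equal(unname(r2["conditional"]), 3 / (3 + pi^2 / 3))
  # var_random = 0 -> marginal == conditional
  r2b <- r2_glmm(list(var_fixed = 0.7, var_random = 0))
  expect_equal(unname(r2b["marginal"]), unname(r2b["conditional"]))
  # var_fixed = 0 -> marginal = 0
  expect_equal(unname(r2_glmm(list(var_fixed = 0, var_random = 1))["marginal"]), 0)
})

test_that("fit_binomial_glmm recovers known effects and reports structure", {
  set.seed(42)
  d <- simulate_proportions(intercept = 2, effect = -2)
  fit <- fit_binomial_glmm(d, fixed = ~ freq)
  expect_s3_class(fit, "pam_glmm")
  expect_equal(fit$n, nrow(d))
  est <- fit$coefficients$estimate[fit$coefficients$term == "freq48"]
  se <- fit$coefficients$se[fit$coefficients$term == "freq48"]
  # the model codes freq48 relative to freq24, so the contrast is +2
  expect_lt(abs(est - 2), 3 * se)
  expect_gte(fit$r2["conditional"], fit$r2["marginal"])
  expect_equal(fit$aicc, aicc(fit$loglik, fit$k, fit$n))

  # complete separation is flagged, never silent
  sep <- d; sep$numerator <- sep$denominator
  expect_warning(fs <- fit_binomial_glmm(sep, fixed = ~ freq), "separation")
  expect_false(fs$convergence$ok)

  # invalid records rejected
  bad <- d; bad$numerator[1] <- bad$denominator[1] + 1
  expect_error(fit_binomial_glmm(bad, ~ freq), "numerator")
})

test_that("null simulated interaction stays within 3 SE of zero", {
  set.seed(7)
  d <- simulate_proportions(intercept = 1, effect = -1)
  rec_no <- as.integer(sub("r", "", d$recording_id))
  d$environment <- factor(ifelse(rec_no <= 5, "lagoon", "open"))
  # no interaction simulated: freq effect identical in both environments
  fit <- fit_binomial_glmm(d, ~ freq * environment)
  co <- fit$coefficients
  inter <- grepl(":", co$term)
  expect_true(any(inter))
  expect_lt(abs(co$estimate[inter]), 3 * co$se[inter])
})

test_that("model_comparison ranks candidate over null for a real effect", {
  set.seed(9)
  d <- simulate_proportions(intercept = 2, effect = -2)
  fits <- list(candidate = fit_binomial_glmm(d, ~ freq),
               null = fit_binomial_glmm(d, ~ 1))
  tab <- model_comparison(fits)
  expect_equal(tab$model[1], "candidate")
  expect_equal(tab$delta_aicc[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
})

test_that("estimated marginal means back-transform correctly", {
  expect_equal(stats::plogis(0), 0.5)
  expect_equal(round(stats::plogis(4.647), 4), 0.9905)
  set.seed(15)
  d <- simulate_proportions(intercept = 1.5, effect = -1.5)
  fit <- fit_binomial_glmm(d, ~ freq)
  emm <- estimated_marginal_means(fit)
  expect_equal(nrow(emm), 2)
  expect_true(all(emm$prob > 0 & emm$prob < 1))
  expect_true(all(emm$lcl < emm$prob & emm$prob < emm$ucl))
  # cell means near the simulated truths
  expect_lt(abs(emm$prob[emm$freq == "24"] - stats::plogis(0)), 0.12)
  expect_lt(abs(emm$prob[emm$freq == "48"] - stats::plogis(1.5)), 0.05)
  # CI is asymmetric about the point estimate after back-transformation
  off_half <- abs((emm$ucl - emm$prob) - (emm$prob - emm$lcl))
  expect_true(any(off_half > 1e-6))
  expect_error(estimated_marginal_means(fit, by = "environment"), "absent")
})

test_that("residual diagnostics behave under null and overdispersed data", {
  set.seed(22)
  d <- simulate_proportions(n_recordings = 5, samples_per_rec = 10)
  fit <- fit_binomial_glmm(d, ~ freq)
  expect_error(residual_diagnostics(fit, n_sim = 50), "at least 100")

  diag <- residual_diagnostics(fit, n_sim = 250, seed = 1)
  expect_length(diag$residuals, nrow(d))
  expect_true(all(diag$residuals > 0 & diag$residuals < 1))
  # same seed -> same residuals
  diag2 <- residual_diagnostics(fit, n_sim = 250, seed = 1)
  expect_identical(diag$residuals, diag2$residuals)

  # observations at the fitted expectation -> central quantile residuals
  set.seed(55)
  near <- simulate_proportions(n_recordings = 5, samples_per_rec = 10,
                               den = 100, intercept = 0, effect = 0,
                               sd_recording = 0.05, sd_sample = 0.05)
  suppressWarnings(fc <- fit_binomial_glmm(near, ~ 1))
  p_hat <- stats::plogis(fc$coefficients$estimate[1])
  fc$data$numerator <- round(100 * p_hat)
  dg <- residual_diagnostics(fc, n_sim = 400, seed = 2)
  expect_lt(max(abs(dg$residuals - 0.5)), 0.15)

  # overdispersion (beta-binomial, rho = 0.2) is detected
  set.seed(33)
  rejections <- vapply(1:10, function(i) {
    db <- simulate_proportions(n_recordings = 10, samples_per_rec = 10,
                               intercept = 1, effect = -1)
    rho <- 0.2; m <- (1 - rho) / rho
    p <- stats::plogis(1 + (db$freq == "24") * -1)
    pp <- stats::rbeta(nrow(db), p * m, (1 - p) * m)
    db$numerator <- stats::rbinom(nrow(db), db$denominator, pp)
    f <- fit_binomial_glmm(db, ~ freq, random = "(1 | recording_id)")
    residual_diagnostics(f, n_sim = 250, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})
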