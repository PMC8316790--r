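# Paired-proportion binomial mixed models with logit link, AICc model
# selection, Nakagawa marginal/conditional R-squared, back-transformed
# estimated marginal means, and simulation-based quantile-residual
# diagnostics. Estimation delegates to lme4::glmer; model construction,
# contrasts and all derived quantities live here.

#' Fit the paired-proportion binomial GLMM
#'
#' Response: paired proportions `numerator / denominator` per sample unit and
#' frequency threshold, with a binomial error structure and logit link. Fixed
#' effects default to frequency, environment and their interaction; sample
#' pairs are random intercepts nested within recording identities (dropping
#' automatically to a single level when only one recording or a constant
#' environment makes the full structure unidentifiable is the caller's
#' choice via `fixed` / `random`).
#'
#' @param records data.frame with columns `numerator`, `denominator`,
#'   `freq` (factor), `sample_id`, `recording_id`, and `environment` when it
#'   appears in `fixed`
#' @param fixed right-hand-side formula for the fixed effects,
#'   e.g. `~ freq * environment` (default), `~ freq`, or `~ 1` for the null
#'   model
#' @param random random-effects specification; default
#'   `(1 | recording_id / sample_id)` (pairs nested within recordings)
#' @return an object of class `"pam_glmm"`: list with the `lme4` `model`,
#'   `coefficients` (logit scale, with SEs), `varcomp` (random-effect
#'   variances), `loglik`, `k` (parameter count), `n` (observation count),
#'   `aicc`, `r2` (marginal, conditional), and `convergence` diagnostics
#'   (`ok`, `messages`, `singular`, `separation`)
#' @export
fit_binomial_glmm <- function(records, fixed = ~ freq * environment,
                              random = "(1 | recording_id / sample_id)") {
  stopifnot(all(c("numerator", "denominator", "freq", "sample_id",
                  "recording_id") %in% names(records)))
  if (nlevels(droplevels(factor(records$freq))) < 2 &&
      length(attr(stats::terms(fixed), "term.labels")) > 0)
    stop("need at least 2 frequency levels to fit the frequency contrast")
  if (any(records$numerator > records$denominator) ||
      any(records$denominator <= 0))
    stop("invalid proportion records: need 0 <= numerator <= denominator, denominator > 0")
  records <- droplevels(records)
  separation <- all(records$numerator == records$denominator) ||
    all(records$numerator == 0)
  messages <- character(0)
  fit_once <- function(rand) {
    f <- stats::as.formula(paste(
      "cbind(numerator, denominator - numerator) ~",
      paste(deparse(fixed[[2]]), collapse = ""), "+", rand))
    withCallingHandlers(
      lme4::glmer(f, data = records, family = stats::binomial(link = "logit"),
                  control = lme4::glmerControl(
                    calc.derivs = FALSE,
                    # constant responses (e.g. every sample at the boundary)
                    # are legal degenerate inputs here; they are flagged as
                    # separation below instead of erroring out
                    check.response.not.const = "ignore")),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        messages <<- c(messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  fallback <- "(1 | recording_id)"
  model <- if (identical(random, fallback)) fit_once(random) else
    tryCatch(fit_once(random), error = function(e) {
      # degenerate data (e.g. zero response variance) can break the nested
      # structure's PIRLS iteration; drop to the recording-level intercept
      messages <<- c(messages, paste0(
        "nested random effects failed (", conditionMessage(e),
        "); refitted with ", fallback))
      fit_once(fallback)
    })
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- nrow(records)
  vc <- lme4::VarCorr(model)
  varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  fit <- structure(
    list(model = model,
         coefficients = summary_coefficients(model),
         varcomp = varcomp,
         loglik = as.numeric(ll), k = k, n = n,
         aicc = aicc(as.numeric(ll), k, n),
         convergence = list(
           ok = length(model@optinfo$conv$lme4) == 0 && !separation,
           messages = messages,
           singular = lme4::isSingular(model),
           separation = separation),
         data = records, fixed = fixed),
    class = "pam_glmm"
  )
  fit$r2 <- r2_glmm(fit)
  if (separation)
    warning("complete separation: all responses at the same boundary; ",
            "estimates are unreliable")
  fit
}

summary_coefficients <- function(model) {
  co <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  data.frame(term = names(co), estimate = as.numeric(co), se = se,
             z = as.numeric(co) / se, row.names = NULL)
}

#' @export
print.pam_glmm <- function(x, ...) {
  cat("<pam_glmm> binomial(logit), n =", x$n, ", k =", x$k, "\n")
  cat(sprintf("  logLik = %.2f, AICc = %.2f, R2m = %.3f, R2c = %.3f\n",
              x$loglik, x$aicc, x$r2[1], x$r2[2]))
  if (!x$convergence$ok) cat("  ! convergence flagged:",
                             paste(unique(x$convergence$messages), collapse = "; "), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik maximised log-likelihood
#' @param k number of estimated parameters
#' @param n number of observations (proportion rows: samples x frequency
#'   levels)
#' @return the AICc value
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector of at least two finite AICc values
#' @return weights summing to 1
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 2, all(is.finite(aicc_values)))
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Model-comparison table (candidate vs null)
#'
#' @param fits named list of `pam_glmm` fits
#' @return data.frame sorted by AICc with columns `model, df, loglik, aicc,
#'   delta_aicc, weight`
#' @export
model_comparison <- function(fits) {
  stopifnot(length(fits) >= 2)
  tab <- data.frame(
    model = names(fits),
    df = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$aicc)
  tab[order(tab$aicc), ]
}

#' Theoretical marginal and conditional R-squared for a logit-link GLMM
#'
#' Marginal: variance of the fixed-effect linear predictor over
#' (fixed + random + pi^2/3); conditional adds the random-effect variance to
#' the numerator. pi^2/3 is the logit distribution-specific variance.
#'
#' @param fit a `pam_glmm`, or a list with elements `var_fixed` and
#'   `var_random` for direct computation
#' @return named numeric vector `c(marginal = , conditional = )`
#' @export
r2_glmm <- function(fit) {
  if (inherits(fit, "pam_glmm")) {
    X <- stats::model.matrix(fit$model)
    var_fixed <- stats::var(as.numeric(X %*% lme4::fixef(fit$model)))
    var_random <- sum(fit$varcomp)
  } else {
    var_fixed <- fit$var_fixed
    var_random <- fit$var_random
  }
  dist_var <- pi^2 / 3
  denom <- var_fixed + var_random + dist_var
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + var_random) / denom)
}

#' Estimated marginal means on the probability scale
#'
#' For each cell of the requested factors, the fixed-effect linear predictor
#' is averaged on the logit scale over the factorial grid of the remaining
#' model factors (equal cell weights), its Wald 95% CI formed on the logit
#' scale, and both are back-transformed through the inverse logit. CIs are
#' therefore asymmetric about the point estimate in general. Cells fitted at
#' 0 or 1 (separation) are reported with a warning, never silently clipped.
#'
#' @param fit a `pam_glmm`
#' @param by character vector of factor names defining the cells
#'   (default all model factors)
#' @param level confidence level
#' @return data.frame: one row per cell with `prob`, `se_logit`, `lcl`, `ucl`
#' @export
estimated_marginal_means <- function(fit, by = NULL, level = 0.95) {
  stopifnot(inherits(fit, "pam_glmm"))
  mf <- stats::model.frame(fit$model)
  factors <- names(mf)[vapply(mf, is.factor, logical(1))]
  # grouping factors used in random effects are not fixed-effect factors
  factors <- intersect(factors, all.vars(fit$fixed))
  if (is.null(by)) by <- factors
  if (length(by) == 0) stop("model has no fixed-effect factors to average over")
  if (!all(by %in% factors))
    stop("cell factor(s) absent from the model design: ",
         paste(setdiff(by, factors), collapse = ", "))
  grid <- expand.grid(lapply(mf[factors], levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  names(grid) <- factors
  X <- stats::model.matrix(stats::as.formula(paste(
    "~", paste(deparse(fit$fixed[[2]]), collapse = ""))), data = grid)
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  cells <- unique(grid[by])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cells
  out$prob <- NA_real_; out$se_logit <- NA_real_
  out$lcl <- NA_real_; out$ucl <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(grid))
    for (f in by) sel <- sel & grid[[f]] == cells[i, f]
    L <- colMeans(X[sel, , drop = FALSE])
    est <- sum(L * beta)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    out$prob[i] <- stats::plogis(est)
    out$se_logit[i] <- se
    out$lcl[i] <- stats::plogis(est - zq * se)
    out$ucl[i] <- stats::plogis(est + zq * se)
  }
  if (any(out$prob > 1 - 1e-10 | out$prob < 1e-10))
    warning("estimated marginal mean at the 0/1 boundary; ",
            "Wald intervals are unreliable there")
  rownames(out) <- NULL
  out
}

#' Simulation-based quantile-residual diagnostics
#'
#' Simulates `n_sim` response datasets from the fitted model (unconditionally:
#' random effects are redrawn), computes a randomised per-observation
#' quantile residual — the rank of the observed count among its simulated
#' counts, with ties broken uniformly at random — and tests the residuals
#' against the standard uniform with a Kolmogorov-Smirnov test. Residuals
#' from a well-specified model are uniform; overdispersion pushes them
#' towards 0/1.
#'
#' @param fit a `pam_glmm`
#' @param n_sim number of simulated datasets (>= 100; the reference analysis
#'   used 10000)
#' @param seed optional seed for the simulations and tie-breaking
#' @return list with `ks_statistic`, `p_value`, `residuals`
#' @export
residual_diagnostics <- function(fit, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "pam_glmm"))
  if (n_sim < 100) stop("n_sim must be at least 100 for stable residuals")
  with_seed(seed, {
    sims <- stats::simulate(fit$model, nsim = n_sim)
    obs <- fit$data$numerator
    n_obs <- length(obs)
    sim_mat <- matrix(0, nrow = n_obs, ncol = n_sim)
    for (j in seq_len(n_sim)) sim_mat[, j] <- sims[[j]][, 1]
    n_less <- rowSums(sim_mat < obs)
    n_equal <- rowSums(sim_mat == obs)
    u <- (n_less + stats::runif(n_obs) * (n_equal + 1)) / (n_sim + 1)
    ks <- stats::ks.test(u, "punif")
    list(ks_statistic = as.numeric(ks$statistic),
         p_value = ks$p.value,
         residuals = u)
  })
}
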