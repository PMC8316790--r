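# End-to-end orchestration of the synthetic experiment: generate soundscapes
# per environment, run the census approach and the downsample-detect-match
# approach, fit both mixed-model comparisons, and emit the tabular outputs
# (census summary, model comparison, estimated marginal means) plus a
# provenance manifest.

#' Experiment configuration
#'
#' @param environments named list of [synth_config()]s, one per environment
#'   (names must match each config's `environment` field)
#' @param n_recordings recordings per environment (>= 2, for the nested
#'   random effects)
#' @param detector_grid grid for [optimize_params()]; `NULL` skips
#'   optimisation and uses [detector_params()] defaults
#' @param approaches which analyses to run
#' @param out_dir output directory for CSVs (`NULL` = no files written)
#' @param seed master seed; per-recording seeds are derived from it by stable
#'   hashing of the recording id, so adding recordings never perturbs
#'   existing ones
#' @param n_sim_diagnostics simulations for residual diagnostics (0 skips)
#' @return an object of class `"pam_experiment_config"`
#' @export
experiment_config <- function(environments, n_recordings = 2,
                              detector_grid = NULL,
                              approaches = c("census", "downsample"),
                              out_dir = NULL, seed = 1L,
                              n_sim_diagnostics = 0) {
  stopifnot(is.list(environments), length(environments) >= 1,
            n_recordings >= 2)
  approaches <- match.arg(approaches, several.ok = TRUE)
  for (nm in names(environments))
    stopifnot(inherits(environments[[nm]], "synth_config"),
              environments[[nm]]$environment == nm)
  structure(list(environments = environments, n_recordings = n_recordings,
                 detector_grid = detector_grid, approaches = approaches,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_sim_diagnostics = n_sim_diagnostics),
            class = "pam_experiment_config")
}

# Generate all recordings for a config; returns list of
# list(recording, truth).
synthesize_recordings <- function(config) {
  out <- list()
  for (env in names(config$environments)) {
    base_cfg <- config$environments[[env]]
    for (r in seq_len(config$n_recordings)) {
      rec_id <- sprintf("%s_rec%02d", env, r)
      cfg <- base_cfg
      cfg$seed <- derive_seed(config$seed, rec_id)
      sc <- render_soundscape(cfg)
      sc$recording$recording_id <- rec_id
      sc$recording$group_id <- sprintf("%s_grp%02d", env, r)
      out[[rec_id]] <- sc
    }
  }
  out
}

#' Cut 5-s labelled subsamples for detector optimisation
#'
#' One 5-s subsample per selected group, cut around the group's first click
#' train and shipped with its ground-truth selection table. Deterministic
#' under a fixed seed.
#'
#' @param soundscapes list of `list(recording, truth)` (from
#'   [render_soundscape()])
#' @param length_s subsample length in seconds
#' @param n_per_group subsamples per group
#' @param seed optional seed
#' @return list of `list(recording, reference)` ready for [optimize_params()];
#'   recordings shorter than `length_s` are skipped with a warning
#' @export
subsample_for_optimization <- function(soundscapes, length_s = 5,
                                       n_per_group = 1, seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (sc in soundscapes) {
      rec <- sc$recording
      if (rec_duration(rec) < length_s) {
        warning("recording ", rec$recording_id, " shorter than ", length_s,
                " s; skipped")
        next
      }
      clicks <- sc$truth$clicks
      if (nrow(clicks) == 0) next
      for (k in seq_len(n_per_group)) {
        anchor <- clicks$begin_s[sample.int(nrow(clicks), 1)]
        start <- max(0, min(anchor - 0.5, rec_duration(rec) - length_s))
        i0 <- round(start * rec$rate_hz) + 1
        i1 <- min(i0 + round(length_s * rec$rate_hz) - 1, length(rec$samples))
        sub <- recording(rec$samples[i0:i1], rec$rate_hz,
                         recording_id = paste0(rec$recording_id, "_sub", k),
                         environment = rec$environment,
                         group_id = rec$group_id)
        inside <- clicks$begin_s >= start & clicks$end_s <= start + length_s
        ref <- clicks[inside, c("begin_s", "end_s"), drop = FALSE]
        ref$begin_s <- ref$begin_s - start
        ref$end_s <- ref$end_s - start
        if (nrow(ref) == 0) next
        out[[length(out) + 1]] <- list(recording = sub, reference = ref)
      }
    }
    out
  })
}

# Census approach over a list of soundscapes -> proportion records.
run_census_approach <- function(soundscapes, noise_margin_db = 6) {
  counts <- list()
  for (sc in soundscapes) {
    rec <- sc$recording
    clicks <- echolocation_filter(sc$truth$clicks)
    if (nrow(clicks) == 0) next
    spec <- spectrogram(rec)
    clicks <- census_clicks(clicks, spec, noise_margin_db)
    units <- segment_samples(rec)
    for (u in seq_len(nrow(units))) {
      cnt <- census_sample(units[u, , drop = FALSE], clicks)
      cnt$environment <- rec$environment
      cnt$group_id <- rec$group_id
      counts[[length(counts) + 1]] <- cnt
    }
  }
  counts <- do.call(rbind, counts)
  list(counts = counts, proportions = census_to_proportions(counts))
}

# Detection approach over a list of soundscapes -> proportion records.
run_downsample_approach <- function(soundscapes, config) {
  params <- if (!is.null(config$detector_grid)) {
    subs <- subsample_for_optimization(soundscapes, seed = config$seed)
    optimize_params(subs, config$detector_grid)
  } else detector_params()
  rows <- list()
  for (sc in soundscapes)
    rows[[length(rows) + 1]] <- match_recording(sc$recording, params)
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Run the full synthetic experiment
#'
#' Synthesizes recordings, runs the requested approaches, fits the candidate
#' (`~ freq * environment`, or `~ freq` with a single environment) and null
#' mixed models for each approach, and assembles model-comparison and
#' estimated-marginal-mean tables. With `out_dir` set, writes
#' `census_proportions.csv`, `match_proportions.csv`,
#' `model_comparison_<approach>.csv`, `emm_<approach>.csv` and
#' `manifest.csv`. Any stage failure aborts with the stage name; outputs
#' produced before the failure persist.
#'
#' @param config an [experiment_config()]
#' @return list with per-approach results (`proportions`, `fits`,
#'   `comparison`, `emm`, optionally `diagnostics`) and a `manifest`
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "pam_experiment_config"))
  multi_env <- length(config$environments) > 1
  fixed <- if (multi_env) ~ freq * environment else ~ freq
  result <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  soundscapes <- stage("synth", synthesize_recordings(config))

  analyse <- function(records, label) {
    records$freq <- droplevels(records$freq)
    fits <- list(
      candidate = fit_binomial_glmm(records, fixed),
      null = fit_binomial_glmm(records, ~ 1)
    )
    res <- list(
      proportions = records,
      fits = fits,
      comparison = model_comparison(fits),
      emm = estimated_marginal_means(fits$candidate)
    )
    if (config$n_sim_diagnostics > 0)
      res$diagnostics <- residual_diagnostics(
        fits$candidate, n_sim = config$n_sim_diagnostics,
        seed = derive_seed(config$seed, paste0("diag_", label)))
    res
  }

  if ("census" %in% config$approaches) {
    census <- stage("census", run_census_approach(soundscapes))
    result$census <- stage("census_glmm", analyse(census$proportions, "census"))
    result$census$counts <- census$counts
  }
  if ("downsample" %in% config$approaches) {
    match_rec <- stage("downsample", run_downsample_approach(soundscapes, config))
    result$downsample <- stage("downsample_glmm", {
      r <- match_rec
      names(r)[names(r) == "numerator"] <- "numerator" # already canonical
      analyse(r, "downsample")
    })
    result$downsample$detector_params <- attr(match_rec, "params")
  }

  result$manifest <- data.frame(
    key = c("seed", "n_recordings", "environments", "approaches",
            "package_version", "r_version"),
    value = c(config$seed, config$n_recordings,
              paste(names(config$environments), collapse = "+"),
              paste(config$approaches, collapse = "+"),
              as.character(utils::packageVersion("pamdown")),
              paste(R.version$major, R.version$minor, sep = ".")),
    stringsAsFactors = FALSE
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
    if (!is.null(result$census)) {
      wr(result$census$proportions, "census_proportions.csv")
      wr(result$census$comparison, "model_comparison_census.csv")
      wr(result$census$emm, "emm_census.csv")
    }
    if (!is.null(result$downsample)) {
      wr(result$downsample$proportions, "match_proportions.csv")
      wr(result$downsample$comparison, "model_comparison_downsample.csv")
      wr(result$downsample$emm, "emm_downsample.csv")
    }
    wr(result$manifest, "manifest.csv")
  }
  result
}
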