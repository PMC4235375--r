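## Orchestration: seeded end-to-end runs (simulate -> preprocess -> epoch ->
## evaluate -> report) driven by a single configuration, plus a small
## deterministic fixture cohort for fast tests.

#' Simulate and preprocess a cohort, one subject at a time
#'
#' Generates each session, runs both preprocessing chains, epochs the
#' stimulus-locked trials (baseline-corrected) and optionally extracts the
#' continuous block-1 clips, discarding the raw session before the next
#' subject to keep memory flat.
#'
#' @param config a [sim_config()].
#' @param models a [session_models()] list.
#' @param montage a [make_montage()].
#' @param seed master seed.
#' @param keep_continuous also return the continuous clips?
#' @param ica run ICA blink removal (TRUE matches the preprocessing chain;
#'   FALSE is faster for feature-level studies without blink artifacts).
#' @param permute_labels if TRUE, trial labels are randomly permuted per
#'   subject after epoching (null-calibration runs).
#' @return list with `trials` (per-subject `bci_trials`) and optionally
#'   `continuous` (per-subject clip lists).
#' @export
cohort_trials <- function(config = sim_config(), models = session_models(),
                          montage = make_montage(), seed = 1L,
                          keep_continuous = FALSE, ica = TRUE,
                          permute_labels = FALSE) {
  trials <- vector("list", config$n_subjects)
  continuous <- if (keep_continuous) vector("list", config$n_subjects) else NULL
  for (i in seq_len(config$n_subjects)) {
    s_seed <- derive_seed(seed, paste0("subject-", i))
    sess <- simulate_session(config, models, montage,
                             subject = sprintf("s%02d", i), seed = s_seed)
    sess <- preprocess_fnirs(sess)
    sess <- preprocess_eeg(sess, ica = ica, seed = s_seed)
    tr <- baseline_correct(epoch_trials(sess))
    if (permute_labels)
      tr$label <- with_seed(derive_seed(s_seed, "permute"),
                            sample(tr$label))
    trials[[i]] <- tr
    if (keep_continuous) continuous[[i]] <- extract_continuous(sess)
    rm(sess)
  }
  list(trials = trials, continuous = continuous)
}

#' Small deterministic fixture cohort
#'
#' Two subjects, 8 trials per label, 6 fNIRS channels per probe - large
#' enough to exercise every pipeline stage, small enough for fast tests.
#'
#' @param seed master seed.
#' @param n_subjects,trials_per_label,channels_per_probe overrides.
#' @return a [cohort_trials()] bundle (with continuous clips).
#' @export
make_fixtures <- function(seed = 1L, n_subjects = 2L, trials_per_label = 8L,
                          channels_per_probe = 6L) {
  cfg <- sim_config(n_subjects = n_subjects, trials_per_label = trials_per_label)
  mont <- make_montage(channels_per_probe, channels_per_probe, channels_per_probe)
  cohort_trials(cfg, session_models(), mont, seed = seed,
                keep_continuous = TRUE, ica = FALSE)
}

default_experiment_config <- function() {
  list(seed = 1L,
       simulation = list(n_subjects = 4L, trials_per_label = 10L),
       montage = list(n_occipital = 6L, n_left_temporal = 6L,
                      n_right_temporal = 6L),
       effect_scale = 1,
       conditions = c("AUD vs VIS", "VIS vs IDLE"),
       modes = c("subject-dependent"),
       continuous = NULL,
       ica = TRUE,
       pow_band = c(3, 40))
}

#' Run a configured end-to-end experiment
#'
#' Simulates a cohort, preprocesses it, and evaluates the configured
#' conditions in the configured cross-validation modes. The run is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config a configuration list (see `default_experiment_config()` in
#'   the sources for the schema) or the path of a YAML file with the same
#'   structure. Unknown condition names fail validation before any
#'   computation.
#' @param out_dir if non-NULL, the report CSV and a JSON manifest are written
#'   there.
#' @return list with `report` (data.frame of per-condition, per-mode,
#'   per-classifier accuracies), `continuous` (data.frame or NULL) and
#'   `manifest`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_experiment_config()
  for (k in names(base)) if (is.null(config[[k]])) config[[k]] <- base[[k]]
  known <- names(bci_conditions())
  bad <- setdiff(config$conditions, known)
  if (length(bad) > 0)
    stop_param("unknown condition name(s): ", paste(bad, collapse = ", "))
  if (!all(config$modes %in% c("subject-dependent", "subject-independent")))
    stop_param("modes must be subject-dependent and/or subject-independent")
  seed <- as.integer(config$seed)

  cfg <- do.call(sim_config, config$simulation)
  mont <- do.call(make_montage, config$montage)
  models <- session_models(effect_scale = config$effect_scale)
  cohort <- cohort_trials(cfg, models, mont, seed = seed,
                          keep_continuous = !is.null(config$continuous),
                          ica = isTRUE(config$ica))
  pow_par <- pow_params(band = config$pow_band)

  rows <- list()
  for (cname in config$conditions) {
    cond <- bci_conditions()[[cname]]
    if ("subject-dependent" %in% config$modes) {
      for (s in seq_along(cohort$trials)) {
        rep <- run_subject_dependent_cv(cohort$trials[[s]], cond,
                                        seed = derive_seed(seed, paste0("sd-", cname, "-", s)),
                                        pow_par = pow_par)
        rows[[length(rows) + 1L]] <- rep$summary
      }
    }
    if ("subject-independent" %in% config$modes) {
      res <- run_subject_independent_cv(cohort$trials, cond,
                                        seed = derive_seed(seed, paste0("si-", cname)),
                                        pow_par = pow_par)
      rows[[length(rows) + 1L]] <- res$summary
    }
  }
  report <- do.call(rbind, rows)

  cont_report <- NULL
  if (!is.null(config$continuous)) {
    for (cname in config$continuous$conditions %||% "AUD vs VIS") {
      cond <- bci_conditions()[[cname]]
      cr <- run_continuous_evaluation(cohort$continuous, cond,
                                      w_lens = config$continuous$w_lens %||%
                                        c(1, 2, 4, 8, 16),
                                      pow_par = pow_par)
      cr$condition <- cname
      cont_report <- rbind(cont_report, cr)
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion("hybridbci")),
                   seed = seed, config = config,
                   n_subjects = cfg$n_subjects,
                   n_trials = vapply(cohort$trials, function(t)
                     length(t$label), integer(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (!is.null(cont_report))
      utils::write.csv(cont_report, file.path(out_dir, "continuous.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, continuous = cont_report, manifest = manifest)
}
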