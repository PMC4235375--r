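## Continuous (non stimulus-locked) decoding on the block-1 clips: the
## recording of each 60 s clip is segmented into 50 %-overlapping windows,
## band-power features are extracted per window exactly as in the
## onset-locked case, and the fNIRS feature becomes the window mean minus the
## mean of the already elapsed clip data. The ERP classifier is excluded (it
## requires onset locking). Evaluation is leave-one-subject-out only.

#' Extract the continuous block-1 clips from a preprocessed session
#'
#' @param session a preprocessed `bci_session`.
#' @return list of clips, each with `label`, `duration_s`, `hbo`/`hbr`
#'   (channels x seconds, clip-local) and `eeg` (electrodes x samples).
#' @export
extract_continuous <- function(session) {
  stopifnot(inherits(session, "bci_session"))
  if (is.null(session$hb) || is.null(session$eeg_clean))
    stop_param("session must be preprocessed first")
  cont <- session$schedule[session$schedule$segment == "continuous", , drop = FALSE]
  lapply(seq_len(nrow(cont)), function(i) {
    on <- cont$onset_s[i]; dur <- cont$duration_s[i]
    ihb <- window_indices(on, dur, 1)
    iee <- window_indices(on, dur, session$fs_eeg)
    list(label = cont$label[i], duration_s = dur,
         hbo = session$hb$hbo[, ihb$first:(ihb$first + ihb$n - 1L), drop = FALSE],
         hbr = session$hb$hbr[, ihb$first:(ihb$first + ihb$n - 1L), drop = FALSE],
         eeg = session$eeg_clean[, iee$first:(iee$first + iee$n - 1L), drop = FALSE])
  })
}

## 1 Hz sample indices (1-based) covering [start, end) in clip-local time.
hz1_indices <- function(start, end) {
  lo <- ceiling(start - 1e-9)
  hi <- ceiling(end - 1e-9) - 1
  if (hi < lo) integer(0) else (lo:hi) + 1L
}

## Window features of one clip for one window length.
clip_window_features <- function(clip, w_len, fs_eeg = FS_EEG,
                                 pow_par = pow_params()) {
  wins <- segment_windows(clip$duration_s, w_len, clip$label)
  n <- nrow(wins)
  n_ch <- nrow(clip$hbo)
  freqs <- pow_freqs(pow_par)
  hbo <- matrix(NA_real_, n, n_ch)
  hbr <- matrix(NA_real_, n, n_ch)
  pow <- matrix(NA_real_, n, length(freqs) * nrow(clip$eeg))
  for (j in seq_len(n)) {
    idx <- hz1_indices(wins$start_s[j], wins$end_s[j])
    ela <- hz1_indices(0, wins$start_s[j])
    hbo[j, ] <- continuous_fnirs_feature(clip$hbo[, idx, drop = FALSE],
                                         clip$hbo[, ela, drop = FALSE])
    hbr[j, ] <- continuous_fnirs_feature(clip$hbr[, idx, drop = FALSE],
                                         clip$hbr[, ela, drop = FALSE])
    i0 <- round(wins$start_s[j] * fs_eeg) + 1L
    i1 <- min(round(wins$end_s[j] * fs_eeg), ncol(clip$eeg))
    pow[j, ] <- pow_of_matrix(clip$eeg[, i0:i1, drop = FALSE], fs_eeg, pow_par)
  }
  list(hbo = hbo, hbr = hbr, pow = pow, label = wins$label)
}

#' Continuous-mode leave-one-subject-out evaluation
#'
#' @param continuous_list per-subject lists of clips from
#'   [extract_continuous()].
#' @param condition a [condition_spec()]; only clip labels available in
#'   block 1 (AUD, VIS, MIX) can contribute.
#' @param w_lens window lengths (s); lengths exceeding the shortest clip are
#'   skipped with a warning.
#' @param include_erp must stay FALSE: the ERP feature requires stimulus
#'   onsets and is rejected in continuous mode.
#' @param pow_par POW feature parameters.
#' @param shrinkage LDA shrinkage.
#' @return data.frame with one row per window length and classifier:
#'   accuracy, window count per subject, and the chance upper bound for the
#'   pooled window count.
#' @export
run_continuous_evaluation <- function(continuous_list, condition,
                                      w_lens = c(1, 2, 4, 8, 16),
                                      include_erp = FALSE,
                                      pow_par = pow_params(),
                                      shrinkage = 0.5) {
  if (include_erp)
    stop_param("the ERP feature is limited to stimulus onsets and cannot ",
               "be used in continuous mode")
  if (length(continuous_list) < 2L) stop_param("needs >= 2 subjects")
  min_dur <- min(unlist(lapply(continuous_list, function(cl)
    vapply(cl, function(c) c$duration_s, numeric(1)))))
  out <- list()
  for (w in w_lens) {
    if (w > min_dur) {
      warning("window length ", w, " s exceeds a segment; skipped")
      next
    }
    feats <- lapply(continuous_list, function(clips) {
      keep <- vapply(clips, function(c)
        c$label %in% c(condition$class1, condition$class2), logical(1))
      if (!any(keep)) stop_param("no clips with condition labels")
      per <- lapply(clips[keep], clip_window_features, w_len = w,
                    pow_par = pow_par)
      list(hbo = do.call(rbind, lapply(per, `[[`, "hbo")),
           hbr = do.call(rbind, lapply(per, `[[`, "hbr")),
           pow = do.call(rbind, lapply(per, `[[`, "pow")),
           y = factor(ifelse(unlist(lapply(per, `[[`, "label")) %in% condition$class1,
                             condition$class1_name, condition$class2_name),
                      levels = c(condition$class1_name, condition$class2_name)))
    })
    n_sub <- length(feats)
    acc <- matrix(NA_real_, n_sub, 4,
                  dimnames = list(NULL, c("HbO", "HbR", "POW", "META")))
    n_win <- 0L
    for (s in seq_len(n_sub)) {
      train_subj <- setdiff(seq_len(n_sub), s)
      heldout <- max(train_subj)
      core <- setdiff(train_subj, heldout)
      if (length(core) == 0L) core <- train_subj
      fit_on <- function(subjects) {
        X <- list(HbO = do.call(rbind, lapply(feats[subjects], `[[`, "hbo")),
                  HbR = do.call(rbind, lapply(feats[subjects], `[[`, "hbr")),
                  POW = do.call(rbind, lapply(feats[subjects], `[[`, "pow")))
        y <- factor(unlist(lapply(feats[subjects], function(f) as.character(f$y))),
                    levels = levels(feats[[1]]$y))
        lapply(X, function(x) {
          nz <- fit_normalizer(x)
          list(nz = nz, model = train_lda(apply_normalizer(nz, x), y, shrinkage))
        })
      }
      predict_on <- function(models, f) {
        X <- list(HbO = f$hbo, HbR = f$hbr, POW = f$pow)
        probs <- lapply(names(models), function(m)
          predict(models[[m]]$model, apply_normalizer(models[[m]]$nz, X[[m]])))
        names(probs) <- names(models)
        probs
      }
      core_models <- fit_on(core)
      ho_probs <- predict_on(core_models, feats[[heldout]])
      ho_y <- as.character(feats[[heldout]]$y)
      ho_acc <- vapply(ho_probs, function(p)
        mean(colnames(p)[ifelse(p[, 1] >= p[, 2], 1, 2)] == ho_y), numeric(1))
      weights <- estimate_fusion_weights(ho_acc)
      models <- fit_on(train_subj)
      probs <- predict_on(models, feats[[s]])
      y_s <- as.character(feats[[s]]$y)
      for (m in names(probs))
        acc[s, m] <- mean(colnames(probs[[m]])[ifelse(probs[[m]][, 1] >=
                                                      probs[[m]][, 2], 1, 2)] == y_s)
      meta <- fuse_predict(probs, weights)
      acc[s, "META"] <- mean(meta$class == y_s)
      n_win <- n_win + length(y_s)
    }
    out[[length(out) + 1L]] <-
      data.frame(w_len_s = w, classifier = colnames(acc),
                 accuracy = colMeans(acc), n_windows = n_win,
                 chance_upper_pct = chance_upper_bound(n_win),
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
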