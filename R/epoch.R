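## Stimulus-locked epoching and 50 %-overlap windowing of continuous segments.
## Time is seconds from session start; epoch windows are half-open
## [onset, onset + length). Sample i (1-based) sits at time (i - 1) / fs.

## First sample index and length of the window [onset, onset + len) at rate fs.
window_indices <- function(onset, len, fs) {
  first <- ceiling(onset * fs - 1e-9) + 1L
  n <- round(len * fs)
  list(first = as.integer(first), n = as.integer(n))
}

#' Extract stimulus-locked trial epochs from a preprocessed session
#'
#' Requires the haemoglobin block (from [preprocess_fnirs()]) and the cleaned
#' EEG block (from [preprocess_eeg()]). Each stimulus-locked event yields a
#' 10 s haemoglobin epoch at 1 Hz (with prestimulus context for baselines)
#' and a 10 s EEG epoch at 256 Hz with 100 ms prestimulus context. IDLE
#' events are epoched exactly like stimulus events. Events whose epoch would
#' overflow the recording are dropped with a warning so that all epochs have
#' equal length.
#'
#' @param session a preprocessed `bci_session`.
#' @param epoch_s epoch length after onset (s).
#' @param hb_prestim_s haemoglobin prestimulus context (s, at 1 Hz).
#' @param eeg_prestim_s EEG prestimulus context (s).
#' @return object of class `bci_trials`.
#' @export
epoch_trials <- function(session, epoch_s = 10, hb_prestim_s = 2,
                         eeg_prestim_s = 0.1) {
  stopifnot(inherits(session, "bci_session"))
  if (is.null(session$hb) || is.null(session$eeg_clean))
    stop_param("session must be preprocessed before epoching ",
               "(run preprocess_fnirs() and preprocess_eeg())")
  ev <- session$schedule[session$schedule$segment == "trial", , drop = FALSE]
  fs_hb <- 1
  ## epochs are anchored at the onset sample (first sample with time >=
  ## onset); the prestimulus context lies strictly before it, so the
  ## post-onset portion is identically aligned in every trial
  n_hb_pre <- round(hb_prestim_s * fs_hb)
  n_hb_post <- round(epoch_s * fs_hb)
  n_hb <- n_hb_pre + n_hb_post
  n_eeg_pre <- round(eeg_prestim_s * session$fs_eeg)
  n_eeg_post <- round(epoch_s * session$fs_eeg)
  n_eeg <- n_eeg_pre + n_eeg_post
  n_ch <- nrow(session$hb$hbo)
  n_el <- nrow(session$eeg_clean)
  onset_idx <- function(onset, fs) as.integer(ceiling(onset * fs - 1e-9) + 1L)

  keep <- logical(nrow(ev))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      ihb <- onset_idx(ev$onset_s[i], fs_hb)
      iee <- onset_idx(ev$onset_s[i], session$fs_eeg)
      keep[i] <- ihb - n_hb_pre >= 1L && iee - n_eeg_pre >= 1L &&
        ihb + n_hb_post - 1L <= ncol(session$hb$hbo) &&
        iee + n_eeg_post - 1L <= ncol(session$eeg_clean)
    }
    if (any(!keep))
      warning(sum(!keep), " event(s) extend past the recording and were dropped")
  }
  ev <- ev[keep, , drop = FALSE]
  n_tr <- nrow(ev)

  hbo <- array(NA_real_, c(n_tr, n_ch, n_hb))
  hbr <- array(NA_real_, c(n_tr, n_ch, n_hb))
  eeg <- array(NA_real_, c(n_tr, n_el, n_eeg))
  for (i in seq_len(n_tr)) {
    ihb <- onset_idx(ev$onset_s[i], fs_hb)
    iee <- onset_idx(ev$onset_s[i], session$fs_eeg)
    hbo[i, , ] <- session$hb$hbo[, (ihb - n_hb_pre):(ihb + n_hb_post - 1L)]
    hbr[i, , ] <- session$hb$hbr[, (ihb - n_hb_pre):(ihb + n_hb_post - 1L)]
    eeg[i, , ] <- session$eeg_clean[, (iee - n_eeg_pre):(iee + n_eeg_post - 1L)]
  }
  structure(list(subject = session$subject,
                 label = ev$label,
                 hbo = hbo, hbr = hbr, eeg = eeg,
                 n_hb_prestim = n_hb_pre,
                 n_eeg_prestim = n_eeg_pre,
                 fs_hb = fs_hb, fs_eeg = session$fs_eeg,
                 epoch_s = epoch_s,
                 montage = session$montage,
                 baseline_corrected = FALSE),
            class = "bci_trials")
}

#' @export
print.bci_trials <- function(x, ...) {
  cat("Trial set - subject", x$subject, "-", length(x$label), "trials")
  if (length(x$label) > 0) {
    tab <- table(x$label)
    cat(" (", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

## Subset a trial set by trial index (used heavily by cross-validation).
subset_trials <- function(trials, idx) {
  out <- trials
  out$label <- trials$label[idx]
  out$hbo <- trials$hbo[idx, , , drop = FALSE]
  out$hbr <- trials$hbr[idx, , , drop = FALSE]
  out$eeg <- trials$eeg[idx, , , drop = FALSE]
  out
}

#' Segment a continuous labeled recording into 50 %-overlapping windows
#'
#' Window starts are consecutive multiples of `w_len / 2` from the segment
#' onset, giving `ceiling(duration / (w_len / 2))` windows; final windows are
#' truncated at the segment end. All windows carry the segment's label.
#'
#' @param duration_s segment duration (s).
#' @param w_len window length (s).
#' @param label segment label.
#' @param onset_s segment onset in session time (s).
#' @return data.frame of class `bci_windows` with columns
#'   `start_s`, `end_s`, `label` (starts in session time).
#' @export
segment_windows <- function(duration_s, w_len, label = "AUD", onset_s = 0) {
  if (!is.numeric(w_len) || length(w_len) != 1L || w_len <= 0)
    stop_param("w_len must be a positive scalar")
  if (duration_s < w_len / 2)
    stop_param("segment shorter than half a window")
  step <- w_len / 2
  n <- ceiling(duration_s / step - 1e-9)
  start <- (seq_len(n) - 1L) * step
  out <- data.frame(start_s = onset_s + start,
                    end_s = onset_s + pmin(start + w_len, duration_s),
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("bci_windows", "data.frame")
  out
}
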