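## Single-trial feature extraction: haemoglobin slope features (difference of
## means around a centre time t_opt), Welch band-power features, filtered and
## downsampled ERP waveform features, z-normalization with train-only
## statistics, and the continuous-mode fNIRS feature.

## Feature matrices are plain numeric matrices with attributes:
##   "feature_type"  one of HbO, HbR, POW, ERP
##   "labels"        per-trial labels (character)
##   "provenance"    data.frame describing each column
feature_matrix <- function(x, type, labels, provenance) {
  stopifnot(nrow(provenance) == ncol(x), length(labels) == nrow(x))
  if (anyNA(x)) stop_param("feature matrix contains missing values")
  attr(x, "feature_type") <- type
  attr(x, "labels") <- labels
  attr(x, "provenance") <- provenance
  class(x) <- c("bci_features", "matrix", "array")
  x
}

#' @export
print.bci_features <- function(x, ...) {
  cat(sprintf("%s feature matrix: %d trials x %d features\n",
              attr(x, "feature_type"), nrow(x), ncol(x)))
  invisible(x)
}

#' Slope feature grid
#'
#' All admissible `(t_opt, w)` pairs for a 10 s epoch at 1 Hz: the windows
#' `[t_opt - w/2, t_opt]` and `[t_opt, t_opt + w/2]` must lie inside the
#' epoch (samples at 0..9 s).
#'
#' @param t_opt,w candidate centre times and total spans (s).
#' @param epoch_s epoch length (s).
#' @return data.frame with columns `t_opt`, `w`.
#' @export
slope_grid <- function(t_opt = 2:8, w = c(2, 4, 6, 8), epoch_s = 10) {
  g <- expand.grid(t_opt = t_opt, w = w)
  g <- g[g$t_opt - g$w / 2 >= 0 & g$t_opt + g$w / 2 <= epoch_s - 1, ]
  g <- g[order(g$t_opt, g$w), ]
  rownames(g) <- NULL
  g
}

#' Haemoglobin slope feature
#'
#' For each channel, the mean of the samples `t_opt .. t_opt + w/2` minus the
#' mean of the samples `t_opt - w/2 .. t_opt` (integer 1 Hz samples, both
#' endpoints inclusive):
#' `f_c = (2/w) * (sum_{t_opt}^{t_opt+w/2} x_c(t) - sum_{t_opt-w/2}^{t_opt} x_c(t))`.
#'
#' @param trials a `bci_trials` object.
#' @param t_opt centre time (s, post-onset).
#' @param w total span (s; `w/2` must be a whole number of samples).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return feature matrix, trials x channels.
#' @export
slope_feature <- function(trials, t_opt, w, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  arr <- trials[[chromophore]]
  npre <- trials$n_hb_prestim
  n_post <- dim(arr)[3] - npre
  if (w <= 0 || w %% 2 != 0) stop_param("w must be a positive even number of seconds")
  if (t_opt - w / 2 < 0 || t_opt + w / 2 > n_post - 1)
    stop_param("slope window [", t_opt - w / 2, ", ", t_opt + w / 2,
               "] exceeds the ", n_post, " s epoch")
  idx_post <- function(t) npre + t + 1L  # sample at post-onset second t
  up <- idx_post(t_opt):idx_post(t_opt + w / 2)
  dn <- idx_post(t_opt - w / 2):idx_post(t_opt)
  slab_sum <- function(idx) {
    n <- dim(arr)[1] * dim(arr)[2]
    matrix(rowSums(matrix(arr[, , idx, drop = FALSE], n, length(idx))),
           dim(arr)[1], dim(arr)[2])
  }
  f <- (2 / w) * (slab_sum(up) - slab_sum(dn))
  type <- if (chromophore == "hbo") "HbO" else "HbR"
  feature_matrix(f, type, trials$label,
                 data.frame(channel = seq_len(ncol(f)), t_opt = t_opt, w = w))
}

#' Band-power feature parameters
#'
#' @param band frequency band (Hz). With `every_other = TRUE` (default),
#'   every other 0.5 Hz component is kept, i.e. the components at
#'   `band[1], band[1]+1, ..., band[2]` Hz; the default 3-40 Hz band gives 38
#'   components per electrode. `every_other = FALSE` keeps the full 0.5 Hz
#'   grid (used for frequency rankings).
#' @param seg_s,overlap Welch segment length (s) and overlap.
#' @param every_other decimate the 0.5 Hz component grid by two?
#' @export
pow_params <- function(band = c(3, 40), seg_s = 2, overlap = 0.5,
                       every_other = TRUE) {
  if (band[1] <= 0 || band[2] <= band[1]) stop_param("invalid frequency band")
  structure(list(band = band, seg_s = seg_s, overlap = overlap,
                 step = if (every_other) 1 else 0.5),
            class = "bci_pow_params")
}

pow_freqs <- function(p) seq(p$band[1], p$band[2], by = p$step %||% 1)

## Welch PSD of one epoch matrix (electrodes x samples) on the selected grid.
pow_of_matrix <- function(x, fs, p) {
  freqs <- pow_freqs(p)
  vals <- lapply(seq_len(nrow(x)), function(e) {
    ps <- welch_psd(x[e, ], fs, p$seg_s, p$overlap)
    sel <- match(freqs, ps$freq)
    if (anyNA(sel)) stop_param("band outside the resolvable frequency grid")
    ps$psd[sel]
  })
  do.call(c, vals)
}

#' Welch band-power feature
#'
#' Each 10 s post-onset EEG epoch is transformed with Welch's method (2 s
#' Hann segments, 50 % overlap, 0.5 Hz resolution) and every other component
#' in the configured band is concatenated across electrodes (38 values per
#' electrode for the default 3-40 Hz band). Power is used on a linear scale.
#'
#' @param trials a `bci_trials` object.
#' @param params a [pow_params()].
#' @return feature matrix, trials x (components * electrodes).
#' @export
pow_feature <- function(trials, params = pow_params()) {
  npre <- trials$n_eeg_prestim
  n_tr <- length(trials$label)
  n_el <- dim(trials$eeg)[2]
  freqs <- pow_freqs(params)
  out <- matrix(NA_real_, n_tr, length(freqs) * n_el)
  for (i in seq_len(n_tr)) {
    epoch <- matrix(trials$eeg[i, , ], nrow = n_el)[, (npre + 1):dim(trials$eeg)[3],
                                                    drop = FALSE]
    out[i, ] <- pow_of_matrix(epoch, trials$fs_eeg, params)
  }
  prov <- data.frame(electrode = rep(trials$montage$electrodes, each = length(freqs)),
                     freq_hz = rep(freqs, n_el))
  feature_matrix(out, "POW", trials$label, prov)
}

#' ERP feature parameters
#'
#' @param k_med median filter length (samples, odd).
#' @param k_avg moving-average length (samples).
#' @param k_down decimation factor (defaults to `k_avg`).
#' @export
erp_params <- function(k_med = 5L, k_avg = 13L, k_down = k_avg) {
  if (k_med %% 2 == 0) stop_param("k_med must be odd")
  if (k_down < 1) stop_param("k_down must be >= 1")
  structure(list(k_med = as.integer(k_med), k_avg = as.integer(k_avg),
                 k_down = as.integer(k_down)), class = "bci_erp_params")
}

## median filter -> centered moving average (edge replication) -> decimate
erp_filter_chain <- function(v, p) {
  v <- stats::runmed(v, p$k_med, endrule = "median")
  half <- (p$k_avg - 1) %/% 2
  padded <- c(rep(v[1], half), v, rep(v[length(v)], p$k_avg - 1 - half))
  ma <- as.numeric(stats::filter(padded, rep(1 / p$k_avg, p$k_avg), sides = 1))
  ma <- ma[(p$k_avg):(p$k_avg + length(v) - 1)]
  ma[seq(1, length(v), by = p$k_down)]
}

#' Downsampled ERP waveform feature
#'
#' The first second (256 samples) of each baseline-corrected EEG epoch is
#' median filtered (k = 5), smoothed with a 13-sample moving average, and
#' decimated by 13, producing 20 values per electrode.
#'
#' @param trials a `bci_trials` object (baseline-corrected).
#' @param params an [erp_params()].
#' @return feature matrix, trials x (20 * electrodes).
#' @export
erp_feature <- function(trials, params = erp_params()) {
  npre <- trials$n_eeg_prestim
  fs <- trials$fs_eeg
  n_el <- dim(trials$eeg)[2]
  n_tr <- length(trials$label)
  if (dim(trials$eeg)[3] - npre < fs)
    stop_param("epochs shorter than the 1 s ERP window")
  idx <- (npre + 1):(npre + fs)
  per_el <- length(erp_filter_chain(numeric(fs), params))
  out <- matrix(NA_real_, n_tr, per_el * n_el)
  for (i in seq_len(n_tr)) {
    epoch <- matrix(trials$eeg[i, , ], nrow = n_el)[, idx, drop = FALSE]
    out[i, ] <- as.numeric(t(apply(epoch, 1, erp_filter_chain, p = params)))
  }
  prov <- data.frame(electrode = rep(trials$montage$electrodes, each = per_el),
                     time_s = rep((seq_len(per_el) - 1) * params$k_down / fs, n_el))
  feature_matrix(out, "ERP", trials$label, prov)
}

## ---- z-normalization -------------------------------------------------------

#' Fit / apply a z-normalizer
#'
#' Per-feature location and scale are learned from training trials only;
#' zero-variance features are flagged and passed through centered.
#'
#' @param train feature matrix (training trials).
#' @return object of class `bci_normalizer`.
#' @export
fit_normalizer <- function(train) {
  if (nrow(train) < 2L) stop_param("need >= 2 training trials")
  train <- unclass(train)
  mu <- colMeans(train)
  n <- nrow(train)
  sd <- sqrt(pmax(colMeans(train * train) - mu * mu, 0) * n / (n - 1))
  flat <- sd < 1e-12
  sd[flat] <- 1
  structure(list(center = mu, scale = sd, degenerate = flat),
            class = "bci_normalizer")
}

#' @rdname fit_normalizer
#' @param nz a fitted normalizer.
#' @param x feature matrix to transform.
#' @export
apply_normalizer <- function(nz, x) {
  stopifnot(inherits(nz, "bci_normalizer"))
  out <- sweep(sweep(unclass(x), 2, nz$center), 2, nz$scale, "/")
  attributes(out)[c("feature_type", "labels", "provenance")] <-
    attributes(x)[c("feature_type", "labels", "provenance")]
  out
}

## ---- continuous-mode fNIRS feature ----------------------------------------

#' Continuous fNIRS feature: window mean minus elapsed mean
#'
#' For a window of a continuous segment, the per-channel mean of the window
#' samples minus the mean of all samples from the segment start to the window
#' start. The first window of a segment (no elapsed data) returns 0 by
#' convention.
#'
#' @param window `channels x samples` matrix (>= 0 columns; empty windows at
#'   the 1 Hz rate fall back to the last elapsed sample).
#' @param elapsed `channels x samples` matrix of all samples before the window.
#' @return numeric vector, one value per channel.
#' @export
continuous_fnirs_feature <- function(window, elapsed) {
  if (is.null(window)) stop_param("empty window")
  if (ncol(elapsed) == 0L) return(numeric(nrow(window)))
  if (ncol(window) == 0L) window <- elapsed[, ncol(elapsed), drop = FALSE]
  rowMeans(window) - rowMeans(elapsed)
}
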