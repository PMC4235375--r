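## EEG preprocessing: zero-phase FIR band-pass, ICA-based eye-blink removal,
## prestimulus baseline correction. EEG signals are `electrodes x samples`
## matrices at 256 Hz.

## Apply an odd-length linear-phase FIR via FFT convolution and compensate
## the (integer) group delay, giving an exactly zero-phase response. `H` can
## be a precomputed filter spectrum of length `nfft` (shared across channels).
fir_apply <- function(x, h, H = NULL, nfft = NULL) {
  n <- length(x)
  m <- length(h)
  stopifnot(m %% 2 == 1)
  if (is.null(nfft)) nfft <- fft_length(n + m - 1L)
  if (is.null(H)) H <- stats::fft(c(h, numeric(nfft - m)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  delay <- (m - 1L) / 2L
  y[(delay + 1L):(delay + n)]
}

#' Zero-phase FIR band-pass filter
#'
#' A Hamming-windowed linear-phase FIR whose length is
#' `3 * fs / low` taps (rounded to odd), applied by FFT convolution with
#' group-delay compensation so the net response is zero-phase.
#'
#' @param x `electrodes x samples` matrix (or numeric vector).
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz), `0 < low < high < fs/2`.
#' @return filtered signal, same shape; attribute `fir_taps` records the
#'   filter order used.
#' @export
bandpass_filter <- function(x, fs = FS_EEG, low = 0.5, high = 48) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop_param("invalid band: need 0 < low < high < fs/2")
  ntaps <- round(3 * fs / low)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  h <- signal::fir1(ntaps - 1L, c(low, high) / (fs / 2), type = "pass")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  nfft <- fft_length(ncol(x) + ntaps - 1L)
  H <- stats::fft(c(h, numeric(nfft - ntaps)))
  out <- x
  for (r in seq_len(nrow(x)))
    out[r, ] <- fir_apply(x[r, ], h, H = H, nfft = nfft)
  if (vec) out <- drop(out)
  attr(out, "fir_taps") <- ntaps
  out
}

## ---- FastICA (logcosh contrast, symmetric decorrelation) -----------------
## A compact seeded implementation; the installed stack has no ICA package.

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% W
}

fastica_unmix <- function(x, seed = 1L, max_iter = 100L, tol = 1e-5,
                          max_samples = 60000L) {
  d <- nrow(x)
  if (ncol(x) > max_samples) {
    ## contiguous central block (thinning would alias the oscillatory bands)
    from <- (ncol(x) - max_samples) %/% 2L + 1L
    x <- x[, from:(from + max_samples - 1L), drop = FALSE]
  }
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / ncol(xc)
  e <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)  # whitening
  z <- K %*% xc
  W <- with_seed(seed, matrix(stats::rnorm(d * d), d, d))
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    W1 <- sym_decorrelate(g %*% t(z) / ncol(z) - diag(gp) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W %*% K  # unmixing applied to centered data
}

## Low-frequency amplitude envelope: |moving-average-smoothed signal|,
## smoothed again, centered. Emphasises sparse large transients (blinks).
lf_envelope <- function(x, fs) {
  ## the pre-smoothing window is wide enough to suppress alpha-band leakage
  ## (which would otherwise correlate envelopes of non-blink components with
  ## the frontal proxy through shared label-gated amplitude modulation)
  k1 <- max(3L, round(0.3 * fs))
  k2 <- max(3L, round(0.5 * fs))
  env <- fast_ma(abs(fast_ma(x, k1)), k2)
  ## remove trial-scale amplitude modulation (label-gated rhythm gains) so
  ## only blink-scale transients remain
  env - fast_ma(env, round(10 * fs))
}

#' Remove the eye-blink component by ICA
#'
#' Decomposes the multichannel EEG into as many independent components as
#' electrodes (FastICA, logcosh contrast, seeded) and removes exactly one
#' component: among the spiky (leptokurtic, excess kurtosis typical of sparse
#' blink trains) components, the one whose low-frequency amplitude envelope
#' correlates most with the frontal (Fz) blink proxy envelope. If no spiky
#' component reaches the correlation threshold, nothing is removed and a
#' warning is issued - continuous rhythms and background components are
#' near-Gaussian and never qualify, which keeps blink-free recordings a
#' clean no-op. The
#' unmixing matrix is estimated on an 8x-decimated copy of the data (blink
#' energy lives well below the decimated Nyquist) and applied at full rate.
#'
#' @param x `electrodes x samples` matrix with an `"Fz"` row.
#' @param fs sampling rate (Hz).
#' @param seed integer seed for the ICA initialisation.
#' @param threshold minimum absolute envelope correlation for removal.
#' @param min_kurtosis minimum component kurtosis to qualify as blink-like.
#' @return cleaned matrix; attribute `blink_component` is the removed
#'   component index or NA, `blink_correlation` its envelope correlation.
#' @export
remove_blink_ica <- function(x, fs = FS_EEG, seed = 1L, threshold = 0.3,
                             min_kurtosis = 5) {
  if (nrow(x) < 2L) stop_param("ICA needs at least 2 electrodes")
  if (ncol(x) / fs < 60) stop_param("need >= 60 s of data for a stable unmixing")
  if (!"Fz" %in% rownames(x)) stop_param("montage must include Fz for the blink proxy")
  dec <- 8L
  keep <- seq(1L, ncol(x), by = dec)
  xs <- matrix(0, nrow(x), length(keep), dimnames = list(rownames(x), NULL))
  for (r in seq_len(nrow(x)))
    xs[r, ] <- fast_ma(x[r, ], dec)[keep]
  W <- fastica_unmix(xs, seed = seed)
  center <- rowMeans(x)
  S <- W %*% (x - center)
  fs_d <- fs / dec
  proxy <- lf_envelope(xs["Fz", ] - mean(xs["Fz", ]), fs_d)
  Sd <- W %*% (xs - rowMeans(xs))
  scores <- apply(Sd, 1, function(s) abs(stats::cor(lf_envelope(s, fs_d), proxy)))
  scores[is.na(scores)] <- 0
  kurt <- apply(Sd, 1, function(s) mean((s - mean(s))^4) / stats::var(s)^2)
  scores[kurt < min_kurtosis] <- 0
  best <- which.max(scores)
  if (scores[best] < threshold) {
    warning("no blink-like component found (max qualifying envelope ",
            "correlation ", round(max(scores), 2), "); nothing removed")
    attr(x, "blink_component") <- NA_integer_
    attr(x, "blink_correlation") <- scores[best]
    return(x)
  }
  A <- solve(W)
  S[best, ] <- 0
  out <- A %*% S + center
  rownames(out) <- rownames(x)
  attr(out, "blink_component") <- best
  attr(out, "blink_correlation") <- scores[best]
  out
}

#' Prestimulus baseline correction of trial epochs
#'
#' Subtracts the mean of the prestimulus window (100 ms context captured at
#' epoching) from each EEG epoch, per electrode. Idempotent.
#'
#' @param trials a `bci_trials` object with prestimulus EEG context.
#' @return the trial set with baseline-corrected EEG epochs.
#' @export
baseline_correct <- function(trials) {
  stopifnot(inherits(trials, "bci_trials"))
  npre <- trials$n_eeg_prestim
  if (is.null(npre) || npre < 1L)
    stop_param("epochs carry no prestimulus samples; cannot baseline-correct")
  for (i in seq_along(trials$label)) {
    epoch <- matrix(trials$eeg[i, , ], nrow = dim(trials$eeg)[2])
    base <- rowMeans(epoch[, seq_len(npre), drop = FALSE])
    trials$eeg[i, , ] <- epoch - base
  }
  trials$baseline_corrected <- TRUE
  trials
}

#' Full EEG preprocessing chain
#'
#' Band-pass filter then (optionally) ICA blink removal on the continuous
#' recording; baseline correction happens per epoch after [epoch_trials()].
#'
#' @param session a `bci_session`.
#' @param low,high band edges (Hz).
#' @param ica run blink-component removal?
#' @param seed ICA seed.
#' @return the session with a `$eeg_clean` block.
#' @export
preprocess_eeg <- function(session, low = 0.5, high = 48, ica = TRUE,
                           seed = 1L) {
  stopifnot(inherits(session, "bci_session"))
  x <- bandpass_filter(session$eeg, session$fs_eeg, low, high)
  blink <- NA_integer_
  if (ica) {
    x <- remove_blink_ica(x, session$fs_eeg, seed = seed)
    blink <- attr(x, "blink_component")
  }
  rownames(x) <- session$montage$electrodes
  session$eeg_clean <- x
  session$eeg_preproc <- list(band = c(low, high), ica = ica,
                              blink_component = blink,
                              fir_taps = attr(x, "fir_taps"))
  session
}
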