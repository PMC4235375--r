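## Welch power spectral density estimation: Hann-windowed overlapping
## segments, one-sided density. Written against stats::fft because the
## installed signal stack carries no Welch routine.

#' Welch power spectral density
#'
#' Splits the signal into `seg_s`-second Hann-windowed segments with the
#' given overlap, averages their periodograms and returns a one-sided density
#' on the `fs / (seg_s * fs)` frequency grid (0.5 Hz for the 2 s default at
#' 256 Hz). Signals shorter than one segment are analysed as a single
#' zero-padded segment on the same grid.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length (s).
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  L <- round(seg_s * fs)
  n <- length(x)
  step <- max(1L, round(L * (1 - overlap)))
  if (n >= L) {
    starts <- seq(1L, n - L + 1L, by = step)
  } else {
    starts <- 1L
  }
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))
  scale <- fs * sum(w^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:min(s + L - 1L, n)]
    seg <- seg - mean(seg)
    if (length(seg) < L) seg <- c(seg, numeric(L - length(seg)))
    acc <- acc + Mod(stats::fft(seg * w))^2
  }
  pxx <- acc / (length(starts) * scale)
  half <- seq_len(floor(L / 2) + 1L)
  one <- pxx[half]
  if (L > 2) one[2:(length(half) - ifelse(L %% 2 == 0, 1L, 0L))] <-
    2 * one[2:(length(half) - ifelse(L %% 2 == 0, 1L, 0L))]
  list(freq = (half - 1) * fs / L, psd = one)
}
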