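## Optical preprocessing chain: AC normalization, data-driven cardiac pulse
## correction, median filtering + downsampling to 1 Hz, conversion of optical
## density changes to haemoglobin concentration changes via the modified
## Beer-Lambert law (MBLL), and common average referencing. Signals are
## `channels x samples` matrices throughout.

#' Molar extinction coefficients for 690/830 nm
#'
#' Values from the Prahl compilation of haemoglobin spectra, in
#' 1/(mM * cm), log10 (absorbance) convention. Rows: wavelengths
#' (690, 830 nm); columns: HbO, HbR.
#' @export
EXTINCTION_COEFFS <- matrix(c(0.276,   2.05196,
                              0.974,   0.693044),
                            nrow = 2, byrow = TRUE,
                            dimnames = list(c("690", "830"), c("HbO", "HbR")))

#' MBLL parameters
#'
#' @param montage a [make_montage()]; supplies per-channel source-detector
#'   distances.
#' @param dpf differential path-length factors, one per wavelength
#'   (default 6.0 at both).
#' @param extinction 2x2 matrix of extinction coefficients (wavelength x
#'   chromophore), 1/(mM * cm).
#' @return object of class `mbll_params`.
#' @export
mbll_params <- function(montage, dpf = c(6, 6), extinction = EXTINCTION_COEFFS) {
  stopifnot(inherits(montage, "bci_montage"), length(dpf) == 2L)
  if (any(extinction <= 0)) stop_param("extinction coefficients must be positive")
  if (abs(det(extinction)) < 1e-12)
    stop_param("extinction coefficient matrix is singular")
  structure(list(extinction = extinction, dpf = dpf,
                 distance_cm = montage$distance_cm),
            class = "mbll_params")
}

## Per-channel 2x2 system matrix M_c: dOD = M_c %*% c(hbo, hbr) with
## concentrations in uM (hence the 1/1000).
mbll_system <- function(p, channel) {
  (p$extinction * p$dpf * p$distance_cm[channel]) / 1000
}

#' Forward modified Beer-Lambert law
#'
#' Maps haemoglobin concentration changes (uM) to optical density changes at
#' the two wavelengths: `dOD_lambda = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF`.
#'
#' @param hb list with `hbo` and `hbr` `channels x samples` matrices (uM).
#' @param p [mbll_params()].
#' @return list with `wl1`, `wl2` optical-density matrices.
#' @export
mbll_forward <- function(hb, p) {
  stopifnot(inherits(p, "mbll_params"))
  n_ch <- nrow(hb$hbo)
  if (n_ch != length(p$distance_cm))
    stop_param("channel count does not match the MBLL parameters")
  wl1 <- matrix(0, n_ch, ncol(hb$hbo))
  wl2 <- wl1
  for (c in seq_len(n_ch)) {
    M <- mbll_system(p, c)
    wl1[c, ] <- M[1, 1] * hb$hbo[c, ] + M[1, 2] * hb$hbr[c, ]
    wl2[c, ] <- M[2, 1] * hb$hbo[c, ] + M[2, 2] * hb$hbr[c, ]
  }
  list(wl1 = wl1, wl2 = wl2)
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the per-channel 2x2 linear system for (dHbO, dHbR) at every time
#' point; exact algebraic inverse of [mbll_forward()].
#'
#' @param od list with `wl1`, `wl2` optical-density matrices.
#' @param p [mbll_params()].
#' @return list with `hbo`, `hbr` matrices (uM).
#' @export
mbll_convert <- function(od, p) {
  stopifnot(inherits(p, "mbll_params"))
  n_ch <- nrow(od$wl1)
  if (n_ch != length(p$distance_cm))
    stop_param("channel count does not match the MBLL parameters")
  hbo <- matrix(0, n_ch, ncol(od$wl1))
  hbr <- hbo
  for (c in seq_len(n_ch)) {
    Minv <- solve(mbll_system(p, c))
    hbo[c, ] <- Minv[1, 1] * od$wl1[c, ] + Minv[1, 2] * od$wl2[c, ]
    hbr[c, ] <- Minv[2, 1] * od$wl1[c, ] + Minv[2, 2] * od$wl2[c, ]
  }
  list(hbo = hbo, hbr = hbr)
}

#' Normalize AC intensities by the channel mean
#'
#' Each channel is divided by its temporal mean, so every output channel has
#' mean exactly 1. Channels with (near-)zero mean cannot be normalized; they
#' are flagged in the `"bad_channels"` attribute and set to constant 1.
#'
#' @param x `channels x samples` intensity matrix.
#' @return normalized matrix with attribute `bad_channels` (logical).
#' @export
normalize_ac <- function(x) {
  m <- rowMeans(x)
  bad <- abs(m) < 1e-12
  if (any(bad)) {
    warning(sum(bad), " zero-mean channel(s) flagged bad")
    m[bad] <- 1
  }
  out <- x / m
  out[bad, ] <- 1
  attr(out, "bad_channels") <- bad
  out
}

## Locate the dominant cardiac spectral peak of a signal in [lo, hi] Hz on a
## Welch-averaged spectrum (averaging keeps the noise floor flat enough that
## a prominence threshold separates a real pulse from broadband noise).
## Returns NULL when no prominent peak exists.
detect_cardiac_peak <- function(x, fs, lo = 0.7, hi = 2.0, prominence = 5) {
  seg_s <- min(25, floor(length(x) / fs / 4))
  if (seg_s < 5) return(NULL)
  w <- welch_psd(x - mean(x), fs, seg_s = seg_s)
  band <- which(w$freq >= lo & w$freq <= hi)
  if (length(band) < 8L) return(NULL)
  pk <- band[which.max(w$psd[band])]
  if (w$psd[pk] < prominence * stats::median(w$psd[band])) return(NULL)
  w$freq[pk]
}

#' Cardiac pulse correction
#'
#' Data-driven cardiac-band removal: the dominant 0.7-2.0 Hz spectral peak is
#' detected on the mean signal across channels, then a zero-phase
#' second-order Butterworth band-stop (+/- `half_width` Hz around the peak)
#' is applied to every channel. If no prominent cardiac peak is found the
#' input is passed through with a warning.
#'
#' @param x normalized `channels x samples` intensity matrix.
#' @param fs sampling rate (Hz); must exceed twice the cardiac ceiling.
#' @param half_width half width of the stop band (Hz).
#' @return corrected matrix with attribute `cardiac_freq` (NA if undetected).
#' @export
pulse_correct <- function(x, fs = FS_FNIRS, half_width = 0.15) {
  if (fs <= 2 * 2.0) stop_param("sampling rate too low for pulse correction")
  f0 <- detect_cardiac_peak(colMeans(x), fs)
  if (is.null(f0)) {
    warning("no detectable cardiac peak in 0.7-2.0 Hz; pulse correction skipped")
    attr(x, "cardiac_freq") <- NA_real_
    return(x)
  }
  band <- c(max(f0 - half_width, 0.05), min(f0 + half_width, fs / 2 - 0.05))
  bf <- signal::butter(2, band / (fs / 2), type = "stop")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  attr(out, "cardiac_freq") <- f0
  out
}

#' Median filter and downsample to 1 Hz
#'
#' A running median of `filter_s` seconds (rounded to an odd sample count) is
#' applied per channel, then the sample nearest each integer second is kept.
#'
#' @param x `channels x samples` matrix at `fs_in` Hz.
#' @param fs_in input rate (Hz).
#' @param filter_s median filter length (s).
#' @param fs_out output rate (Hz; must be 1).
#' @return `channels x seconds` matrix at 1 Hz.
#' @export
median_downsample <- function(x, fs_in = FS_FNIRS, filter_s = 8, fs_out = 1) {
  stopifnot(fs_out == 1)
  k <- round(filter_s * fs_in)
  if (k %% 2 == 0) k <- k + 1L
  n <- ncol(x)
  if (n < k) stop_param("input shorter than the median filter length")
  filt <- t(apply(x, 1, function(ch) stats::runmed(ch, k, endrule = "median")))
  t_out <- 0:floor((n - 1) / fs_in)
  idx <- pmin(round(t_out * fs_in) + 1L, n)
  filt[, idx, drop = FALSE]
}

#' Intensity to optical density change
#'
#' `dOD = -log10(I / I0)` with `I0 = 1` for mean-normalized intensities.
#' Non-positive samples (possible after artifact injection) are clipped to a
#' small positive value with a warning.
#'
#' @param x mean-normalized intensity matrix.
#' @return optical-density matrix.
#' @export
intensity_to_od <- function(x) {
  bad <- x <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive intensity sample(s) clipped")
    x[bad] <- 1e-6
  }
  -log10(x)
}

#' Common average referencing
#'
#' Subtracts the across-channel mean from each channel at every time point.
#'
#' @param x `channels x samples` matrix (>= 2 channels).
#' @return referenced matrix; column means are exactly 0.
#' @export
common_average_reference <- function(x) {
  if (nrow(x) < 2L) stop_param("CAR undefined for fewer than 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Full fNIRS preprocessing chain
#'
#' normalize -> pulse-correct -> median filter/downsample -> optical density
#' -> MBLL -> common average referencing (jointly over all channels, for HbO
#' and HbR separately). Attaches the 1 Hz haemoglobin block to the session.
#'
#' @param session a `bci_session`.
#' @param params [mbll_params()]; defaults to the session montage with
#'   DPF 6.0.
#' @param pulse apply pulse correction?
#' @param car apply common average referencing?
#' @return the session with a `$hb` block (`hbo`, `hbr`, 1 Hz).
#' @export
preprocess_fnirs <- function(session, params = NULL, pulse = TRUE, car = TRUE) {
  stopifnot(inherits(session, "bci_session"))
  if (is.null(params)) params <- mbll_params(session$montage)
  od <- vector("list", 2)
  bad <- rep(FALSE, nrow(session$fnirs_ac[[1]]))
  for (w in 1:2) {
    x <- normalize_ac(session$fnirs_ac[[w]])
    bad <- bad | attr(x, "bad_channels")
    if (pulse) x <- pulse_correct(x, session$fs_fnirs)
    x <- median_downsample(x, session$fs_fnirs)
    od[[w]] <- intensity_to_od(x)
  }
  hb <- mbll_convert(list(wl1 = od[[1]], wl2 = od[[2]]), params)
  if (car) {
    hb$hbo <- common_average_reference(hb$hbo)
    hb$hbr <- common_average_reference(hb$hbr)
  }
  session$hb <- hb
  session$fnirs_bad_channels <- bad
  session$fnirs_preproc <- list(dpf = params$dpf, pulse = pulse, car = car)
  session
}
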