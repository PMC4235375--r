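# Shared fixtures, built once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small two-subject cohort (8 trials/label, 6 channels/probe), continuous
# clips included, ICA off for speed.
fixture_cohort <- function() memo("cohort", function() make_fixtures(seed = 42))

fixture_trials <- function() fixture_cohort()$trials[[1]]

fixture_montage <- function() make_montage(6, 6, 6)

# Hand-built trial container with planted, perfectly controllable signals.
# n trials alternate between two labels; class-dependent effects are planted
# in the haemoglobin epochs (sigmoidal rise centred at `step_at` seconds,
# mimicking a haemodynamic onset) and in the EEG (a fixed 10 Hz tone + a
# P300-like bump).
synthetic_trials <- function(n = 20, n_ch = 6, labels = c("AUD", "VIS"),
                             hb_effect = 1, eeg_effect = 5, step_at = 5,
                             noise = 0.3, seed = 1, montage = NULL) {
  set.seed(seed)
  if (is.null(montage)) montage <- make_montage(2, 2, 2)
  n_ch <- montage$n_channels
  lab <- rep(labels, length.out = n)
  npre_hb <- 2L; npre_eeg <- 26L
  hbo <- array(rnorm(n * n_ch * 12, 0, noise), c(n, n_ch, 12))
  hbr <- array(rnorm(n * n_ch * 12, 0, noise), c(n, n_ch, 12))
  eeg <- array(rnorm(n * 10 * 2586, 0, noise), c(n, 10, 2586))
  tt <- seq(0, 1 - 1 / 256, by = 1 / 256)
  bump <- exp(-(tt - 0.35)^2 / (2 * 0.06^2))
  tone <- sin(2 * pi * 10 * seq(0, 10 - 1 / 256, by = 1 / 256))
  for (i in seq_len(n)) {
    if (lab[i] == labels[1]) {
      rise <- hb_effect * stats::plogis(0:9 - step_at)
      hbo[i, , (npre_hb + 1):12] <- hbo[i, , (npre_hb + 1):12] +
        rep(rise, each = n_ch)
      hbr[i, , (npre_hb + 1):12] <- hbr[i, , (npre_hb + 1):12] -
        rep(0.3 * rise, each = n_ch)
      eeg[i, 1, (npre_eeg + 1):(npre_eeg + 256)] <-
        eeg[i, 1, (npre_eeg + 1):(npre_eeg + 256)] + eeg_effect * bump
      eeg[i, 4, (npre_eeg + 1):2586] <- eeg[i, 4, (npre_eeg + 1):2586] + eeg_effect * tone
    }
  }
  structure(list(subject = "synth", label = lab, hbo = hbo, hbr = hbr,
                 eeg = eeg, n_hb_prestim = npre_hb, n_eeg_prestim = npre_eeg,
                 fs_hb = 1, fs_eeg = 256, epoch_s = 10, montage = montage,
                 baseline_corrected = TRUE),
            class = "bci_trials")
}

# Minimal EDF writer for import tests (int16, one data-record layout).
write_test_edf <- function(path, signals, fs, labels) {
  ns <- length(signals)
  n_sec <- floor(length(signals[[1]]) / fs[1])
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("patient", 80), con, eos = NULL)
  writeChar(pad("recording", 80), con, eos = NULL)
  writeChar(pad("01.01.20", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(as.character(256 + ns * 256), 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(as.character(n_sec), 8), con, eos = NULL)
  writeChar(pad("1", 8), con, eos = NULL)
  writeChar(pad(as.character(ns), 4), con, eos = NULL)
  pmin_ <- vapply(signals, min, numeric(1)); pmax_ <- vapply(signals, max, numeric(1))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  wfld <- function(vals, w) for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  wfld(labels, 16); wfld(rep("", ns), 80); wfld(rep("uV", ns), 8)
  wfld(format(pmin_, digits = 6), 8); wfld(format(pmax_, digits = 6), 8)
  wfld(rep("-32768", ns), 8); wfld(rep("32767", ns), 8)
  wfld(rep("", ns), 80); wfld(as.character(fs), 8); wfld(rep("", ns), 32)
  for (r in seq_len(n_sec)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][((r - 1) * fs[i] + 1):(r * fs[i])]
      dig <- as.integer(round((seg - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
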