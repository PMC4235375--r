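## Synthetic multimodal session generator. Emulates the signal phenomenology
## of the study design: slow haemodynamic responses at the stimulated probe
## (visual stimuli drive the occipital probe, auditory stimuli the temporal
## probes, mixed stimuli both, idle none), modality-specific event-related
## potentials in the first second after onset, occipital alpha power that is
## suppressed by visual engagement, cardiac pulsation in the optical signal
## and eye blinks in the EEG. All generation is a pure function of
## (config, models, seed).

## Causal convolution via FFT (y has the same length as x).
conv_causal <- function(x, h) {
  n <- length(x)
  nfft <- fft_length(n + length(h) - 1L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Canonical double-gamma haemodynamic response function
#'
#' @param t time grid (s).
#' @param peak_s time-to-peak of the positive lobe (s).
#' @param undershoot_ratio relative amplitude of the late undershoot.
#' @return impulse response sampled at `t` (arbitrary scale).
#' @export
canonical_hrf <- function(t, peak_s = 5.5, undershoot_ratio = 1 / 6) {
  a1 <- peak_s + 1  # gamma shape with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = 16, rate = 1)
  h[t < 0] <- 0
  h
}

#' Haemodynamic forward model parameters
#'
#' Amplitudes are peak oxyhaemoglobin responses (uM) to a reference 12.5 s
#' stimulus at the driven probe. Visual stimuli drive the occipital probe,
#' auditory stimuli the two temporal probes, mixed stimuli both (additively),
#' idle none. The deoxyhaemoglobin response is a scaled, sign-flipped copy.
#'
#' @param vis_amp,aud_amp HbO peak amplitudes (uM).
#' @param hbr_ratio HbR/HbO amplitude ratio (negative).
#' @param peak_s,undershoot_ratio HRF shape, see [canonical_hrf()].
#' @param channel_gain_sd log-normal sd of per-channel, per-subject gain
#'   jitter around the distance-dependent sensitivity profile.
#' @param sens_d_opt,sens_sigma centre (cm) and width of the Gaussian
#'   distance-sensitivity profile: multi-distance channels near `sens_d_opt`
#'   sample the activated cortex best, short/long channels barely at all.
#'   The profile is a fixed property of the montage geometry, hence shared
#'   across subjects.
#' @param subject_sd log-normal sd of per-subject amplitude scaling.
#' @param drift_sd random-walk optical-density drift per sample.
#' @param slow_amp amplitude of slow (0.05-0.12 Hz) vasomotion in OD units.
#' @param white_sd relative white intensity noise.
#' @param pulse_amp relative amplitude of the multiplicative cardiac pulse.
#' @param pulse_freq_range cardiac frequency range (Hz), drawn per subject.
#' @param general_activity if TRUE, auditory and visual stimuli drive all
#'   probes identically (a modality-unspecific "general activation" model,
#'   used as a planted confound).
#' @return object of class `bci_hrf_model`.
#' @export
hrf_model <- function(vis_amp = 0.5, aud_amp = 0.4, hbr_ratio = -0.3,
                      peak_s = 5.5, undershoot_ratio = 1 / 6,
                      channel_gain_sd = 0.3, subject_sd = 0.25,
                      sens_d_opt = 2.3, sens_sigma = 0.15,
                      drift_sd = 6e-5, slow_amp = 2.5e-3, white_sd = 0.005,
                      pulse_amp = 0.008, pulse_freq_range = c(1.0, 1.5),
                      general_activity = FALSE) {
  if (hbr_ratio > 0) stop_param("hbr_ratio must be <= 0 (HbR deflects opposite to HbO)")
  amp <- rbind(
    occipital      = c(AUD = 0, VIS = vis_amp, MIX = vis_amp, IDLE = 0),
    left_temporal  = c(AUD = aud_amp, VIS = 0, MIX = aud_amp, IDLE = 0),
    right_temporal = c(AUD = aud_amp, VIS = 0, MIX = aud_amp, IDLE = 0))
  if (general_activity) {
    act <- mean(c(vis_amp, aud_amp))
    amp <- rbind(occipital      = c(AUD = act, VIS = act, MIX = act, IDLE = 0),
                 left_temporal  = c(AUD = act, VIS = act, MIX = act, IDLE = 0),
                 right_temporal = c(AUD = act, VIS = act, MIX = act, IDLE = 0))
  }
  structure(list(amp = amp, hbr_ratio = hbr_ratio, peak_s = peak_s,
                 undershoot_ratio = undershoot_ratio,
                 channel_gain_sd = channel_gain_sd, subject_sd = subject_sd,
                 sens_d_opt = sens_d_opt, sens_sigma = sens_sigma,
                 drift_sd = drift_sd, slow_amp = slow_amp, white_sd = white_sd,
                 pulse_amp = pulse_amp, pulse_freq_range = pulse_freq_range),
            class = "bci_hrf_model")
}

## HRF kernel normalized so that the response to a reference 12.5 s boxcar
## peaks at exactly 1 (amplitudes are therefore peak concentrations).
hrf_kernel <- function(model, fs, len_s = 32) {
  t <- seq(0, len_s, by = 1 / fs)
  h <- canonical_hrf(t, model$peak_s, model$undershoot_ratio)
  box <- rep(1, round(12.5 * fs))
  ref <- conv_causal(c(box, numeric(length(h))), h)
  h / max(ref)
}

#' Event-related potential templates
#'
#' One 1 s waveform per label and electrode: a small early negativity at
#' ~100 ms and a P300-like positive deflection at ~350 ms (inside the window
#' starting at 312 ms). Visual templates weight occipital electrodes,
#' auditory templates central-midline electrodes; mixed stimuli superpose
#' both; idle has no evoked response. Templates are zero before onset by
#' construction (they are added at the onset sample).
#'
#' @param electrodes electrode names.
#' @param fs sampling rate (Hz).
#' @param p300_amp,n1_amp component amplitudes (uV).
#' @param latency_jitter_sd trial-to-trial latency jitter (s).
#' @param amp_jitter_sd log-normal trial-to-trial amplitude jitter.
#' @param identical_modalities if TRUE the auditory and visual templates are
#'   identical (general-activation confound).
#' @return object of class `bci_erp_template`.
#' @export
erp_template <- function(electrodes = EEG_ELECTRODES, fs = FS_EEG,
                         p300_amp = 8, n1_amp = 4,
                         latency_jitter_sd = 0.02, amp_jitter_sd = 0.15,
                         identical_modalities = FALSE) {
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  shape <- -n1_amp * exp(-(t - 0.10)^2 / (2 * 0.03^2)) +
    p300_amp * exp(-(t - 0.35)^2 / (2 * 0.06^2))
  wgt <- function(named) {
    w <- rep(0.2, length(electrodes)); names(w) <- electrodes
    w[names(named)] <- named
    w
  }
  w_vis <- wgt(c(Oz = 1, O1 = 0.9, O2 = 0.9, Pz = 0.6))
  w_aud <- wgt(c(Cz = 1, Fz = 0.9, Pz = 0.7))
  if (identical_modalities) w_vis <- w_aud <- wgt(c(Cz = 0.9, Fz = 0.8, Pz = 0.65,
                                                    Oz = 0.6, O1 = 0.55, O2 = 0.55))
  waves <- list(AUD = outer(w_aud, shape),
                VIS = outer(w_vis, shape),
                MIX = outer(pmin(w_aud + w_vis, 1.4), shape),
                IDLE = outer(0 * w_aud, shape))
  structure(list(waveforms = waves, fs = fs, duration_s = 1,
                 latency_jitter_sd = latency_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd, electrodes = electrodes),
            class = "bci_erp_template")
}

#' Oscillatory EEG background model
#'
#' A 1/f background plus narrow-band alpha (9.5 Hz) and beta (18.5 Hz)
#' generators whose amplitudes are gated by the stimulus label: occipital
#' alpha is suppressed during visual engagement (VIS/MIX) and elevated during
#' AUD and IDLE. Eye blinks arrive as a Poisson process with a
#' frontally-weighted biphasic waveform.
#'
#' @param background_sd 1/f background amplitude (uV rms).
#' @param white_sd sensor white-noise amplitude (uV rms).
#' @param alpha_freq,beta_freq generator centre frequencies (Hz).
#' @param alpha_amp,beta_amp generator amplitudes (uV rms at weight 1).
#' @param alpha_gain,beta_gain named per-label relative gains.
#' @param rest_gain gain outside stimulus intervals.
#' @param blink_rate blinks per second.
#' @param blink_amp blink amplitude at Fz (uV).
#' @param enforce_ordering assert the occipital alpha ordering
#'   AUD >= IDLE > VIS (disable for confound models).
#' @return object of class `bci_osc_model`.
#' @export
oscillatory_model <- function(background_sd = 6, white_sd = 1.5,
                              alpha_freq = 9.5, beta_freq = 18.5,
                              alpha_amp = 5, beta_amp = 2,
                              alpha_gain = c(AUD = 1.0, VIS = 0.35,
                                             MIX = 0.35, IDLE = 0.9),
                              beta_gain = c(AUD = 1.0, VIS = 0.6,
                                            MIX = 0.6, IDLE = 0.75),
                              rest_gain = 0.9,
                              blink_rate = 0.15, blink_amp = 100,
                              enforce_ordering = TRUE) {
  if (enforce_ordering &&
      !(alpha_gain["AUD"] >= alpha_gain["IDLE"] &&
        alpha_gain["IDLE"] > alpha_gain["VIS"]))
    stop_param("occipital alpha gains must satisfy AUD >= IDLE > VIS")
  structure(list(background_sd = background_sd, white_sd = white_sd,
                 alpha_freq = alpha_freq, beta_freq = beta_freq,
                 alpha_amp = alpha_amp, beta_amp = beta_amp,
                 alpha_gain = alpha_gain, beta_gain = beta_gain,
                 rest_gain = rest_gain,
                 blink_rate = blink_rate, blink_amp = blink_amp),
            class = "bci_osc_model")
}

## ---- fNIRS simulation -----------------------------------------------------

#' Simulate two-wavelength fNIRS AC intensities for a schedule
#'
#' Label-gated boxcars are convolved with the canonical HRF per probe,
#' scaled by per-channel gains, converted to optical densities through the
#' forward MBLL and to intensities `I = I0 * 10^(-dOD)` with a multiplicative
#' cardiac pulse, optical drift and white noise.
#'
#' @param schedule a [event_schedule()].
#' @param hrf a [hrf_model()].
#' @param montage a [make_montage()].
#' @param seed integer seed.
#' @param subject_scale per-subject amplitude factor.
#' @param pulse_freq cardiac frequency (Hz); drawn from the model range if NULL.
#' @param pad_s seconds of signal simulated past the last event.
#' @return list with `wl1`, `wl2` intensity matrices (channels x samples,
#'   19.5 Hz).
#' @export
simulate_fnirs <- function(schedule, hrf, montage, seed = 1L,
                           subject_scale = 1, pulse_freq = NULL, pad_s = 15) {
  stopifnot(inherits(hrf, "bci_hrf_model"), inherits(montage, "bci_montage"))
  for (pr in montage$probes)
    if (montage$probe_channels[pr] < 1L) stop_param("empty probe: ", pr)
  fs <- FS_FNIRS
  span <- if (nrow(schedule) > 0) max(schedule$onset_s + schedule$duration_s) else 60
  n <- ceiling((span + pad_s) * fs)
  tt <- (seq_len(n) - 1) / fs
  kern <- hrf_kernel(hrf, fs)

  ## probe-level concentration responses
  probe_sig <- matrix(0, length(montage$probes), n,
                      dimnames = list(montage$probes, NULL))
  for (pr in montage$probes) {
    drive <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      a <- hrf$amp[pr, schedule$label[i]]
      if (a == 0) next
      i0 <- window_indices(schedule$onset_s[i], schedule$duration_s[i], fs)
      drive[i0$first:min(i0$first + i0$n - 1L, n)] <-
        drive[i0$first:min(i0$first + i0$n - 1L, n)] + a
    }
    probe_sig[pr, ] <- conv_causal(drive, kern)
  }

  with_seed(derive_seed(seed, "fnirs"), {
    n_ch <- montage$n_channels
    ## Focal, distance-dependent sensitivity: overlapping multi-distance
    ## channels sample the activated cortex unevenly - channels near the
    ## optimal separation see most of the response, short/long channels
    ## little. The profile is fixed montage geometry (shared across
    ## subjects); per-subject coupling jitter comes on top. This keeps the
    ## probe-mean response (and hence the CAR crosstalk onto undriven
    ## probes) well below the best channel's response.
    sens <- exp(-((montage$distance_cm - hrf$sens_d_opt) / hrf$sens_sigma)^2)
    gain <- sens * exp(stats::rnorm(n_ch, 0, hrf$channel_gain_sd)) * subject_scale
    hbo <- probe_sig[montage$channel_probe, , drop = FALSE] * gain
    hbr <- hrf$hbr_ratio * hbo
    od <- mbll_forward(list(hbo = hbo, hbr = hbr), mbll_params(montage))
    if (is.null(pulse_freq))
      pulse_freq <- stats::runif(1, hrf$pulse_freq_range[1], hrf$pulse_freq_range[2])
    out <- vector("list", 2)
    names(out) <- c("wl1", "wl2")
    clipped <- 0L
    for (w in 1:2) {
      sig <- od[[w]]
      if (hrf$drift_sd > 0)
        sig <- sig + t(apply(matrix(stats::rnorm(n_ch * n, 0, hrf$drift_sd),
                                    n_ch, n), 1, cumsum))
      if (hrf$slow_amp > 0) {
        f_slow <- stats::runif(n_ch, 0.05, 0.12)
        ph <- stats::runif(n_ch, 0, 2 * pi)
        a_slow <- hrf$slow_amp * stats::runif(n_ch, 0.5, 1.5)
        sig <- sig + a_slow * sin(outer(2 * pi * f_slow, tt) + ph)
      }
      I0 <- exp(stats::rnorm(n_ch, 0, 0.3))
      ph_p <- stats::runif(n_ch, 0, 2 * pi)
      I <- I0 * 10^(-sig)
      if (hrf$pulse_amp > 0)
        I <- I * (1 + hrf$pulse_amp * sin(outer(rep(2 * pi * pulse_freq, n_ch), tt) + ph_p))
      if (hrf$white_sd > 0)
        I <- I + I0 * matrix(stats::rnorm(n_ch * n, 0, hrf$white_sd), n_ch, n)
      neg <- I <= 0
      if (any(neg)) {
        clipped <- clipped + sum(neg)
        I[neg] <- 1e-6
      }
      out[[w]] <- I
    }
    if (clipped > 0L)
      warning(clipped, " negative intensity sample(s) clipped")
    attr(out, "channel_gain") <- gain  # realized gains, for recovery oracles
    out
  })
}

## ---- EEG simulation -------------------------------------------------------

## Spectrally shaped Gaussian noise, unit rms. Generated at the next
## power-of-two length (fast FFT) and truncated.
shaped_noise <- function(n, fs, shape_fun) {
  m <- fft_length(n)
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  y <- Re(stats::fft(spec * shape_fun(abs(f)), inverse = TRUE))[seq_len(n)]
  y / stats::sd(y)
}

## Band-limited Gaussian noise centred at f0 (Hz) with bandwidth bw, unit rms.
narrowband_noise <- function(n, fs, f0, bw = 0.5) {
  shaped_noise(n, fs, function(f) exp(-(f - f0)^2 / (2 * bw^2)))
}

## 1/f-shaped background noise, unit rms.
pink_noise <- function(n, fs, floor_hz = 0.5) {
  shaped_noise(n, fs, function(f) {
    s <- 1 / sqrt(pmax(f, floor_hz))
    s[f == 0] <- 0
    s
  })
}

## Smoothed label-gain time course over the schedule.
gain_timecourse <- function(schedule, gains, rest_gain, n, fs) {
  g <- rep(rest_gain, n)
  for (i in seq_len(nrow(schedule))) {
    i0 <- window_indices(schedule$onset_s[i], schedule$duration_s[i], fs)
    g[i0$first:min(i0$first + i0$n - 1L, n)] <- gains[schedule$label[i]]
  }
  fast_ma(g, round(fs))  # 1 s ramp
}

#' Simulate multichannel EEG for a schedule
#'
#' Signal = 1/f background + label-gated narrow-band alpha/beta generators +
#' evoked-response templates at each stimulus onset + Poisson-timed blinks +
#' sensor noise. Seeded and reproducible.
#'
#' @param schedule a [event_schedule()].
#' @param erp an [erp_template()].
#' @param osc an [oscillatory_model()].
#' @param montage a [make_montage()].
#' @param seed integer seed.
#' @param subject_scale per-subject scaling of evoked and oscillatory effects.
#' @param pad_s seconds of signal simulated past the last event.
#' @return `electrodes x samples` matrix (uV, 256 Hz).
#' @export
simulate_eeg <- function(schedule, erp, osc, montage, seed = 1L,
                         subject_scale = 1, pad_s = 5) {
  stopifnot(inherits(erp, "bci_erp_template"), inherits(osc, "bci_osc_model"))
  if (!all(unique(schedule$label) %in% names(erp$waveforms)))
    stop_param("ERP templates missing for some schedule labels")
  if (nrow(schedule) > 0 && erp$duration_s > min(schedule$duration_s))
    stop_param("ERP template longer than the shortest stimulus")
  fs <- FS_EEG
  el <- montage$electrodes
  n_el <- length(el)
  span <- if (nrow(schedule) > 0) max(schedule$onset_s + schedule$duration_s) else 60
  n <- ceiling((span + pad_s) * fs)

  wgt <- function(named, default) {
    w <- rep(default, n_el); names(w) <- el
    w[names(named)[names(named) %in% el]] <- named[names(named) %in% el]
    w
  }
  w_alpha <- wgt(c(Oz = 1, O1 = 0.9, O2 = 0.9, Pz = 0.6), 0.15)
  w_beta  <- wgt(c(Cz = 0.8, Fz = 0.7, Pz = 0.6), 0.3)
  w_blink <- wgt(c(Fz = 1, Cz = 0.5, Pz = 0.25, FT7 = 0.3, FT8 = 0.3,
                   TP7 = 0.15, TP8 = 0.15, Oz = 0.1, O1 = 0.1, O2 = 0.1), 0.1)

  with_seed(derive_seed(seed, "eeg"), {
    sig <- matrix(0, n_el, n, dimnames = list(el, NULL))
    for (e in seq_len(n_el))
      sig[e, ] <- osc$background_sd * pink_noise(n, fs)
    ## oscillatory generators
    if (osc$alpha_amp > 0) {
      carrier <- narrowband_noise(n, fs, osc$alpha_freq)
      g <- gain_timecourse(schedule, osc$alpha_gain, osc$rest_gain, n, fs)
      sig <- sig + (subject_scale * osc$alpha_amp * w_alpha) %o% (g * carrier)
    }
    if (osc$beta_amp > 0) {
      carrier <- narrowband_noise(n, fs, osc$beta_freq)
      g <- gain_timecourse(schedule, osc$beta_gain, osc$rest_gain, n, fs)
      sig <- sig + (subject_scale * osc$beta_amp * w_beta) %o% (g * carrier)
    }
    ## evoked responses at each onset
    L <- ncol(erp$waveforms[[1]])
    for (i in seq_len(nrow(schedule))) {
      wave <- erp$waveforms[[schedule$label[i]]]
      if (all(wave == 0)) next
      jit <- round(stats::rnorm(1, 0, erp$latency_jitter_sd) * fs)
      amp <- exp(stats::rnorm(1, 0, erp$amp_jitter_sd)) * subject_scale
      i0 <- window_indices(schedule$onset_s[i], erp$duration_s, fs)$first + jit
      if (i0 < 1L || i0 + L - 1L > n) next
      sig[, i0:(i0 + L - 1L)] <- sig[, i0:(i0 + L - 1L)] + amp * wave[el, ]
    }
    ## blinks
    if (osc$blink_rate > 0) {
      n_blink <- stats::rpois(1, osc$blink_rate * n / fs)
      if (n_blink > 0) {
        Lb <- round(0.35 * fs)
        bshape <- sin(pi * seq(0, 1, length.out = Lb))^2
        times <- sort(stats::runif(n_blink, 0, n / fs - 0.4))
        for (tb in times) {
          i0 <- round(tb * fs) + 1L
          a <- osc$blink_amp * exp(stats::rnorm(1, 0, 0.2))
          sig[, i0:(i0 + Lb - 1L)] <- sig[, i0:(i0 + Lb - 1L)] +
            (a * w_blink) %o% bshape
        }
      }
    }
    if (osc$white_sd > 0)
      sig <- sig + matrix(stats::rnorm(n_el * n, 0, osc$white_sd), n_el, n)
    sig
  })
}

## ---- Session and cohort ---------------------------------------------------

#' Default generative models for a session
#'
#' `effect_scale` scales every label-dependent effect: haemodynamic
#' amplitudes, evoked-response amplitudes, and the deviation of the
#' oscillatory label gains from their mean. `effect_scale = 0` gives a null
#' generator with no class information.
#'
#' @param effect_scale non-negative scalar.
#' @param general_activity build the modality-unspecific confound generator
#'   (identical auditory/visual effects everywhere).
#' @return list with `hrf`, `erp`, `osc` model objects.
#' @export
session_models <- function(effect_scale = 1, general_activity = FALSE) {
  hrf <- hrf_model(vis_amp = 0.5 * effect_scale, aud_amp = 0.4 * effect_scale,
                   general_activity = general_activity)
  erp <- erp_template(p300_amp = 8 * effect_scale, n1_amp = 4 * effect_scale,
                      identical_modalities = general_activity)
  shrink <- function(g) {
    out <- mean(g) + effect_scale * (g - mean(g))
    names(out) <- names(g)
    out
  }
  ag <- shrink(c(AUD = 1.0, VIS = 0.35, MIX = 0.35, IDLE = 0.9))
  bg <- shrink(c(AUD = 1.0, VIS = 0.6, MIX = 0.6, IDLE = 0.75))
  if (general_activity) {
    ag[c("AUD", "VIS", "MIX")] <- 0.5
    bg[c("AUD", "VIS", "MIX")] <- 0.65
  }
  osc <- oscillatory_model(alpha_gain = ag, beta_gain = bg,
                           enforce_ordering = FALSE)
  list(hrf = hrf, erp = erp, osc = osc)
}

#' Simulate one complete session
#'
#' @param config a [sim_config()].
#' @param models a [session_models()] list.
#' @param montage a [make_montage()].
#' @param subject subject id.
#' @param seed integer seed; subject-level random effects (amplitude scaling,
#'   cardiac frequency) are drawn from it.
#' @return a `bci_session`.
#' @export
simulate_session <- function(config = sim_config(), models = session_models(),
                             montage = make_montage(), subject = "s01",
                             seed = 1L) {
  schedule <- generate_schedule(config, seed)
  fx <- with_seed(derive_seed(seed, "subject-effects"), {
    list(scale_f = exp(stats::rnorm(1, 0, models$hrf$subject_sd)),
         scale_e = exp(stats::rnorm(1, 0, 0.15)),
         pulse = stats::runif(1, models$hrf$pulse_freq_range[1],
                              models$hrf$pulse_freq_range[2]))
  })
  fnirs <- simulate_fnirs(schedule, models$hrf, montage, seed = seed,
                          subject_scale = fx$scale_f, pulse_freq = fx$pulse)
  eeg <- simulate_eeg(schedule, models$erp, models$osc, montage, seed = seed,
                      subject_scale = fx$scale_e)
  new_session(subject, fnirs, eeg, schedule, montage,
              provenance = list(seed = seed, generator = "hybridbci-sim-1",
                                subject_effects = fx))
}

#' Generate a cohort of sessions
#'
#' Per-subject seeds are derived deterministically from the master seed.
#' Memory note: a full-length session is tens of MB; for large cohorts
#' prefer [cohort_trials()] which processes subjects one at a time.
#'
#' @param config a [sim_config()].
#' @param models a [session_models()] list.
#' @param montage a [make_montage()].
#' @param seed master seed.
#' @return list of `bci_session`.
#' @export
generate_cohort <- function(config = sim_config(), models = session_models(),
                            montage = make_montage(), seed = 1L) {
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_session(config, models, montage,
                     subject = sprintf("s%02d", i),
                     seed = derive_seed(seed, paste0("subject-", i)))
  })
}
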