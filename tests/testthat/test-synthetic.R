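# Synthetic session generator: schedules, fNIRS and EEG phenomenology,
# determinism.

test_that("default schedules have 30 trials per label within stated bounds", {
  sch <- generate_schedule(sim_config(), seed = 7)
  tr <- sch[sch$segment == "trial", ]
  expect_equal(as.integer(table(tr$label)), rep(30L, 4))
  expect_true(all(tr$duration_s >= 10 & tr$duration_s <= 15))
  gaps <- diff(tr$onset_s) - tr$duration_s[-nrow(tr)]
  expect_true(all(gaps >= 15 - 1e-9))   # rest periods at least 15 s
  # block 1: three fixed 60 s clips with 20 s gaps
  b1 <- sch[sch$segment == "continuous", ]
  expect_equal(b1$label, c("AUD", "VIS", "MIX"))
  expect_equal(b1$onset_s, c(0, 80, 160))
  expect_equal(b1$duration_s, rep(60, 3))
})

test_that("no two consecutive stimuli share a label within a block", {
  for (seed in 1:5) {
    sch <- generate_schedule(sim_config(trials_per_label = 12), seed = seed)
    tr <- sch[sch$segment == "trial", ]
    for (b in unique(tr$block)) {
      l <- tr$label[tr$block == b]
      expect_true(all(l[-1] != l[-length(l)]), info = paste("seed", seed))
    }
  }
})

test_that("schedules are a pure function of (config, seed)", {
  expect_identical(generate_schedule(sim_config(), 11),
                   generate_schedule(sim_config(), 11))
  expect_false(identical(generate_schedule(sim_config(), 11),
                         generate_schedule(sim_config(), 12)))
})

test_that("unsatisfiable no-repeat constraints raise a scheduling error", {
  # one label only: any two consecutive trials must repeat
  counts <- c(AUD = 5L)
  expect_error(with_seed(1, hybridbci:::randomize_labels(counts, max_tries = 50)),
               "constraint")
})

test_that("noise-free fNIRS reproduces the configured amplitude at the HRF peak", {
  mont <- make_montage(3, 3, 3)
  sch <- event_schedule(30, 12.5, "VIS", 2)
  hrf <- hrf_model(vis_amp = 0.5, drift_sd = 0, slow_amp = 0, white_sd = 0,
                   pulse_amp = 0, channel_gain_sd = 0)
  ac <- simulate_fnirs(sch, hrf, mont, seed = 4)
  gain <- attr(ac, "channel_gain")
  # independent convolution oracle at 19.5 Hz
  fs <- 19.5
  kern <- hybridbci:::hrf_kernel(hrf, fs)
  drive <- numeric(ncol(ac$wl1))
  i0 <- hybridbci:::window_indices(30, 12.5, fs)
  drive[i0$first:(i0$first + i0$n - 1)] <- 0.5
  expected <- hybridbci:::conv_causal(drive, kern)
  # recover concentrations exactly: noise-free baseline intensity is I0
  od <- list(wl1 = -log10(ac$wl1 / ac$wl1[, 1]),
             wl2 = -log10(ac$wl2 / ac$wl2[, 1]))
  hb <- mbll_convert(od, mbll_params(mont))
  occ <- hybridbci:::probe_channels(mont, "occipital")[1]
  expect_equal(max(hb$hbo[occ, ]), gain[occ] * max(expected), tolerance = 1e-6)
  expect_equal(which.max(hb$hbo[occ, ]), which.max(expected))
  # HbR is the scaled, sign-flipped copy
  expect_equal(hb$hbr[occ, ], -0.3 * hb$hbo[occ, ], tolerance = 1e-6)
})

test_that("IDLE-only schedules produce no occipital deflection beyond noise", {
  mont <- make_montage(3, 3, 3)
  on <- seq(20, 500, by = 35)
  sch <- event_schedule(on, rep(12, length(on)), rep("IDLE", length(on)),
                        rep(2, length(on)))
  ac <- simulate_fnirs(sch, hrf_model(), mont, seed = 8)
  od <- -log10(ac$wl2 / rowMeans(ac$wl2))
  # trial-averaged deflection around onsets vs baseline spread
  fs <- 19.5
  win <- round(5.5 * fs)
  defl <- mean(vapply(on, function(o) {
    i <- round(o * fs)
    mean(od[1, (i + win):(i + win + 20)]) - mean(od[1, (i - 20):i])
  }, numeric(1)))
  expect_lt(abs(defl), 3 * 2.5e-3)  # within the slow-noise scale
})

test_that("fNIRS simulation is deterministic given the seed", {
  mont <- make_montage(2, 2, 2)
  sch <- event_schedule(c(10, 40), c(12, 12), c("AUD", "VIS"), c(2, 2))
  a <- simulate_fnirs(sch, hrf_model(), mont, seed = 3)
  b <- simulate_fnirs(sch, hrf_model(), mont, seed = 3)
  expect_identical(a, b)
})

test_that("noise-free, blink-free EEG contains exactly the injected templates", {
  mont <- make_montage(2, 2, 2)
  sch <- event_schedule(c(10, 40), c(12, 12), c("VIS", "VIS"), c(2, 2))
  erp <- erp_template(latency_jitter_sd = 0, amp_jitter_sd = 0)
  osc <- oscillatory_model(background_sd = 0, white_sd = 0, alpha_amp = 0,
                           beta_amp = 0, blink_rate = 0)
  eeg <- simulate_eeg(sch, erp, osc, mont, seed = 2)
  i0 <- hybridbci:::window_indices(10, 1, 256)
  epoch <- eeg[, i0$first:(i0$first + 255)]
  expect_equal(unname(epoch), unname(erp$waveforms$VIS), tolerance = 1e-10)
  # zero outside any stimulus (templates are zero before onset)
  expect_equal(max(abs(eeg[, 1:(9 * 256)])), 0)
})

test_that("occipital alpha power is lower during VIS than IDLE", {
  mont <- make_montage(2, 2, 2)
  on <- seq(10, 610, by = 40)
  lab <- rep(c("VIS", "IDLE"), length.out = length(on))
  sch <- event_schedule(on, rep(30, length(on)), lab, rep(2, length(on)))
  osc <- oscillatory_model(blink_rate = 0)
  eeg <- simulate_eeg(sch, erp_template(), osc, mont, seed = 6)
  alpha_power <- function(o) {
    i0 <- hybridbci:::window_indices(o + 2, 25, 256)
    w <- welch_psd(eeg["Oz", i0$first:(i0$first + i0$n - 1)], 256)
    sum(w$psd[w$freq >= 8 & w$freq <= 12])
  }
  p_vis <- mean(vapply(on[lab == "VIS"], alpha_power, numeric(1)))
  p_idle <- mean(vapply(on[lab == "IDLE"], alpha_power, numeric(1)))
  expect_lt(p_vis, p_idle)
})

test_that("blink rate zero leaves frontal channels blink-free and seeds reproduce", {
  mont <- make_montage(2, 2, 2)
  sch <- event_schedule(10, 12, "AUD", 2)
  osc0 <- oscillatory_model(blink_rate = 0, background_sd = 0, white_sd = 0,
                            alpha_amp = 0, beta_amp = 0)
  erp0 <- erp_template(p300_amp = 0, n1_amp = 0)
  eeg <- simulate_eeg(sch, erp0, osc0, mont, seed = 3)
  expect_equal(max(abs(eeg)), 0)  # nothing left when every source is off
  a <- simulate_eeg(sch, erp_template(), oscillatory_model(), mont, seed = 5)
  b <- simulate_eeg(sch, erp_template(), oscillatory_model(), mont, seed = 5)
  expect_identical(a, b)
})

test_that("templates longer than the shortest stimulus are rejected", {
  mont <- make_montage(2, 2, 2)
  sch <- event_schedule(10, 0.5, "AUD", 2)
  expect_error(simulate_eeg(sch, erp_template(), oscillatory_model(), mont, 1),
               "longer than the shortest")
})

test_that("alpha gain ordering AUD >= IDLE > VIS is enforced by construction", {
  expect_error(oscillatory_model(alpha_gain = c(AUD = 0.3, VIS = 0.9,
                                                MIX = 0.4, IDLE = 0.8)),
               "AUD >= IDLE > VIS")
  m <- oscillatory_model()
  expect_true(m$alpha_gain["AUD"] >= m$alpha_gain["IDLE"])
  expect_gt(m$alpha_gain["IDLE"], m$alpha_gain["VIS"])
})

test_that("cohorts derive per-subject seeds deterministically", {
  cfg <- sim_config(n_subjects = 2, trials_per_label = 2)
  mont <- make_montage(2, 2, 2)
  a <- generate_cohort(cfg, session_models(), mont, seed = 13)
  b <- generate_cohort(cfg, session_models(), mont, seed = 13)
  expect_length(a, 2)
  expect_identical(a[[1]]$fnirs_ac, b[[1]]$fnirs_ac)
  expect_identical(a[[2]]$eeg, b[[2]]$eeg)
  expect_false(identical(a[[1]]$eeg, a[[2]]$eeg))
})
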