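# Feature extraction: slope features, Welch band power, ERP waveform
# features, z-normalization, continuous-mode fNIRS feature.

test_that("the slope feature matches direct summation on worked examples", {
  tr <- synthetic_trials(n = 2, noise = 0)
  # plant x(t) = t on every channel of trial 1 (post-onset seconds 0..9)
  for (ch in seq_len(dim(tr$hbo)[2])) tr$hbo[1, ch, ] <- c(0, 0, 0:9)
  f <- slope_feature(tr, t_opt = 5, w = 4, "hbo")
  expect_equal(unclass(f)[1, ], rep(3, dim(tr$hbo)[2]))  # (2/4)*((5+6+7)-(3+4+5))
  # constant epoch -> 0
  tr$hbo[1, , ] <- 4.2
  expect_equal(unclass(slope_feature(tr, 5, 4, "hbo"))[1, ],
               rep(0, dim(tr$hbo)[2]))
  # unit step strictly after t_opt -> h
  h <- 2.5
  for (ch in seq_len(dim(tr$hbo)[2]))
    tr$hbo[1, ch, ] <- c(rep(0, 2 + 6), rep(h, 4))  # step after second 5
  expect_equal(unclass(slope_feature(tr, 5, 4, "hbo"))[1, ],
               rep(h, dim(tr$hbo)[2]))
  expect_error(slope_feature(tr, 9, 4, "hbo"), "exceeds")
  expect_error(slope_feature(tr, 5, 3, "hbo"), "even")
})

test_that("slope features equal a brute-force oracle over the whole grid", {
  set.seed(8)
  tr <- synthetic_trials(n = 10, noise = 1)
  grid <- slope_grid()
  npre <- tr$n_hb_prestim
  for (g in seq_len(nrow(grid))) {
    t_opt <- grid$t_opt[g]; w <- grid$w[g]
    f <- unclass(slope_feature(tr, t_opt, w, "hbr"))
    for (i in c(1, 7)) {
      for (ch in c(1, 4)) {
        x <- tr$hbr[i, ch, ]
        up <- sum(x[npre + (t_opt:(t_opt + w / 2)) + 1])
        dn <- sum(x[npre + ((t_opt - w / 2):t_opt) + 1])
        expect_equal(f[i, ch], (2 / w) * (up - dn), tolerance = 1e-12)
      }
    }
  }
})

test_that("slope parameter selection recovers a planted effect time", {
  tr <- synthetic_trials(n = 40, hb_effect = 1.5, step_at = 6, noise = 0.7,
                         seed = 3)
  bt <- build_condition(tr, condition_spec("AUD vs VIS", "AUD", "VIS"))
  sel <- select_slope_params(bt, "hbo", seed = 2)
  expect_true(abs(sel$t_opt - 6) <= 1)
  # single grid point -> that point
  one <- select_slope_params(bt, "hbo", grid = data.frame(t_opt = 4, w = 2))
  expect_equal(one$t_opt, 4)
  # all-constant features -> all grid accuracies tie -> deterministic first
  # (smallest t_opt, then smallest w)
  trc <- synthetic_trials(n = 12, hb_effect = 0, eeg_effect = 0, noise = 0)
  trc$hbo[] <- 1
  btc <- build_condition(trc, condition_spec("AUD vs VIS", "AUD", "VIS"))
  tie <- select_slope_params(btc, "hbo", seed = 2)
  g <- slope_grid()
  expect_equal(c(tie$t_opt, tie$w), c(g$t_opt[1], g$w[1]))
  expect_error(select_slope_params(bt, "hbo", grid = slope_grid()[0, ]),
               "empty")
})

test_that("Welch PSD localizes tones and matches a periodogram oracle", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  w <- welch_psd(x, fs)
  expect_equal(w$freq[which.max(w$psd)], 10)
  expect_equal(w$freq[2] - w$freq[1], 0.5)
  # total power of a unit-variance white signal integrates to ~1
  set.seed(1)
  n <- rnorm(fs * 60)
  wn <- welch_psd(n, fs)
  expect_equal(sum(wn$psd) * 0.5, 1, tolerance = 0.1)
  # single zero-padded segment path for short signals keeps the grid
  ws <- welch_psd(sin(2 * pi * 10 * t[1:256]), fs)
  expect_equal(ws$freq[2] - ws$freq[1], 0.5)
  expect_equal(ws$freq[which.max(ws$psd)], 10)
})

test_that("POW features have the printed dimensionality and band behaviour", {
  tr <- synthetic_trials(n = 4, noise = 0.5)
  P <- pow_feature(tr)
  expect_equal(ncol(P), 38 * 10)     # 38 components per electrode
  prov <- attr(P, "provenance")
  expect_equal(sort(unique(prov$freq_hz)), 3:40)
  # a planted 10 Hz tone dominates at its electrode
  big <- which.max(unclass(P)[1, prov$electrode == "Oz"])
  expect_equal(prov$freq_hz[prov$electrode == "Oz"][big], 10)
  # ablation band 13-40 drops alpha and has 28 components
  P2 <- pow_feature(tr, pow_params(band = c(13, 40)))
  expect_equal(ncol(P2), 28 * 10)
  expect_false(10 %in% attr(P2, "provenance")$freq_hz)
  expect_error(pow_params(band = c(40, 13)), "invalid")
})

test_that("ERP features downsample to 20 values per electrode", {
  tr <- synthetic_trials(n = 3, noise = 0.5)
  E <- erp_feature(tr)
  expect_equal(ncol(E), 20 * 10)
  # constant epoch -> constant features
  trc <- synthetic_trials(n = 2, noise = 0)
  trc$eeg[] <- 3.3
  trc$baseline_corrected <- TRUE
  Ec <- erp_feature(trc)
  expect_true(all(abs(unclass(Ec) - 3.3) < 1e-12))
  # isolated single-sample spike is erased by the median filter
  trs <- synthetic_trials(n = 2, noise = 0)
  trs$eeg[] <- 0
  trs$eeg[1, 1, 300] <- 50
  expect_true(all(unclass(erp_feature(trs)) == 0))
  expect_error(erp_params(k_med = 4), "odd")
})

test_that("z-normalization uses training statistics only", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5, mean = 2, sd = 3), 30, 5)
  nz <- fit_normalizer(X)
  Z <- apply_normalizer(nz, X)
  expect_equal(colMeans(Z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(Z, 2, stats::sd), rep(1, 5), tolerance = 1e-12)
  # shifted copy: transformed means equal the shift (in sd units here checked
  # via the raw shift divided by the learned scale)
  Z2 <- apply_normalizer(nz, X + 1.5)
  expect_equal(colMeans(Z2), 1.5 / nz$scale, tolerance = 1e-12)
  # constant column flagged and centered, not divided
  Xc <- cbind(X, 7)
  nzc <- fit_normalizer(Xc)
  expect_true(nzc$degenerate[6])
  expect_equal(apply_normalizer(nzc, Xc)[, 6], rep(0, 30))
  expect_error(fit_normalizer(X[1, , drop = FALSE]), ">= 2")
})

test_that("the continuous fNIRS feature is window mean minus elapsed mean", {
  w <- matrix(2, 3, 4); e <- matrix(1.5, 3, 10)
  expect_equal(continuous_fnirs_feature(w, e), rep(0.5, 3))
  # first window: no elapsed data -> 0
  expect_equal(continuous_fnirs_feature(w, e[, 0]), rep(0, 3))
  # step of height h at the window start, constant elapsed -> h
  h <- 1.2
  expect_equal(continuous_fnirs_feature(matrix(1 + h, 2, 3), matrix(1, 2, 6)),
               rep(h, 2))
  # empty window at the 1 Hz rate falls back to the last elapsed sample
  expect_equal(continuous_fnirs_feature(matrix(0, 2, 0), cbind(c(1, 1), c(2, 3))),
               c(0, 0) + c(2, 3) - rowMeans(cbind(c(1, 1), c(2, 3))))
  expect_error(continuous_fnirs_feature(NULL, e), "empty window")
  # stationary signal: features hover around zero
  set.seed(2)
  vals <- replicate(200, {
    x <- matrix(rnorm(30), 1, 30)
    continuous_fnirs_feature(x[, 21:30, drop = FALSE], x[, 1:20, drop = FALSE])
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("extractors are deterministic and reject missing values", {
  tr <- synthetic_trials(n = 4, seed = 9)
  expect_identical(unclass(pow_feature(tr)), unclass(pow_feature(tr)))
  tr$hbo[1, 1, 5] <- NA
  expect_error(slope_feature(tr, 2, 2, "hbo"), "missing")
})
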