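# Optical preprocessing chain: normalization, pulse correction, median
# filtering/downsampling, MBLL, common average referencing.

test_that("AC normalization gives unit channel means and flags dead channels", {
  x <- matrix(rexp(5 * 100) + 0.5, 5, 100)
  nx <- normalize_ac(x)
  expect_equal(rowMeans(nx), rep(1, 5), tolerance = 1e-12)
  # constant channel -> all ones
  xc <- rbind(rep(3, 50), rexp(50) + 1)
  expect_equal(normalize_ac(xc)[1, ], rep(1, 50))
  # two-point case (a, 3a) -> (0.5, 1.5)
  expect_equal(as.numeric(normalize_ac(matrix(c(2, 6), 1, 2))), c(0.5, 1.5))
  # zero-mean channel flagged
  expect_warning(nz <- normalize_ac(rbind(rep(0, 50), rexp(50) + 1)), "flagged")
  expect_true(attr(nz, "bad_channels")[1])
})

test_that("pulse correction removes >=90% of cardiac power, keeps the rest", {
  fs <- 19.5
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  drift <- 0.02 * sin(2 * pi * 0.05 * t)
  pulse <- 0.01 * sin(2 * pi * 1.1 * t)
  x <- matrix(1 + drift + pulse, 1, length(t))
  y <- pulse_correct(x, fs)
  expect_equal(attr(y, "cardiac_freq"), 1.1, tolerance = 0.05)
  band_power <- function(v, lo, hi) {
    w <- welch_psd(v - mean(v), fs, seg_s = 20)
    sum(w$psd[w$freq >= lo & w$freq <= hi])
  }
  expect_lt(band_power(y[1, ], 1.0, 1.2) / band_power(x[1, ], 1.0, 1.2), 0.1)
  # slow drift band essentially untouched (< 5 % change)
  expect_equal(band_power(y[1, ], 0.02, 0.2), band_power(x[1, ], 0.02, 0.2),
               tolerance = 0.05)
})

test_that("pulse correction passes through when no cardiac peak exists", {
  set.seed(2)
  x <- matrix(1 + rnorm(4 * 2000, 0, 0.01), 4, 2000)
  expect_warning(y <- pulse_correct(x, 19.5), "no detectable cardiac peak")
  expect_equal(unclass(y)[, ], x[, ])
})

test_that("median filtering + downsampling follows the stated arithmetic", {
  x <- matrix(5, 2, 390)                  # constant -> constant
  y <- median_downsample(x)
  expect_equal(ncol(y), 20)               # 390 samples = 20 s -> 20 samples
  expect_true(all(y == 5))
  # an isolated spike never survives the median filter
  xs <- matrix(0, 1, 390); xs[1, 200] <- 100
  expect_true(all(median_downsample(xs) == 0))
  expect_error(median_downsample(matrix(0, 1, 100)), "shorter")
})

test_that("MBLL forward and inverse are exact mutual inverses", {
  mont <- make_montage(3, 3, 3)
  p <- mbll_params(mont)
  set.seed(4)
  hb <- list(hbo = matrix(rnorm(9 * 40), 9), hbr = matrix(rnorm(9 * 40), 9))
  od <- mbll_forward(hb, p)
  back <- mbll_convert(od, p)
  expect_equal(back$hbo, hb$hbo, tolerance = 1e-10)
  expect_equal(back$hbr, hb$hbr, tolerance = 1e-10)
  # zero optical density -> zero concentrations
  z <- mbll_convert(list(wl1 = matrix(0, 9, 5), wl2 = matrix(0, 9, 5)), p)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  # single-point round trip
  m1 <- make_montage(1, 1, 1)
  one <- mbll_convert(mbll_forward(list(hbo = matrix(1, 3, 1),
                                        hbr = matrix(-0.5, 3, 1)),
                                   mbll_params(m1)), mbll_params(m1))
  expect_equal(drop(one$hbo), rep(1, 3), tolerance = 1e-12)
  expect_equal(drop(one$hbr), rep(-0.5, 3), tolerance = 1e-12)
})

test_that("MBLL matches an explicit 2x2 algebraic solve and scaling laws", {
  mont <- make_montage(2, 2, 2)
  p <- mbll_params(mont)
  set.seed(9)
  od <- list(wl1 = matrix(rnorm(6 * 10, 0, 0.01), 6),
             wl2 = matrix(rnorm(6 * 10, 0, 0.01), 6))
  hb <- mbll_convert(od, p)
  # oracle: closed-form 2x2 inverse per channel
  E <- p$extinction
  for (c in 1:6) {
    M <- E * p$dpf * p$distance_cm[c] / 1000
    det_ <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    hbo <- (M[2, 2] * od$wl1[c, ] - M[1, 2] * od$wl2[c, ]) / det_
    hbr <- (-M[2, 1] * od$wl1[c, ] + M[1, 1] * od$wl2[c, ]) / det_
    expect_equal(hb$hbo[c, ], hbo, tolerance = 1e-10)
    expect_equal(hb$hbr[c, ], hbr, tolerance = 1e-10)
  }
  # doubling the distance halves the recovered concentrations
  mont2 <- mont; mont2$distance_cm <- mont$distance_cm  # same montage, scaled DPF
  p2 <- mbll_params(mont2, dpf = c(12, 12))              # doubling d*DPF product
  hb2 <- mbll_convert(od, p2)
  expect_equal(hb2$hbo, hb$hbo / 2, tolerance = 1e-10)
  # singular extinction matrix rejected at construction
  expect_error(mbll_params(mont, extinction = matrix(1, 2, 2)), "singular")
})

test_that("CAR zeroes the channel mean and preserves differences", {
  x <- rbind(c(1, 5), c(3, 1))
  y <- common_average_reference(x)
  expect_equal(y[, 1], c(-1, 1))
  expect_equal(colMeans(y), c(0, 0), tolerance = 1e-12)
  set.seed(3)
  z <- matrix(rnorm(8 * 30), 8)
  zc <- common_average_reference(z)
  expect_equal(colMeans(zc), rep(0, 30), tolerance = 1e-12)
  expect_equal(common_average_reference(zc), zc)            # idempotent
  expect_equal(zc[1, ] - zc[2, ], z[1, ] - z[2, ])          # differences kept
  expect_error(common_average_reference(z[1, , drop = FALSE]), "2 channels")
})

test_that("the noise-free chain recovers injected amplitudes within 5%", {
  mont <- make_montage(3, 3, 3)
  on <- seq(30, 450, by = 45)
  sch <- event_schedule(on, rep(12.5, length(on)), rep("VIS", length(on)),
                        rep(2, length(on)))
  hrf <- hrf_model(vis_amp = 0.5, drift_sd = 0, slow_amp = 0, white_sd = 0,
                   pulse_amp = 0, channel_gain_sd = 0)
  ac <- simulate_fnirs(sch, hrf, mont, seed = 4)
  gain <- attr(ac, "channel_gain")
  sess <- new_session("x", ac, matrix(0, 10, ceiling(475 * 256)), sch, mont)
  sess <- preprocess_fnirs(sess, pulse = FALSE)
  # oracle: the exact concentration time course pushed through the same
  # median filter + decimation + CAR (the only attenuating steps)
  fs <- 19.5
  kern <- hybridbci:::hrf_kernel(hrf, fs)
  n <- ncol(ac$wl1)
  drive <- numeric(n)
  for (o in on) {
    i0 <- hybridbci:::window_indices(o, 12.5, fs)
    drive[i0$first:(i0$first + i0$n - 1)] <- 0.5
  }
  resp <- hybridbci:::conv_causal(drive, kern)
  truth <- outer(gain, resp)                       # channels x samples
  truth_1hz <- median_downsample(truth, fs)
  truth_car <- common_average_reference(truth_1hz)
  occ <- hybridbci:::probe_channels(mont, "occipital")
  best <- occ[which.max(gain[occ])]
  expect_equal(max(sess$hb$hbo[best, ]), max(truth_car[best, ]),
               tolerance = 0.05)
})
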