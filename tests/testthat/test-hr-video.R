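test_that("ROI extraction averages uniform regions exactly", {
  lm <- gen_landmark_frames(rep(4, 3))
  mk_frame <- function(r, g, b) {
    fr <- array(0, dim = c(480, 640, 3))
    fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
    fr
  }
  frames <- list(mk_frame(200, 0, 0), mk_frame(100, 0, 0),
                 mk_frame(110, 0, 0))
  tr <- extract_roi_traces(frames, lm)
  expect_equal(unname(tr$r[, "left"]), c(200, 100, 110))
  expect_equal(unname(tr$r[, "right"]), c(200, 100, 110))
  expect_true(all(tr$g == 0) && all(tr$b == 0))
})

test_that("too many invalid landmark frames raise a quality error", {
  lm <- gen_landmark_frames(rep(4, 10), valid = c(rep(TRUE, 5), rep(FALSE, 5)))
  frames <- replicate(10, array(0, dim = c(48, 64, 3)), simplify = FALSE)
  expect_error(extract_roi_traces(frames, lm), "valid landmarks")
})

test_that("PCA selects the cardiac component, not drift or noise", {
  fs <- 30
  n <- 3600
  t <- (0:(n - 1)) / fs
  set.seed(5)
  pulse <- sin(2 * pi * 1.2 * t)
  m <- cbind(pulse + rnorm(n, 0, 0.5), pulse + rnorm(n, 0, 0.5))
  comp <- pca_clean(m, fps = fs)
  sp <- power_spectrum(comp)
  sel <- sp$freqs_hz > 0.3
  expect_lt(abs(sp$freqs_hz[sel][which.max(sp$power[sel])] - 1.2), 0.05)

  # strong common drift must not capture the selection
  drift <- 6 * sin(2 * pi * 0.05 * t)
  m2 <- cbind(pulse + drift + rnorm(n, 0, 0.3),
              pulse + drift + rnorm(n, 0, 0.3))
  comp2 <- pca_clean(m2, fps = fs)
  sp2 <- power_spectrum(comp2)
  inband <- sp2$freqs_hz >= 0.6 & sp2$freqs_hz <= 2.2
  peak_f <- sp2$freqs_hz[inband][which.max(sp2$power[inband])]
  expect_lt(abs(peak_f - 1.2), 0.05)

  # identical noiseless traces: rank-1, component reproduces the trace
  m3 <- cbind(pulse, pulse)
  comp3 <- pca_clean(m3, fps = fs)
  expect_gt(abs(stats::cor(comp3$values, pulse)), 0.999)

  # single trace: fallback flagged
  single <- pca_clean(matrix(pulse, ncol = 1), fps = fs)
  expect_true(attr(single, "fallback"))
})

test_that("smoothness-priors detrending matches its closed form", {
  fs <- 30
  # a linear ramp is pure trend
  ramp <- sampled_signal(seq(0, 100, length.out = 900), fs)
  out <- detrend_smoothness_priors(ramp, detrend_spec(lambda = 10))
  expect_lt(max(abs(out$values)), 1e-6 * 100)

  # dense-matrix oracle equivalence at several lambdas
  set.seed(6)
  v <- cumsum(rnorm(400)) + sin(2 * pi * 1.2 * (0:399) / fs)
  for (lam in c(10, 500)) {
    mine <- detrend_smoothness_priors(sampled_signal(v, fs),
                                      detrend_spec(lambda = lam))$values
    expect_lt(max(abs(mine - detrend_dense_oracle(v, lam))), 1e-8)
  }

  # default cutoff-derived lambda passes the cardiac band untouched
  x12 <- tone(1.2, fs, 60)
  kept <- detrend_smoothness_priors(x12, detrend_spec())
  expect_gt(sum(kept$values^2) / sum(x12$values^2), 0.95)
  # ... and removes sub-cutoff drift
  slow <- tone(0.02, fs, 300)
  gone <- detrend_smoothness_priors(slow, detrend_spec())
  expect_lt(sum(gone$values^2) / sum(slow$values^2), 0.01)

  z <- detrend_smoothness_priors(sampled_signal(rep(0, 50), fs))
  expect_true(all(z$values == 0))
  expect_error(detrend_spec(lambda = -1), "lambda")
})

test_that("z-score uses the population SD and flags degenerate input", {
  z <- zscore(sampled_signal(c(1, 2, 3), 30))
  expect_equal(z$values, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-4)
  expect_equal(z$values[3], 1.2247, tolerance = 1e-4)

  con <- zscore(sampled_signal(rep(4, 10), 30))
  expect_true(attr(con, "degenerate"))
  expect_true(all(con$values == 0))

  again <- zscore(z)
  expect_equal(again$values, z$values, tolerance = 1e-9)
})

test_that("window HR finds in-band tones and rejects out-of-band input", {
  fs <- 30
  w72 <- sin(2 * pi * 1.2 * (0:99) / fs + 0.7)
  expect_lt(abs(as.numeric(hr_from_window(w72, fs)) - 72), 1)
  w60 <- sin(2 * pi * 1.0 * (0:99) / fs)
  expect_lt(abs(as.numeric(hr_from_window(w60, fs)) - 60), 1)

  w_out <- sin(2 * pi * 0.3 * (0:99) / fs)
  est <- hr_from_window(w_out, fs)
  expect_false(attr(est, "valid"))

  expect_error(hr_from_window(rnorm(80), fs), "exactly 100")
})

test_that("the HR series tracks a stepped tone minute by minute", {
  fs <- 30
  t1 <- (0:(60 * fs - 1)) / fs
  x <- c(sin(2 * pi * 1.0 * t1), sin(2 * pi * 1.5 * t1))
  hr <- hr_series_video(sampled_signal(x, fs))
  expect_equal(hr$bpm, c(60, 90), tolerance = 2 / 60)
  expect_true(all(hr$valid))

  expect_error(hr_series_video(sampled_signal(rnorm(90), fs)), "too short")
})

test_that("HR estimates are invariant to red-trace scaling", {
  g <- gen_roi_trace(sim_spec(120, seed = 21, hr_bpm = 66, snr_db = 6,
                              drift_amplitude_ratio = 2))
  h1 <- hr_video_pipeline(g$trace)$hr
  tr2 <- g$trace
  tr2$r <- tr2$r * 3.7
  h2 <- hr_video_pipeline(tr2)$hr
  expect_equal(h1$bpm, h2$bpm, tolerance = 1e-6)
})

test_that("the pipeline recovers a stepped heart rate end to end", {
  g <- gen_roi_trace(sim_spec(120, seed = 22, hr_bpm = c(60, 90),
                              snr_db = 5, drift_amplitude_ratio = 3))
  hr <- hr_video_pipeline(g$trace)$hr
  expect_equal(hr$bpm[1], 60, tolerance = 2 / 60)
  expect_equal(hr$bpm[2], 90, tolerance = 2 / 90)
})
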