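test_that("robust spread is the mean absolute deviation", {
  expect_equal(robust_std_dev(c(0, 2, 0, 2)), 1.0)
  expect_equal(robust_std_dev(c(7, 7, 7)), 0.0)
  expect_equal(robust_std_dev(c(-1, 1)), 1.0)
  expect_error(robust_std_dev(numeric(0)), "empty")
  # alternative estimator exposed but not default
  expect_equal(robust_std_dev(c(0, 2, 0, 2), "scaled_mad"), 1.4826)
})

test_that("blink threshold is mean + 3 x robust spread of eyes-open EOG", {
  expect_equal(compute_blink_threshold(c(0, 0, 0, 0))$value, 0)
  thr <- compute_blink_threshold(c(0, 2, 0, 2))
  expect_equal(thr$value, 4.0)           # 1 + 3 * 1
  expect_equal(thr$mean_open, 1.0)
  expect_equal(thr$robust_sd, 1.0)
  expect_equal(compute_blink_threshold(c(1, 1, 1, 1))$value, 1.0)
  short <- sampled_signal(rnorm(100), 256)  # 0.39 s at 256 Hz
  expect_error(compute_blink_threshold(short), "too short")
})

test_that("template respects its invariants", {
  tm <- blink_template(256)
  expect_equal(max(abs(tm$waveform)), 1)
  expect_error(blink_template(256, duration_s = 0.05), "between")
  expect_error(blink_template(256, duration_s = 0.9), "between")
})

test_that("injected template-shaped deflections are all recovered", {
  fs <- 256
  band <- bandpass_spec(2, 10, 5)
  dur <- 70
  n <- dur * fs
  bump <- blink_template(fs)$waveform
  truth <- seq(5, 62, length.out = 12)
  x <- numeric(n)
  for (tt in truth) {
    i <- round(tt * fs) + seq_along(bump)
    x[i] <- x[i] + 2 * bump        # 2x threshold amplitude scale
  }
  xf <- bandpass(sampled_signal(x, fs), band)
  ev <- detect_blinks_eog(xf, threshold = 0.1, template = blink_template(fs),
                          band = band)
  expect_equal(nrow(ev), 12)
  expect_true(all(ev$correlation > 0.99))

  # everything below threshold: no events
  ev0 <- detect_blinks_eog(xf, threshold = 10, template = blink_template(fs),
                           band = band)
  expect_equal(nrow(ev0), 0)
})

test_that("a rectangular pulse is rejected by the correlation gate", {
  fs <- 256
  band <- bandpass_spec(2, 10, 5)
  n <- 20 * fs
  x <- numeric(n)
  x[(10 * fs):(10 * fs + round(0.3 * fs))] <- 2   # square artifact
  xf <- bandpass(sampled_signal(x, fs), band)
  # correlation oracle: the filtered square's centred segment vs the
  # filtered template is itself below the 0.9 cutoff
  tmpl <- facevitals:::filtered_template_waveform(blink_template(fs), band)
  ipk <- which.max(xf$values)
  half <- floor(length(tmpl) / 2)
  seg <- xf$values[(ipk - half):(ipk - half + length(tmpl) - 1)]
  expect_lt(stats::cor(seg, tmpl), 0.9)
  ev <- detect_blinks_eog(xf, threshold = 0.1, template = blink_template(fs),
                          band = band)
  expect_equal(nrow(ev), 0)
})

test_that("detection is equivariant under time shifts", {
  fs <- 256
  band <- bandpass_spec(2, 10, 5)
  spec <- sim_spec(40, seed = 31, blink_rate_per_min = 12, snr_db = 20,
                   edge_pad_s = 3)
  g <- gen_eog(spec)
  thr <- compute_blink_threshold(bandpass(g$calibration, band))
  detect <- function(v) {
    xf <- bandpass(sampled_signal(v, fs), band)
    detect_blinks_eog(xf, thr, blink_template(fs), band = band)$t_peak_s
  }
  base <- detect(g$signal$values)
  shifted <- detect(c(rep(0, round(0.5 * fs)), g$signal$values))
  expect_gte(length(base), 3)
  # every event reappears 0.5 s later, to within one sample
  for (tt in base) {
    expect_lt(min(abs(shifted - (tt + 0.5))), 1.5 / fs)
  }
})

test_that("template fs mismatch errors", {
  fs <- 256
  xf <- bandpass(sampled_signal(rnorm(10 * fs), fs), bandpass_spec(2, 10, 5))
  expect_error(detect_blinks_eog(xf, 1, blink_template(30)), "fs")
})

test_that("scaling blink amplitudes never decreases the count", {
  fs <- 256
  band <- bandpass_spec(2, 10, 5)
  spec <- sim_spec(50, seed = 77, blink_rate_per_min = 15, snr_db = 14,
                   edge_pad_s = 3)
  g <- gen_eog(spec)
  thr <- compute_blink_threshold(bandpass(g$calibration, band))
  count_for <- function(scale) {
    # scale only the blink component
    clean <- gen_eog(sim_spec(50, seed = 77, blink_rate_per_min = 15,
                              snr_db = Inf, edge_pad_s = 3))
    noise <- g$signal$values - clean$signal$values
    xf <- bandpass(sampled_signal(scale * clean$signal$values + noise, fs),
                   band)
    nrow(detect_blinks_eog(xf, thr, blink_template(fs), band = band))
  }
  counts <- vapply(c(1, 1.5, 2.5), count_for, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("EBR is count per minute", {
  ev <- facevitals:::blink_events(seq_len(10), rep(1, 10), duration_s = 120)
  expect_equal(compute_ebr(ev), 5.0)
  expect_equal(compute_ebr(facevitals:::blink_events(numeric(0), numeric(0),
                                                     duration_s = 60)), 0.0)
  expect_equal(compute_ebr(7, duration_s = 90), 4.6667, tolerance = 1e-4)
  expect_error(compute_ebr(7, duration_s = 0), "positive")
})
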