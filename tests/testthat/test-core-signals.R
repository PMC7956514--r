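test_that("sampled_signal enforces its invariants", {
  expect_error(sampled_signal(numeric(0), 30), "at least one")
  expect_error(sampled_signal(c(1, NA), 30), "finite")
  expect_error(sampled_signal(1:5, -1), "positive")
  s <- sampled_signal(1:10, 5)
  expect_equal(signal_duration(s), 2)
  expect_equal(signal_times(s)[1], 0)
})

test_that("signal CSV round-trips exactly and rejects malformed files", {
  s <- sampled_signal(seq(0, 10, length.out = 2561), fs = 256)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, path)
  r <- read_signal_csv(path, fs = 256)
  expect_equal(r$values, s$values, tolerance = 1e-12)
  expect_equal(r$fs, 256)

  # header only
  writeLines("value", path)
  expect_error(read_signal_csv(path, 256), "empty")

  # non-numeric cell names its row
  writeLines(c("value", "1.0", "oops", "2.0"), path)
  expect_error(read_signal_csv(path, 256), "row 3")

  # jittered time column
  tt <- c(0, 1 / 30, 2.2 / 30, 3 / 30)
  writeLines(c("time,value", paste(tt, c(1, 2, 3, 4), sep = ",")), path)
  expect_error(read_signal_csv(path, 30), "non-uniform")

  # non-monotone time
  writeLines(c("time,value", "0,1", "0.1,2", "0.05,3"), path)
  expect_error(read_signal_csv(path, 10), "non-monotone")
})

test_that("events CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(t_peak_s = c(1.5, 3.25), amplitude = c(2, 3),
                   correlation = c(0.95, 0.97))
  write_events_csv(ev, path)
  r <- read_events_csv(path)
  expect_equal(r$t_peak_s, ev$t_peak_s, tolerance = 1e-12)
  writeLines("a,b", path)
  expect_error(read_events_csv(path), "t_peak_s")
})

test_that("band-pass removes DC and meets designed gains", {
  fs <- 30
  const <- sampled_signal(rep(5, 600), fs)
  for (spec in list(bandpass_spec(1, 3, 2), bandpass_spec(0.6, 2.2, 128,
                                                          "hamming_fir"))) {
    y <- bandpass(const, spec)
    m <- transient_samples(y) + 1
    expect_lt(max(abs(y$values[m:(length(y$values) - m + 1)])), 1e-6)
  }

  # FIR: designed-response oracle first, then the filtered amplitude
  fir <- bandpass_spec(0.6, 2.2, 128, "hamming_fir")
  g_pass <- bandpass_response(fir, fs, 1.2)
  g_stop <- bandpass_response(fir, fs, 5.0)
  expect_gt(g_pass, 0.95)        # single-pass
  expect_lt(g_stop, 0.1)
  y <- bandpass(tone(1.2, fs, 60), fir)
  expect_gt(steady_amp(y), 0.9)  # zero-phase squares the response
  expect_lt(steady_amp(y), 1.1)
  y5 <- bandpass(tone(5, fs, 60), fir)
  expect_lt(steady_amp(y5), 0.1)
})

test_that("band edges at or above Nyquist and short signals error", {
  expect_error(bandpass(tone(1, 30, 10), bandpass_spec(2, 15, 5)), "Nyquist")
  short <- sampled_signal(rnorm(20), 256)
  expect_error(bandpass(short, bandpass_spec(2, 10, 5)), "too short")
})

test_that("zero-phase filtering leaves a band-centred tone unshifted", {
  fs <- 256
  x <- tone(5, fs, 20)
  y <- bandpass(x, bandpass_spec(2, 10, 5))
  n <- length(x$values)
  core <- 2000:(n - 2000)
  cc <- stats::ccf(y$values[core], x$values[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear", {
  fs <- 256
  set.seed(1)
  a <- rnorm(4000)
  b <- rnorm(4000)
  spec <- bandpass_spec(2, 10, 5)
  f <- function(v) bandpass(sampled_signal(v, fs), spec)$values
  expect_equal(f(2 * a + 3 * b), 2 * f(a) + 3 * f(b), tolerance = 1e-9)
})

test_that("power spectrum localises tones and respects Parseval", {
  fs <- 30
  x <- tone(1.0, fs, 10)
  sp <- power_spectrum(x, n_fft = 1024)
  expect_lt(abs(sp$freqs_hz[which.max(sp$power)] - 1.0), sp$resolution_hz)

  # argmax within one grid bin for generous padding
  for (f0 in c(0.7, 1.7, 3.3)) {
    xx <- tone(f0, fs, 8)
    spx <- power_spectrum(xx, n_fft = 4 * 2^ceiling(log2(length(xx$values))))
    expect_lt(abs(spx$freqs_hz[which.max(spx$power)] - f0), spx$resolution_hz)
  }

  set.seed(2)
  w <- sampled_signal(rnorm(512), fs)
  spw <- power_spectrum(w, n_fft = 512)
  v <- w$values - mean(w$values)
  total <- 2 * sum(spw$power) - spw$power[1] - spw$power[length(spw$power)]
  expect_lt(abs(total - sum(v^2)) / sum(v^2), 0.1)

  z <- sampled_signal(rep(0, 64), fs)
  expect_true(all(power_spectrum(z, n_fft = 64)$power == 0))
})
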