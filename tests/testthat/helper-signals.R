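# shared fixtures built in code

tone <- function(freq_hz, fs, duration_s, amp = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sampled_signal(amp * sin(2 * pi * freq_hz * t + phase), fs)
}

# steady-state amplitude, ignoring the edges
steady_amp <- function(x, frac = 0.25) {
  n <- length(x$values)
  i <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  max(abs(x$values[i]))
}

# dense-matrix oracle for the smoothness-priors detrender
detrend_dense_oracle <- function(v, lambda) {
  n <- length(v)
  d2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) d2[i, i:(i + 2)] <- c(1, -2, 1)
  a <- diag(n) + lambda^2 * t(d2) %*% d2
  tr <- solve(a, v)
  tr <- tr + solve(a, v - as.numeric(a %*% tr))  # iterative refinement
  as.numeric(v - tr)
}
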