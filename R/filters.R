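#' Band-pass filter specification
#'
#' The pipelines use four fixed bands: 2--10 Hz (vertical EOG), 1--4 Hz
#' (ECG QRS emphasis), 1--3 Hz (eyelid-distance trace) and 0.6--2.2 Hz
#' (cardiac band of the photoplethysmographic pulse, i.e. 36--132 bpm).
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Filter order (Butterworth) or tap count (FIR).
#' @param family `"butterworth"` (IIR, applied as cascaded second-order
#'   sections) or `"hamming_fir"` (Hamming-window FIR, `order` taps).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz, high_hz, order = 5L,
                          family = c("butterworth", "hamming_fir")) {
  family <- match.arg(family)
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 ||
      high_hz <= low_hz) {
    stop("require 0 < low_hz < high_hz", call. = FALSE)
  }
  if (order < 1L) stop("filter order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), family = family),
            class = "bandpass_spec")
}

# Butterworth band-pass designed in zero-pole-gain form via the analog
# prototype and the bilinear transform, then grouped into biquad sections.
# The expanded transfer-function polynomial is numerically fragile for
# narrow bands at high sampling rates (e.g. 1-4 Hz at 256 Hz), so the
# design never leaves pole form.
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  w1 <- 2 * fs * tan(pi * low_hz / fs)   # prewarped band edges, rad/s
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0sq <- w1 * w2
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # prototype poles
  pa <- unlist(lapply(p_lp, function(p) {
    disc <- sqrt((p * bw / 2)^2 - w0sq)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  bil <- function(s) (1 + s / (2 * fs)) / (1 - s / (2 * fs))
  pz <- bil(pa)
  zz <- c(bil(rep(0, order)), rep(-1 + 0i, order))
  wc <- 2 * pi * sqrt(low_hz * high_hz) / fs
  ejw <- exp(1i * wc)
  gain <- 1 / abs(prod(ejw - zz) / prod(ejw - pz))
  ppos <- pz[Im(pz) >= 0]
  ppos <- ppos[order(Re(ppos))]
  sos <- lapply(ppos, function(p) {
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2))
  })
  list(sos = sos, gain = gain)
}

fir_bandpass_taps <- function(taps, low_hz, high_hz, fs) {
  as.numeric(signal::fir1(taps - 1L, c(low_hz, high_hz) / (fs / 2),
                          type = "pass", window = signal::hamming(taps)))
}

#' Frequency response of a band-pass design
#'
#' Single-pass magnitude response at the probe frequencies. Zero-phase
#' (forward-backward) application squares this magnitude.
#'
#' @param spec A [bandpass_spec()].
#' @param fs Sampling rate the filter is applied at, Hz.
#' @param freqs_hz Probe frequencies, Hz.
#' @return Numeric vector of single-pass gains `|H(f)|`.
#' @export
bandpass_response <- function(spec, fs, freqs_hz) {
  check_band(spec, fs)
  w <- 2 * pi * freqs_hz / fs
  if (spec$family == "butterworth") {
    d <- butter_bandpass_sos(spec$order, spec$low_hz, spec$high_hz, fs)
    vapply(w, function(wi) {
      z <- exp(1i * wi)
      h <- prod(vapply(d$sos, function(s) {
        abs((s$b[1] + s$b[2] / z + s$b[3] / z^2) /
            (s$a[1] + s$a[2] / z + s$a[3] / z^2))
      }, numeric(1)))
      h * d$gain
    }, numeric(1))
  } else {
    h <- fir_bandpass_taps(spec$order, spec$low_hz, spec$high_hz, fs)
    n <- seq_along(h) - 1
    vapply(w, function(wi) abs(sum(h * exp(-1i * wi * n))), numeric(1))
  }
}

check_band <- function(spec, fs) {
  if (spec$high_hz >= fs / 2) {
    stop(sprintf("band edge %g Hz is at or above the Nyquist frequency %g Hz",
                 spec$high_hz, fs / 2), call. = FALSE)
  }
  invisible(TRUE)
}

#' Zero-phase band-pass filtering
#'
#' Applies the filter forward and backward (`filtfilt`), preserving event
#' timing; the recordings are analysed offline so causality is not needed.
#' Butterworth filters run as cascaded second-order sections for numerical
#' stability with narrow bands at 256 Hz. The returned signal carries an
#' attribute `transient_samples`: the number of samples at each end that
#' downstream thresholding should treat as filter transients.
#'
#' @param x A [sampled_signal()].
#' @param spec A [bandpass_spec()].
#' @return A [sampled_signal()] of the same length and sampling rate, with
#'   attribute `transient_samples`.
#' @export
bandpass <- function(x, spec) {
  stopifnot(is_sampled_signal(x), inherits(spec, "bandpass_spec"))
  fs <- x$fs
  check_band(spec, fs)
  if (spec$low_hz <= 0 || spec$low_hz >= spec$high_hz) {
    stop("invalid band edges", call. = FALSE)
  }
  # DC lies outside any passband; removing it up front makes the
  # rejection exact instead of limited by the stopband floor
  v <- x$values - mean(x$values)
  if (spec$family == "butterworth") {
    if (length(v) <= 3 * (2 * spec$order)) {
      stop(sprintf(
        "signal too short (%d samples) for zero-phase order-%d band-pass",
        length(v), spec$order), call. = FALSE)
    }
    d <- butter_bandpass_sos(spec$order, spec$low_hz, spec$high_hz, fs)
    for (s in d$sos) v <- signal::filtfilt(s$b, s$a, v)
    v <- v * d$gain^2
    # settle time of the slowest pole, generously doubled for filtfilt
    pmax_mod <- max(vapply(d$sos, function(s) {
      max(Mod(polyroot(rev(s$a))))
    }, numeric(1)))
    trans <- ceiling(-6 / log(pmax_mod))
  } else {
    if (length(v) <= spec$order) {
      stop(sprintf("signal too short (%d samples) for a %d-tap FIR",
                   length(v), spec$order), call. = FALSE)
    }
    h <- fir_bandpass_taps(spec$order, spec$low_hz, spec$high_hz, fs)
    v <- signal::filtfilt(h, 1, v)
    trans <- spec$order - 1L
  }
  out <- sampled_signal(v, fs = fs, t0 = x$t0, label = x$label)
  attr(out, "transient_samples") <- as.integer(min(trans, floor(length(v) / 2)))
  out
}

#' Number of transient samples flagged by the last filtering step
#' @param x A filtered [sampled_signal()].
#' @return Integer count (0 if the signal was never filtered).
#' @export
transient_samples <- function(x) {
  ts <- attr(x, "transient_samples")
  if (is.null(ts)) 0L else ts
}

#' One-sided power spectrum
#'
#' Periodogram of the mean-removed, zero-padded signal. Power is
#' `|FFT|^2 / n`, where `n` is the original sample count, so that summing
#' the two-sided spectrum recovers `sum((x - mean(x))^2)` (Parseval).
#'
#' @param x A [sampled_signal()].
#' @param n_fft FFT length; must be at least the signal length.
#' @param remove_mean Subtract the mean before transforming (default TRUE).
#' @return An object of class `spectrum_1s` with fields `freqs_hz`,
#'   `power` and `resolution_hz`.
#' @export
power_spectrum <- function(x, n_fft = NULL, remove_mean = TRUE) {
  stopifnot(is_sampled_signal(x))
  v <- x$values
  n <- length(v)
  if (n < 1L) stop("empty signal", call. = FALSE)
  if (is.null(n_fft)) n_fft <- stats::nextn(max(n, 2L), 2)
  if (n_fft < n) stop("n_fft must be >= signal length", call. = FALSE)
  if (remove_mean) v <- v - mean(v)
  padded <- c(v, rep(0, n_fft - n))
  p <- Mod(stats::fft(padded))^2 / n
  half <- seq_len(floor(n_fft / 2) + 1L)
  structure(list(freqs_hz = (half - 1) * x$fs / n_fft,
                 power = p[half],
                 resolution_hz = x$fs / n_fft),
            class = "spectrum_1s")
}

#' @export
print.spectrum_1s <- function(x, ...) {
  cat(sprintf("<spectrum> %d bins, 0-%.3g Hz, resolution %.4g Hz\n",
              length(x$freqs_hz), max(x$freqs_hz), x$resolution_hz))
  invisible(x)
}
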