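#' Robust spread: mean absolute deviation
#'
#' Spread estimate used by the blink threshold: the mean absolute
#' deviation about the mean, `mean(|x - mean(x)|)`. (Despite the
#' "robust standard deviation" name used for this quantity in blink
#' detection practice, the definition is the literal mean absolute
#' deviation; a median-based estimator is available via `estimator`.)
#'
#' @param x A [sampled_signal()] or numeric vector.
#' @param estimator `"mean_abs_dev"` (default) or `"scaled_mad"`
#'   (1.4826 * median absolute deviation, a consistent SD estimator).
#' @return Non-negative scalar in signal units; 0 iff the input is
#'   constant.
#' @export
robust_std_dev <- function(x, estimator = c("mean_abs_dev", "scaled_mad")) {
  estimator <- match.arg(estimator)
  v <- if (is_sampled_signal(x)) x$values else as.numeric(x)
  if (!length(v)) stop("empty segment", call. = FALSE)
  switch(estimator,
    mean_abs_dev = mean(abs(v - mean(v))),
    scaled_mad = 1.4826 * stats::median(abs(v - stats::median(v)))
  )
}

#' Blink detection threshold from an eyes-open calibration segment
#'
#' `threshold = mean(segment) + 3 * robust_std_dev(segment)`, computed on
#' the band-passed (2--10 Hz) eyes-open EOG. The components are retained
#' for audit.
#'
#' @param eyes_open Band-passed eyes-open calibration segment, a
#'   [sampled_signal()] (or numeric vector at a stated `fs`).
#' @param estimator Spread estimator, see [robust_std_dev()].
#' @param min_duration_s Minimum calibration length in seconds (default 1).
#' @return An object of class `blink_threshold` with fields `value`,
#'   `mean_open`, `robust_sd`.
#' @export
compute_blink_threshold <- function(eyes_open,
                                    estimator = c("mean_abs_dev", "scaled_mad"),
                                    min_duration_s = 1) {
  estimator <- match.arg(estimator)
  if (is_sampled_signal(eyes_open)) {
    if (signal_duration(eyes_open) < min_duration_s) {
      stop(sprintf("calibration segment too short (%.2f s < %g s)",
                   signal_duration(eyes_open), min_duration_s), call. = FALSE)
    }
    v <- eyes_open$values
  } else {
    v <- as.numeric(eyes_open)
    if (!length(v)) stop("empty calibration segment", call. = FALSE)
  }
  m <- mean(v)
  rsd <- robust_std_dev(v, estimator = estimator)
  structure(list(value = m + 3 * rsd, mean_open = m, robust_sd = rsd),
            class = "blink_threshold")
}

#' @export
print.blink_threshold <- function(x, ...) {
  cat(sprintf("<blink_threshold> %.4g (mean %.4g + 3 x %.4g)\n",
              x$value, x$mean_open, x$robust_sd))
  invisible(x)
}

#' Parametric blink template
#'
#' Vertical-EOG blink deflections are smooth monophasic bumps; the default
#' template is a 300 ms raised-cosine (Hann) bump with unit peak
#' amplitude. A template can alternatively be built from data as the mean
#' of supra-threshold excursions in a calibration run.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Bump duration in seconds, between 0.1 and 0.5.
#' @return An object of class `blink_template` with fields `waveform`,
#'   `fs`, `duration_s`.
#' @export
blink_template <- function(fs, duration_s = 0.3) {
  if (duration_s < 0.1 || duration_s > 0.5) {
    stop("template duration must be between 0.1 and 0.5 s", call. = FALSE)
  }
  n <- max(3L, round(duration_s * fs))
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  structure(list(waveform = w / max(abs(w)), fs = fs, duration_s = duration_s),
            class = "blink_template")
}

# What a template bump looks like after the 2-10 Hz band-pass: biphasic
# with pronounced negative side lobes. Candidate segments are correlated
# against this filtered shape, since the signal being searched has been
# through the same filter. Extracted over +-`half_s` around the peak.
filtered_template_waveform <- function(template, band, half_s = 0.35) {
  fs <- template$fs
  pad <- numeric(round(4 * fs))
  mid <- round(1.5 * fs)
  pad[mid + seq_along(template$waveform)] <- template$waveform
  padf <- bandpass(sampled_signal(pad, fs), band)$values
  ipk <- which.max(padf)
  half <- round(half_s * fs)
  w <- padf[(ipk - half):(ipk + half)]
  w / max(abs(w))
}

#' Detect blinks in a band-passed vertical EOG trace
#'
#' Two-step procedure: every contiguous excursion above the calibration
#' threshold is a candidate; the candidate is accepted as a real blink
#' when the Pearson correlation between the trace segment centred on the
#' excursion maximum and the blink template exceeds `min_corr` (default
#' 0.9). The template is passed through the same band-pass as the signal
#' before correlating, so like is compared with like. Events closer than
#' the 200 ms physiological refractory period are merged, and excursions
#' overlapping the filter-transient edges are discarded.
#'
#' @param filtered The 2--10 Hz band-passed EOG, a [sampled_signal()]
#'   (typically the output of [bandpass()]).
#' @param threshold A [compute_blink_threshold()] result (or scalar).
#' @param template A [blink_template()]; its `fs` must equal the signal's.
#' @param min_corr Correlation acceptance cutoff (default 0.9).
#' @param refractory_s Minimum separation between accepted event peaks.
#' @param band The band-pass applied to the signal, used to filter the
#'   template for correlation (default the 2--10 Hz order-5 Butterworth).
#' @return An object of class `blink_events`: a data frame of events
#'   (`t_peak_s`, `amplitude`, `correlation`) with attribute
#'   `condition_duration_s`.
#' @export
detect_blinks_eog <- function(filtered, threshold, template,
                              min_corr = 0.9, refractory_s = 0.2,
                              band = bandpass_spec(2, 10, 5)) {
  stopifnot(is_sampled_signal(filtered))
  if (inherits(template, "blink_template") && template$fs != filtered$fs) {
    stop(sprintf("template fs (%g) does not match signal fs (%g)",
                 template$fs, filtered$fs), call. = FALSE)
  }
  thr <- if (inherits(threshold, "blink_threshold")) threshold$value
         else as.numeric(threshold)
  fs <- filtered$fs
  x <- filtered$values
  tmpl <- filtered_template_waveform(template, band)
  half <- floor(length(tmpl) / 2)
  margin <- max(transient_samples(filtered), round(1 * fs))

  above <- x > thr
  d <- diff(c(FALSE, above, FALSE))
  st <- which(d == 1)
  en <- which(d == -1) - 1L
  t_peak <- amp <- corr <- numeric(0)
  for (k in seq_along(st)) {
    ipk <- st[k] - 1L + which.max(x[st[k]:en[k]])
    if (ipk <= margin || ipk > length(x) - margin) next
    lo <- ipk - half
    hi <- lo + length(tmpl) - 1L
    if (lo < 1L || hi > length(x)) next
    r <- suppressWarnings(stats::cor(x[lo:hi], tmpl))
    if (is.na(r) || r <= min_corr) next
    tp <- filtered$t0 + (ipk - 1) / fs
    if (length(t_peak) && tp - t_peak[length(t_peak)] < refractory_s) next
    t_peak <- c(t_peak, tp)
    amp <- c(amp, x[ipk])
    corr <- c(corr, r)
  }
  blink_events(t_peak, amp, corr, duration_s = signal_duration(filtered))
}

blink_events <- function(t_peak_s, amplitude, correlation = rep(NA_real_, length(t_peak_s)),
                         duration_s) {
  df <- data.frame(t_peak_s = t_peak_s, amplitude = amplitude,
                   correlation = correlation)
  attr(df, "condition_duration_s") <- duration_s
  class(df) <- c("blink_events", "data.frame")
  df
}

#' @export
print.blink_events <- function(x, ...) {
  cat(sprintf("<blink_events> %d events over %.1f s (EBR %.2f /min)\n",
              nrow(x), attr(x, "condition_duration_s"), compute_ebr(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Eye-blink rate of a condition
#'
#' Blinks per minute over the recording condition:
#' `count / (duration / 60)`.
#'
#' @param events A `blink_events` data frame, or an event count.
#' @param duration_s Condition duration in seconds (taken from the events
#'   object when omitted).
#' @return Blinks per minute (>= 0).
#' @export
compute_ebr <- function(events, duration_s = NULL) {
  if (inherits(events, "blink_events") || is.data.frame(events)) {
    n <- nrow(events)
    if (is.null(duration_s)) duration_s <- attr(events, "condition_duration_s")
  } else {
    n <- as.numeric(events)
  }
  if (is.null(duration_s) || !is.finite(duration_s) || duration_s <= 0) {
    stop("condition duration must be a positive number of seconds",
         call. = FALSE)
  }
  n / (duration_s / 60)
}
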