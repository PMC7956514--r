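#' Uniformly sampled scalar signal
#'
#' The common currency of all pipelines: a numeric vector of sample values
#' together with its sampling rate. Biosignals (EOG, ECG) are typically
#' sampled at 256 Hz, video-derived traces at the camera frame rate
#' (30 fps).
#'
#' @param values Numeric vector of sample values; must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#' @param label Free-text label carried through processing stages.
#' @return An object of class `sampled_signal` with fields `values`, `fs`,
#'   `t0` and `label`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 30)), fs = 30)
#' signal_duration(s)
#' @export
sampled_signal <- function(values, fs, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("signal must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("signal values must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0),
         label = as.character(label)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$values), x$fs, signal_duration(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Duration of a signal in seconds
#' @param x A [sampled_signal()].
#' @return Duration `length(values) / fs` in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  length(x$values) / x$fs
}

#' Sample times of a signal
#' @param x A [sampled_signal()].
#' @return Numeric vector of time stamps in seconds (`t0 + (0:(n-1))/fs`).
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

is_sampled_signal <- function(x) inherits(x, "sampled_signal")

#' Read a signal from CSV
#'
#' Accepts a one-column file with header `value`, or a two-column file
#' with headers `time,value`. For two-column files the time stamps must be
#' uniform: sample-interval jitter above 1% of `1/fs` is an error, never
#' silently resampled.
#'
#' @param path Path to a CSV file (comma-separated, `.` decimal, header
#'   row mandatory).
#' @param fs Sampling rate in Hz. For two-column files it is checked
#'   against the time stamps.
#' @param label Optional label for the resulting signal.
#' @return A [sampled_signal()].
#' @export
read_signal_csv <- function(path, fs, label = basename(path)) {
  df <- utils::read.csv(path, header = TRUE)
  if (nrow(df) == 0L) {
    stop("empty signal file (header only): ", path, call. = FALSE)
  }
  if ("value" %in% names(df) && !"time" %in% names(df)) {
    vals <- df$value
    check_numeric_column(vals, "value", path)
    t0 <- 0
  } else if (all(c("time", "value") %in% names(df))) {
    check_numeric_column(df$time, "time", path)
    check_numeric_column(df$value, "value", path)
    tt <- as.numeric(df$time)
    if (length(tt) > 1L) {
      dt <- diff(tt)
      if (any(dt <= 0)) {
        stop(sprintf("non-monotone time column at row %d in %s",
                     which(dt <= 0)[1] + 1L, path), call. = FALSE)
      }
      if (any(abs(dt - 1 / fs) > 0.01 / fs)) {
        stop(sprintf(
          "non-uniform sampling at row %d in %s (dt=%.6g, expected %.6g)",
          which(abs(dt - 1 / fs) > 0.01 / fs)[1] + 1L, path, dt[which.max(abs(dt - 1 / fs))],
          1 / fs), call. = FALSE)
      }
    }
    vals <- df$value
    t0 <- tt[1]
  } else {
    stop("signal CSV must have a 'value' column or 'time','value' columns: ",
         path, call. = FALSE)
  }
  sampled_signal(vals, fs = fs, t0 = t0, label = label)
}

check_numeric_column <- function(v, name, path) {
  vn <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(vn))
  if (length(bad)) {
    stop(sprintf("non-numeric cell in column '%s' at row %d in %s",
                 name, bad[1] + 1L, path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a signal to CSV
#'
#' Writes `time,value` columns so the file round-trips through
#' [read_signal_csv()] with values reproduced to better than 1e-9.
#'
#' @param x A [sampled_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(is_sampled_signal(x))
  df <- data.frame(time = signal_times(x), value = x$values)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write event tables
#'
#' Event CSVs carry one detected event per row with columns `t_peak_s`
#' and `amplitude` (a `correlation` column is included when present,
#' as produced by the EOG template-matching detector).
#'
#' @param path CSV path.
#' @return `read_events_csv`: a data frame with at least `t_peak_s` and
#'   `amplitude`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(c("t_peak_s", "amplitude") %in% names(df))) {
    stop("events CSV must have columns 't_peak_s','amplitude': ", path,
         call. = FALSE)
  }
  if (nrow(df)) {
    check_numeric_column(df$t_peak_s, "t_peak_s", path)
    check_numeric_column(df$amplitude, "amplitude", path)
  }
  df
}

#' @rdname read_events_csv
#' @param events Data frame of events.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.csv(format(events, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linear interpolation helper over flagged samples
#'
#' Replaces the samples at `bad` indices with linear interpolation from the
#' nearest valid neighbours (constant extrapolation at the edges).
#'
#' @param values Numeric vector.
#' @param bad Integer or logical index of samples to replace.
#' @return Numeric vector with the flagged samples interpolated.
#' @keywords internal
interpolate_flagged <- function(values, bad) {
  if (is.logical(bad)) bad <- which(bad)
  if (!length(bad)) return(values)
  good <- setdiff(seq_along(values), bad)
  if (!length(good)) stop("no valid samples to interpolate from", call. = FALSE)
  out <- values
  out[bad] <- stats::approx(good, values[good], xout = bad, rule = 2)$y
  out
}
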