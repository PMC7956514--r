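#' Eyelid distance from 68-point facial landmarks
#'
#' In the standard 68-point annotation (0-based indices used in the
#' column names `x0,y0,...,x67,y67`), each eye is a hexagon:
#'
#' ```
#'          37  38                      43  44
#'       36        39              42        45
#'          41  40                      47  46
#' ```
#'
#' Left eye: upper lid 37, 38 pair with lower lid 41, 40; right eye:
#' upper 43, 44 pair with lower 47, 46. The per-eye distance is the mean
#' Euclidean distance of the two vertical pairs; the returned trace is
#' the mean of the two eyes. Invalid frames are linearly interpolated and
#' flagged.
#'
#' @param frames Data frame with columns `frame_index`, `valid` (logical
#'   or 0/1), and `x0..x67`, `y0..y67` pixel coordinates.
#' @param fps Video frame rate in Hz (default 30).
#' @return A list of class `eyelid_trace`: `distance` (a
#'   [sampled_signal()], pixels), `left`, `right` (per-eye vectors,
#'   retained for audit) and `interpolated` (logical flags).
#' @export
eyelid_distance <- function(frames, fps = 30) {
  stopifnot(is.data.frame(frames))
  valid <- as.logical(frames$valid)
  if (!any(valid)) stop("no valid landmark frames", call. = FALSE)

  pair_dist <- function(i_up, i_lo) {
    sqrt((frames[[paste0("x", i_up)]] - frames[[paste0("x", i_lo)]])^2 +
         (frames[[paste0("y", i_up)]] - frames[[paste0("y", i_lo)]])^2)
  }
  left <- (pair_dist(37, 41) + pair_dist(38, 40)) / 2
  right <- (pair_dist(43, 47) + pair_dist(44, 46)) / 2
  d <- (left + right) / 2
  bad <- !valid | !is.finite(d)
  d <- interpolate_flagged(ifelse(bad, NA_real_, d), bad)
  structure(list(distance = sampled_signal(d, fs = fps, label = "eyelid distance"),
                 left = left, right = right, interpolated = bad),
            class = "eyelid_trace")
}

#' @export
print.eyelid_trace <- function(x, ...) {
  cat(sprintf("<eyelid_trace> %d frames @ %g fps, %d interpolated\n",
              length(x$distance$values), x$distance$fs, sum(x$interpolated)))
  invisible(x)
}

#' Quadratic-mean (RMS) blink threshold
#'
#' `sqrt(mean(x^2))` of the band-passed eyelid-distance trace over the
#' experimental condition, excluding the filter-transient samples at each
#' end.
#'
#' @param filtered The 1--3 Hz band-passed trace, a [sampled_signal()].
#' @param transient_s Additional guard interval (seconds) excluded at
#'   each end on top of the filter's own transient flag.
#' @return The RMS threshold in signal units.
#' @export
rms_threshold <- function(filtered, transient_s = 0) {
  stopifnot(is_sampled_signal(filtered))
  m <- max(transient_samples(filtered), round(transient_s * filtered$fs))
  v <- filtered$values
  if (2 * m >= length(v)) m <- 0L
  core <- v[(m + 1):(length(v) - m)]
  if (!length(core)) stop("empty signal", call. = FALSE)
  sqrt(mean(core^2))
}

# Scale of the filtered-trace noise floor, robust to the (one-sided,
# positive-going in closure direction) blink mass. A first pass with the
# RMS threshold locates candidate blinks; samples within +-0.9 s of
# clearly supra-threshold events are masked and the scale is the
# lower-half MAD of the remainder. When blinks cover most of the trace
# the minimum over 4-s chunks is used instead.
lower_half_scale <- function(v) {
  med <- stats::median(v)
  below <- v[v < med]
  if (!length(below)) return(0)
  1.4826 * stats::median(med - below)
}

chunk_scales <- function(v, fs, chunk_s = 4) {
  n <- length(v)
  k <- max(1L, floor(n / (chunk_s * fs)))
  idx <- split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
  vapply(idx, function(i) lower_half_scale(v[i]), numeric(1))
}

estimate_noise_floor <- function(y, fs, core, th_rms) {
  cs <- chunk_scales(y[core], fs)
  sig0 <- unname(stats::quantile(cs, 0.25))
  pk0 <- pick_excursion_peaks(y, max(th_rms, 1e-8), fs,
                              margin = min(core) - 1L)
  big <- pk0[y[pk0] >= max(1.5 * th_rms, 4 * sig0)]
  mask <- rep(FALSE, length(y))
  r <- round(0.9 * fs)
  for (p in big) mask[max(1L, p - r):min(length(y), p + r)] <- TRUE
  un <- y[core][!mask[core]]
  if (length(un) >= 0.2 * length(core)) lower_half_scale(un) else min(cs)
}

# Candidate event peaks: contiguous excursions of y above th, split at
# internal valleys dropping below half the smaller adjacent local
# maximum (so a long plateau stays one event but two blinks whose
# responses merge are separated); ringing side lobes of the band-pass
# are removed by a neighbourhood-dominance gate (a peak must reach
# `dom_frac` of the largest peak within +-`dom_win_s`); finally a
# refractory prune keeps the larger of any two peaks closer than
# `refractory_s`. Peaks inside the `margin` edge region are discarded.
pick_excursion_peaks <- function(y, th, fs, margin, refractory_s = 0.2,
                                 dom_win_s = 1.0, dom_frac = 0.35) {
  above <- y > th
  d <- diff(c(FALSE, above, FALSE))
  st <- which(d == 1)
  en <- which(d == -1) - 1L
  if (!length(st)) return(integer(0))
  pk <- integer(0)
  for (k in seq_along(st)) {
    seg <- y[st[k]:en[k]]
    lm <- if (length(seg) >= 3L) which(diff(sign(diff(seg))) == -2) + 1L
          else integer(0)
    if (length(lm) < 2L) {
      pk <- c(pk, st[k] - 1L + which.max(seg))
      next
    }
    sel <- lm[1]
    for (j in lm[-1]) {
      valley <- min(seg[sel[length(sel)]:j])
      if (valley < 0.5 * min(seg[sel[length(sel)]], seg[j])) {
        sel <- c(sel, j)
      } else if (seg[j] > seg[sel[length(sel)]]) {
        sel[length(sel)] <- j
      }
    }
    pk <- c(pk, st[k] - 1L + sel)
  }
  pk <- pk[pk > margin & pk <= length(y) - margin]
  if (!length(pk)) return(integer(0))
  amp <- y[pk]
  dom <- vapply(seq_along(pk), function(i) {
    amp[i] >= dom_frac * max(amp[abs(pk - pk[i]) <= dom_win_s * fs])
  }, logical(1))
  pk <- pk[dom]
  amp <- amp[dom]
  keep <- rep(TRUE, length(pk))
  taken <- integer(0)
  for (i in order(amp, decreasing = TRUE)) {
    if (length(taken) && any(abs(pk[i] - taken) < refractory_s * fs)) {
      keep[i] <- FALSE
    } else {
      taken <- c(taken, pk[i])
    }
  }
  sort(pk[keep])
}

#' Detect blinks in the band-passed eyelid-distance trace
#'
#' A blink closes the eye, so the band-passed trace swings negative; the
#' detector thresholds the closure direction (`-x`) at the quadratic-mean
#' threshold of the condition. To keep the event count stable it also
#' (i) requires events to clear a robust noise floor (guarding against
#' spurious crossings when blinks are sparse and the RMS is small),
#' (ii) suppresses the band-pass filter's ringing side lobes via a
#' neighbourhood-dominance gate, (iii) splits excursions containing two
#' distinct blink responses, and (iv) enforces a 200 ms refractory
#' period. Events inside the filter-transient edges are discarded.
#'
#' @param filtered The 1--3 Hz band-passed eyelid trace (order-2
#'   Butterworth by default, see [ebr_video_pipeline()]).
#' @param threshold The RMS threshold from [rms_threshold()] (>= 0).
#' @param refractory_s Refractory period (default 0.2 s).
#' @param noise_floor_mult Multiple of the robust noise scale an event
#'   must clear (default 4.6).
#' @param transient_s Edge guard in seconds (default 3.5; the order-2
#'   band-pass settles in about 3 s at 30 fps).
#' @return A `blink_events` data frame (see [detect_blinks_eog()]);
#'   `correlation` is `NA` for this detector.
#' @export
detect_blinks_video <- function(filtered, threshold, refractory_s = 0.2,
                                noise_floor_mult = 4.6, transient_s = 3.5) {
  stopifnot(is_sampled_signal(filtered))
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number", call. = FALSE)
  }
  fs <- filtered$fs
  y <- -filtered$values
  m <- max(transient_samples(filtered), round(transient_s * fs))
  if (2 * m >= length(y)) m <- 0L
  core <- (m + 1):(length(y) - m)
  sig <- estimate_noise_floor(y, fs, core, threshold)
  th <- max(threshold, noise_floor_mult * sig, 1e-8)
  pk <- pick_excursion_peaks(y, th, fs, margin = m,
                             refractory_s = refractory_s)
  blink_events(filtered$t0 + (pk - 1) / fs, y[pk],
               duration_s = signal_duration(filtered))
}

#' Video eye-blink-rate pipeline: eyelid trace to blink events
#'
#' Band-pass the eyelid-distance trace to 1--3 Hz, compute the
#' quadratic-mean threshold over the condition, detect blink events, and
#' report the blink rate. The band-pass is an order-2 zero-phase
#' Butterworth: the 1--3 Hz band is only two octaves wide and a steeper
#' roll-off rings strongly on the sharp closure transients, multiplying
#' threshold crossings per blink.
#'
#' @param eyelid An `eyelid_trace` from [eyelid_distance()], or a
#'   [sampled_signal()] of eyelid distances in pixels.
#' @param band The noise-removal band (default 1--3 Hz, order 2).
#' @param transient_s Edge guard passed to the detector and threshold.
#' @return A list with `events` (`blink_events`), `ebr` (blinks/min),
#'   `threshold` and `filtered`.
#' @export
ebr_video_pipeline <- function(eyelid, band = bandpass_spec(1, 3, 2),
                               transient_s = 3.5) {
  x <- if (inherits(eyelid, "eyelid_trace")) eyelid$distance else eyelid
  stopifnot(is_sampled_signal(x))
  filtered <- bandpass(x, band)
  thr <- rms_threshold(filtered, transient_s = transient_s)
  events <- detect_blinks_video(filtered, thr, transient_s = transient_s)
  list(events = events, ebr = compute_ebr(events), threshold = thr,
       filtered = filtered)
}
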