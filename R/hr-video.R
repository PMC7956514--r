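#' Cheek ROI colour traces
#'
#' Per-frame spatial means of the R, G, B channels in the left and right
#' cheek regions of interest. Channel values are either 8-bit ([0, 255])
#' or normalised ([0, 1]); the two cheeks must have the same length.
#'
#' @param r_left,g_left,b_left,r_right,g_right,b_right Per-frame channel
#'   means.
#' @param fps Video frame rate, Hz.
#' @param roi_geometry Optional per-frame ROI rectangles, kept for audit.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(r_left, g_left, b_left, r_right, g_right, b_right,
                      fps, roi_geometry = NULL) {
  n <- length(r_left)
  stopifnot(length(r_right) == n, length(g_left) == n, length(b_left) == n,
            length(g_right) == n, length(b_right) == n, fps > 0)
  structure(list(r = cbind(left = r_left, right = r_right),
                 g = cbind(left = g_left, right = g_right),
                 b = cbind(left = b_left, right = b_right),
                 fps = fps, roi_geometry = roi_geometry),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace> %d frames @ %g fps, 2 cheek ROIs\n",
              nrow(x$r), x$fps))
  invisible(x)
}

#' Extract cheek ROI traces from video frames
#'
#' The cheek rectangles sit below each eye with the medial edge at the
#' nose-tip landmark column; size scales with the inter-ocular distance
#' (IOD): width 0.45 IOD, height 0.35 IOD, top edge 0.25 IOD below the
#' eye centre. Per frame and per ROI, the spatial mean of each colour
#' channel is recorded.
#'
#' @param frames List of video frames, each an `h x w x 3` numeric array.
#' @param landmarks Landmark data frame (see [eyelid_distance()]).
#' @param fps Frame rate, Hz.
#' @param min_valid_frac Minimum fraction of frames with valid landmarks
#'   (default 0.9); below it a quality error lists the gaps.
#' @param width_iod,height_iod,drop_iod ROI geometry constants as
#'   fractions of the inter-ocular distance.
#' @return An [roi_trace()].
#' @export
extract_roi_traces <- function(frames, landmarks, fps = 30,
                               min_valid_frac = 0.9,
                               width_iod = 0.45, height_iod = 0.35,
                               drop_iod = 0.25) {
  stopifnot(is.list(frames), is.data.frame(landmarks),
            length(frames) == nrow(landmarks))
  valid <- as.logical(landmarks$valid)
  if (mean(valid) < min_valid_frac) {
    gaps <- which(!valid)
    stop(sprintf("only %.0f%% of frames have valid landmarks (need %.0f%%); invalid frames: %s%s",
                 100 * mean(valid), 100 * min_valid_frac,
                 paste(utils::head(gaps, 20), collapse = ","),
                 if (length(gaps) > 20) ",..." else ""), call. = FALSE)
  }
  eye_centre <- function(i, idx) {
    c(mean(vapply(idx, function(j) landmarks[[paste0("x", j)]][i], numeric(1))),
      mean(vapply(idx, function(j) landmarks[[paste0("y", j)]][i], numeric(1))))
  }
  out <- matrix(NA_real_, nrow = length(frames), ncol = 6)
  for (i in seq_along(frames)) {
    if (!valid[i]) next
    fr <- frames[[i]]
    h <- dim(fr)[1]; w <- dim(fr)[2]
    le <- eye_centre(i, 36:41)
    re <- eye_centre(i, 42:47)
    nose_x <- landmarks[["x30"]][i]
    iod <- sqrt(sum((le - re)^2))
    top <- mean(c(le[2], re[2])) + drop_iod * iod
    roi_mean <- function(x0, x1) {
      cols <- max(1L, round(x0)):min(w, round(x1))
      rows <- max(1L, round(top)):min(h, round(top + height_iod * iod))
      vapply(1:3, function(ch) mean(fr[rows, cols, ch]), numeric(1))
    }
    left <- roi_mean(nose_x - 0.05 * iod - width_iod * iod, nose_x - 0.05 * iod)
    right <- roi_mean(nose_x + 0.05 * iod, nose_x + 0.05 * iod + width_iod * iod)
    out[i, ] <- c(left, right)
  }
  for (j in 1:6) out[, j] <- interpolate_flagged(out[, j], !valid)
  roi_trace(r_left = out[, 1], g_left = out[, 2], b_left = out[, 3],
            r_right = out[, 4], g_right = out[, 5], b_right = out[, 6],
            fps = fps)
}

# In-band (cardiac) to out-of-band power ratio of a candidate component.
# Frequencies below `floor_hz` are excluded from the out-of-band mass:
# slow illumination drift is removed by the dedicated detrending stage
# and must not penalise a component that carries both drift and pulse.
inband_power_ratio <- function(v, fps, band = c(0.6, 2.2), floor_hz = 0.25) {
  sp <- power_spectrum(sampled_signal(v, fps))
  f <- sp$freqs_hz
  ib <- sum(sp$power[f >= band[1] & f <= band[2]])
  ob <- sum(sp$power[f >= floor_hz & (f < band[1] | f > band[2])])
  ib / (ob + 1e-12)
}

#' PCA cleanup of the red-channel cheek traces
#'
#' Principal components of the standardised left/right red sub-traces.
#' The returned component is the one whose power spectrum has the
#' greatest in-band (0.6--2.2 Hz) to out-of-band power ratio -- the
#' cardiac pulse is common to both cheeks, while sensor noise is not --
#' with its sign fixed to correlate positively with the mean red trace.
#' With a single red trace the trace itself is returned with a fallback
#' flag.
#'
#' @param trace An [roi_trace()], or a matrix with one red sub-trace per
#'   column.
#' @param fps Frame rate (taken from the `roi_trace` when omitted).
#' @param band Cardiac band used for component selection.
#' @return A [sampled_signal()] with attributes `component` (index of the
#'   selected component) and `fallback` (TRUE when PCA was skipped).
#' @export
pca_clean <- function(trace, fps = NULL, band = c(0.6, 2.2)) {
  if (inherits(trace, "roi_trace")) {
    m <- trace$r
    fps <- trace$fps
  } else {
    m <- as.matrix(trace)
    if (is.null(fps)) stop("fps required when not passing an roi_trace",
                           call. = FALSE)
  }
  if (ncol(m) < 2L) {
    out <- sampled_signal(as.numeric(m[, 1]), fps, label = "red (no PCA)")
    attr(out, "fallback") <- TRUE
    return(out)
  }
  if (nrow(m) <= 100L) {
    stop("need more than 100 frames for PCA cleanup", call. = FALSE)
  }
  ms <- scale(m)
  ms[, apply(m, 2, stats::sd) == 0] <- 0  # constant sub-trace guard
  pc <- stats::prcomp(ms, center = FALSE, scale. = FALSE)
  ratios <- apply(pc$x, 2, inband_power_ratio, fps = fps, band = band)
  j <- which.max(ratios)
  comp <- pc$x[, j]
  ref <- rowMeans(m)
  if (stats::sd(comp) > 0 && stats::sd(ref) > 0 &&
      stats::cor(comp, ref) < 0) {
    comp <- -comp
  }
  out <- sampled_signal(comp, fps, label = sprintf("red PC%d", j))
  attr(out, "component") <- j
  attr(out, "fallback") <- FALSE
  out
}

#' Smoothness-priors detrending
#'
#' Removes the low-frequency trend estimated by regularised least
#' squares with a second-difference penalty: the trend is
#' `(I + lambda^2 t(D2) D2)^{-1} x` with `D2` the second-order difference
#' operator, and the detrended signal is `x - trend`. The system is
#' solved sparsely (banded), which is exact -- a dense solve gives the
#' same answer to machine precision.
#'
#' The detrender acts as a high-pass filter whose half-power cutoff is
#' approximately `fs / (2 * pi * sqrt(lambda))`. The default therefore
#' derives `lambda` from the target cutoff frequency (0.060 Hz, the slow
#' illumination-drift boundary) and the signal's sampling rate, so the
#' same physical cutoff applies at any frame rate; a fixed `lambda` can
#' be supplied instead.
#'
#' @param x A [sampled_signal()] of length >= 3.
#' @param spec A [detrend_spec()].
#' @return Detrended [sampled_signal()].
#' @export
detrend_smoothness_priors <- function(x, spec = detrend_spec()) {
  stopifnot(is_sampled_signal(x), inherits(spec, "detrend_spec"))
  n <- length(x$values)
  if (n < 3L) stop("need at least 3 samples to detrend", call. = FALSE)
  lam <- detrend_lambda(spec, x$fs)
  if (!is.finite(lam) || lam <= 0) stop("lambda must be > 0", call. = FALSE)
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  a <- Matrix::Diagonal(n) + lam^2 * Matrix::crossprod(d2)
  trend <- as.numeric(Matrix::solve(a, x$values))
  # one step of iterative refinement: the system is ill-conditioned for
  # the large lambdas implied by low cutoffs
  resid <- x$values - as.numeric(a %*% trend)
  trend <- trend + as.numeric(Matrix::solve(a, resid))
  out <- sampled_signal(x$values - trend, fs = x$fs, t0 = x$t0,
                        label = x$label)
  attr(out, "transient_samples") <- transient_samples(x)
  out
}

#' Detrending parameters
#'
#' @param lambda Smoothing parameter; `NULL` (default) derives it from
#'   `cutoff_hz` at the signal's sampling rate as
#'   `(fs / (2 * pi * cutoff_hz))^2`.
#' @param cutoff_hz Half-power cutoff of the implied high-pass, Hz
#'   (default 0.060).
#' @return An object of class `detrend_spec`.
#' @export
detrend_spec <- function(lambda = NULL, cutoff_hz = 0.060) {
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (cutoff_hz <= 0) stop("cutoff_hz must be > 0", call. = FALSE)
  structure(list(lambda = lambda, cutoff_hz = cutoff_hz),
            class = "detrend_spec")
}

detrend_lambda <- function(spec, fs) {
  if (!is.null(spec$lambda)) spec$lambda
  else (fs / (2 * pi * spec$cutoff_hz))^2
}

#' z-score normalisation
#'
#' `(x - mean(x)) / sd(x)` with the population SD (divisor N). A constant
#' input returns zeros with a degenerate flag rather than dividing by
#' zero.
#'
#' @param x A [sampled_signal()].
#' @return A [sampled_signal()] with attribute `degenerate`.
#' @export
zscore <- function(x) {
  stopifnot(is_sampled_signal(x))
  v <- x$values
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev == 0) {
    out <- sampled_signal(rep(0, length(v)), x$fs, x$t0, x$label)
    attr(out, "degenerate") <- TRUE
  } else {
    out <- sampled_signal((v - mu) / sdev, x$fs, x$t0, x$label)
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "transient_samples") <- transient_samples(x)
  out
}

#' Heart rate from one 100-frame window
#'
#' `bpm = 60 *` argmax of the zero-padded power spectrum restricted to
#' the cardiac band, refined by 3-point parabolic interpolation on log
#' power. At 30 fps a 100-frame window has a raw FFT resolution of
#' 0.3 Hz (18 bpm); zero padding plus parabolic interpolation brings the
#' pure-tone error below 1 bpm; a Hann taper applied to the segment
#' suppresses leakage from the negative-frequency image, which at only
#' ~4 cardiac cycles per window otherwise biases the interpolated peak
#' by several tenths of a bpm. The estimate is flagged invalid when the
#' in-band peak is not a clear local maximum inside the band (argmax on a
#' band edge) or lacks prominence (peak below `min_peak_ratio` times the
#' median in-band power).
#'
#' @param window A [sampled_signal()] (or numeric vector) of exactly
#'   `window_frames` samples.
#' @param fps Frame rate, Hz.
#' @param band Cardiac band (default 0.6--2.2 Hz).
#' @param n_fft FFT length (default 4096, >= 1024).
#' @param window_frames Required window length (default 100).
#' @param min_peak_ratio Prominence floor (default 5).
#' @return `bpm` (scalar) with attribute `valid`; `NA` with
#'   `valid = FALSE` when no credible in-band peak exists.
#' @export
hr_from_window <- function(window, fps, band = c(0.6, 2.2), n_fft = 4096,
                           window_frames = 100L, min_peak_ratio = 5) {
  v <- if (is_sampled_signal(window)) window$values else as.numeric(window)
  if (length(v) != window_frames) {
    stop(sprintf("window must hold exactly %d frames (got %d)",
                 window_frames, length(v)), call. = FALSE)
  }
  n <- length(v)
  v <- v * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  sp <- power_spectrum(sampled_signal(v, fps), n_fft = n_fft)
  f <- sp$freqs_hz
  p <- sp$power
  sel <- which(f >= band[1] & f <= band[2])
  i <- sel[which.max(p[sel])]
  invalid <- i == sel[1] || i == sel[length(sel)] ||
    p[i] < min_peak_ratio * stats::median(p[sel]) || p[i] <= 0
  if (invalid) {
    out <- NA_real_
    attr(out, "valid") <- FALSE
    return(out)
  }
  lp <- log(p[(i - 1):(i + 1)] + 1e-300)
  denom <- lp[1] - 2 * lp[2] + lp[3]
  delta <- if (denom < 0) 0.5 * (lp[1] - lp[3]) / denom else 0
  out <- 60 * (f[i] + delta * fps / n_fft)
  attr(out, "valid") <- TRUE
  out
}

#' Heart-rate series from a pulse signal
#'
#' Applies [hr_from_window()] over a 100-frame sliding window with a 1 s
#' hop and aggregates to 60 s resolution as the median of the valid
#' window estimates whose window starts in that minute. Minutes with
#' fewer than `min_valid_frac` valid windows are flagged invalid.
#'
#' @param x The normalised pulse signal, a [sampled_signal()].
#' @param fps Frame rate (taken from `x`).
#' @param window_frames Sliding-window length (default 100 frames).
#' @param hop_s Window hop (default 1 s).
#' @param resolution_s Output resolution (default 60 s).
#' @param min_valid_frac Minimum fraction of valid windows per minute.
#' @param ... Passed to [hr_from_window()].
#' @details Windows overlapping the filter-transient margins flagged by
#'   the preceding band-pass are skipped (unless that would leave no
#'   window at all).
#' @return An `hr_series` data frame (see [hr_from_peaks()]).
#' @export
hr_series_video <- function(x, fps = x$fs, window_frames = 100L, hop_s = 1,
                            resolution_s = 60, min_valid_frac = 0.5, ...) {
  stopifnot(is_sampled_signal(x))
  n <- length(x$values)
  if (n < window_frames) {
    stop(sprintf("signal too short: %d frames < %d-frame window",
                 n, window_frames), call. = FALSE)
  }
  m <- transient_samples(x)
  if (n - 2 * m < window_frames) m <- 0L
  starts <- seq(m + 1L, n - window_frames + 1L - m,
                by = max(1L, round(hop_s * fps)))
  est <- vapply(starts, function(s) {
    as.numeric(hr_from_window(x$values[s:(s + window_frames - 1L)], fps,
                              window_frames = window_frames, ...))
  }, numeric(1))
  mins <- floor((starts - 1) / fps / resolution_s)
  um <- sort(unique(mins))
  bpm <- valid <- numeric(length(um))
  for (k in seq_along(um)) {
    e <- est[mins == um[k]]
    ok <- is.finite(e)
    valid[k] <- mean(ok) >= min_valid_frac
    bpm[k] <- if (any(ok)) stats::median(e[ok]) else NA_real_
  }
  dur <- vapply(um, function(m) {
    min(resolution_s, n / fps - m * resolution_s)
  }, numeric(1))
  hr_series(window_start_s = x$t0 + um * resolution_s,
            window_duration_s = dur, bpm = bpm, valid = as.logical(valid))
}

#' Remote-photoplethysmography heart-rate pipeline
#'
#' Full video HR chain: cheek red traces -> PCA component selection ->
#' smoothness-priors detrending -> Hamming band-pass (128 taps,
#' 0.6--2.2 Hz) -> z-score -> windowed spectral-peak HR at 60 s
#' resolution.
#'
#' @param trace An [roi_trace()].
#' @param band Cardiac band, Hz.
#' @param fir_taps Hamming FIR length (default 128).
#' @param detrend A [detrend_spec()].
#' @param ... Passed to [hr_series_video()].
#' @return A list with `hr` (an `hr_series`) and `pulse` (the normalised
#'   pulse [sampled_signal()]).
#' @export
hr_video_pipeline <- function(trace, band = c(0.6, 2.2), fir_taps = 128L,
                              detrend = detrend_spec(), ...) {
  stopifnot(inherits(trace, "roi_trace"))
  x <- pca_clean(trace, band = band)
  x <- detrend_smoothness_priors(x, detrend)
  x <- bandpass(x, bandpass_spec(band[1], band[2], fir_taps,
                                 family = "hamming_fir"))
  x <- zscore(x)
  list(hr = hr_series_video(x, band = band, ...), pulse = x)
}
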