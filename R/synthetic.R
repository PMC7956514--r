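#' Simulation specification
#'
#' Ground-truth generator settings shared by all synthetic-signal
#' generators. A fixed `seed` makes every generator byte-identical
#' across runs.
#'
#' @param duration_s Recording duration, seconds (> 0).
#' @param fs Sampling rate for biosignals, Hz (default 256).
#' @param fps Frame rate for video-derived traces, Hz (default 30).
#' @param seed Integer RNG seed.
#' @param hr_bpm Heart rate in bpm: a constant in [40, 180], or a
#'   per-minute vector for a stepwise profile.
#' @param blink_rate_per_min Blink rate in [0, 60].
#' @param snr_db Signal-to-noise ratio in dB: the power of the clean
#'   physiological component over the power of the additive Gaussian
#'   noise.
#' @param drift_amplitude_ratio Amplitude of the common low-frequency
#'   illumination drift relative to the pulse amplitude (ROI traces).
#' @param rr_jitter Fractional beat-to-beat RR jitter (default 0.03).
#' @param blink_duration_s Range of closure durations, seconds.
#' @param edge_pad_s Event-free lead-in/lead-out of the recording,
#'   seconds; the pipelines' filter transients live here.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(duration_s, fs = 256, fps = 30, seed = 1L,
                     hr_bpm = 70, blink_rate_per_min = 15, snr_db = 20,
                     drift_amplitude_ratio = 0, rr_jitter = 0.03,
                     blink_duration_s = c(0.2, 0.35), edge_pad_s = 4) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (any(hr_bpm < 40 | hr_bpm > 180)) {
    stop("hr_bpm must lie in [40, 180]", call. = FALSE)
  }
  if (blink_rate_per_min < 0 || blink_rate_per_min > 60) {
    stop("blink_rate_per_min must lie in [0, 60]", call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs = fs, fps = fps,
                 seed = as.integer(seed), hr_bpm = hr_bpm,
                 blink_rate_per_min = blink_rate_per_min, snr_db = snr_db,
                 drift_amplitude_ratio = drift_amplitude_ratio,
                 rr_jitter = rr_jitter, blink_duration_s = blink_duration_s,
                 edge_pad_s = edge_pad_s),
            class = "sim_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

hann_bump <- function(duration_s, fs) {
  n <- max(3L, round(duration_s * fs))
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Blink onset times: Poisson process thinned to a 500 ms minimum
# inter-blink interval (simple, defensible physiology), restricted to
# the event-carrying core of the recording.
draw_blink_times <- function(duration_s, rate_per_min, pad_s,
                             min_spacing_s = 0.5) {
  lam <- rate_per_min / 60
  if (lam <= 0) return(numeric(0))
  cand <- cumsum(stats::rexp(ceiling(duration_s * lam * 3) + 20L, lam))
  cand <- cand + pad_s
  cand <- cand[cand < duration_s - pad_s]
  out <- numeric(0)
  for (tt in cand) {
    if (!length(out) || tt - out[length(out)] >= min_spacing_s) {
      out <- c(out, tt)
    }
  }
  out
}

qrs_kernel <- function(fs) {
  # narrow biphasic R spike flanked by smaller P and T bumps
  t <- seq(-0.35, 0.45, by = 1 / fs)
  r <- exp(-(t / 0.012)^2) - 0.35 * exp(-((t - 0.03) / 0.02)^2) -
    0.18 * exp(-((t + 0.03) / 0.025)^2)
  p <- 0.15 * exp(-((t + 0.18) / 0.03)^2)
  tw <- 0.30 * exp(-((t - 0.25) / 0.06)^2)
  w <- r + p + tw
  list(w = w / max(abs(w)), i_peak = which.max(abs(w)))
}

add_noise <- function(clean, snr_db, ref_power = mean(clean^2)) {
  if (!is.finite(snr_db)) return(clean)
  sdn <- sqrt(ref_power) / 10^(snr_db / 20)
  clean + stats::rnorm(length(clean), 0, sdn)
}

#' Synthetic single-lead ECG with known beat times
#'
#' A periodic QRS-like kernel train (biphasic R spike plus smaller P and
#' T bumps) at `RR = 60 / hr_bpm`, with optional fractional RR jitter,
#' plus additive Gaussian noise at `snr_db`. `hr_bpm` may be a
#' per-minute vector for a stepwise rate profile.
#'
#' @param spec A [sim_spec()].
#' @return List with `signal` (a [sampled_signal()]) and `truth`
#'   (R-peak times in seconds).
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs
    dur <- spec$duration_s
    n <- round(dur * fs)
    hr_at <- function(t) {
      i <- min(length(spec$hr_bpm), floor(t / 60) + 1L)
      spec$hr_bpm[i]
    }
    tp <- numeric(0)
    tcur <- 0.5
    while (tcur < dur - 0.5 + 1e-9) {
      tp <- c(tp, tcur)
      rr <- 60 / hr_at(tcur)
      jit <- if (spec$rr_jitter > 0) {
        stats::runif(1, -spec$rr_jitter, spec$rr_jitter)
      } else 0
      tcur <- tcur + rr * (1 + jit)
    }
    k <- qrs_kernel(fs)
    x <- numeric(n)
    for (tc in tp) {
      idx <- round(tc * fs) + 1L - (k$i_peak - 1L) + seq_along(k$w) - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + k$w[ok]
    }
    x <- add_noise(x, spec$snr_db)
    list(signal = sampled_signal(x, fs, label = "synthetic ECG"),
         truth = tp)
  })
}

#' Synthetic vertical EOG with blink deflections
#'
#' Gaussian baseline noise plus positive 300 ms Hann-bump blink
#' deflections at Poisson-thinned times (500 ms minimum spacing). The
#' noise level realises `snr_db` against the expected blink-component
#' power at the requested rate (so a realisation that happens to carry
#' few blinks still gets a sensible noise floor). A blink-free eyes-open
#' calibration segment with the identical noise level is returned
#' alongside, ready for threshold computation.
#'
#' @param spec A [sim_spec()]; uses `blink_rate_per_min`, `snr_db`,
#'   `edge_pad_s`.
#' @param calib_duration_s Length of the eyes-open calibration segment.
#' @param blink_times Optional externally supplied truth times (seconds);
#'   lets two modalities share one physiological truth.
#' @return List with `signal`, `calibration` (both [sampled_signal()])
#'   and `truth` (blink peak times, seconds).
#' @export
gen_eog <- function(spec, calib_duration_s = 30, blink_times = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  rate <- spec$blink_rate_per_min
  if (rate * spec$duration_s / 60 < 1) {
    warning("fewer than one blink expected over the recording",
            call. = FALSE)
  }
  with_seed(spec$seed, {
    fs <- spec$fs
    n <- round(spec$duration_s * fs)
    tb <- if (is.null(blink_times)) {
      draw_blink_times(spec$duration_s, rate, spec$edge_pad_s)
    } else {
      sort(blink_times)
    }
    bump <- hann_bump(0.3, fs)
    s <- numeric(n)
    for (tt in tb) {
      i <- round(tt * fs) + 1L - floor(length(bump) / 2) +
        seq_along(bump) - 1L
      ok <- i >= 1L & i <= n
      s[i[ok]] <- s[i[ok]] + bump[ok]
    }
    rate_ref <- if (rate > 0) rate else 15
    p_ref <- (rate_ref / 60) * 0.3 * mean(hann_bump(0.3, fs)^2)
    sdn <- sqrt(p_ref) / 10^(spec$snr_db / 20)
    sig <- s + stats::rnorm(n, 0, sdn)
    calib <- stats::rnorm(round(calib_duration_s * fs), 0, sdn)
    list(signal = sampled_signal(sig, fs, label = "synthetic EOG"),
         calibration = sampled_signal(calib, fs, label = "eyes-open EOG"),
         truth = tb)
  })
}

#' Synthetic eyelid-distance trace with closures
#'
#' Baseline eyelid aperture (6 px) with downward Hann-shaped closure
#' transients (durations drawn from `blink_duration_s`, depth 4 px) at
#' Poisson-thinned truth times, plus frame-to-frame landmark measurement
#' noise at `snr_db` (referenced to the expected closure-component power
#' at the requested rate).
#'
#' @param spec A [sim_spec()].
#' @param base_px Open-eye eyelid distance (default 6 px).
#' @param depth_px Closure depth (default 4 px).
#' @param blink_times Optional externally supplied truth times (seconds).
#' @return List with `trace` (a [sampled_signal()] at `fps`) and `truth`
#'   (closure centre times, seconds).
#' @export
gen_eyelid_trace <- function(spec, base_px = 6, depth_px = 4,
                             blink_times = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  rate <- spec$blink_rate_per_min
  if (rate * spec$duration_s / 60 < 1) {
    warning("fewer than one blink expected over the recording",
            call. = FALSE)
  }
  with_seed(spec$seed, {
    fps <- spec$fps
    n <- round(spec$duration_s * fps)
    tb <- if (is.null(blink_times)) {
      draw_blink_times(spec$duration_s, rate, spec$edge_pad_s)
    } else {
      sort(blink_times)
    }
    s <- numeric(n)
    for (tt in tb) {
      bl <- depth_px * hann_bump(stats::runif(1, spec$blink_duration_s[1],
                                              spec$blink_duration_s[2]), fps)
      i <- round(tt * fps) + 1L - floor(length(bl) / 2) + seq_along(bl) - 1L
      ok <- i >= 1L & i <= n
      s[i[ok]] <- s[i[ok]] - bl[ok]
    }
    rate_ref <- if (rate > 0) rate else 15
    mean_dur <- mean(spec$blink_duration_s)
    p_ref <- (rate_ref / 60) * mean_dur * 0.375 * depth_px^2
    sdn <- sqrt(p_ref) / 10^(spec$snr_db / 20)
    x <- pmax(0, base_px + s + stats::rnorm(n, 0, sdn))
    list(trace = sampled_signal(x, fps, label = "synthetic eyelid distance"),
         truth = tb)
  })
}

#' Synthetic cheek-ROI RGB traces with embedded cardiac pulse
#'
#' The red channel of both cheeks carries a common pulse at
#' `hr_bpm / 60` Hz with a second harmonic at 30% amplitude (so the
#' spectral-peak picker is exercised against harmonic confusion), a
#' common low-frequency illumination drift (three random tones in
#' 0.02--0.1 Hz, RMS `drift_amplitude_ratio` times the pulse RMS scaled
#' to amplitude), and independent per-cheek sensor noise at `snr_db`
#' relative to the pulse power. Green and blue carry only base level,
#' drift and noise. A stepwise per-minute `hr_bpm` profile is supported
#' through phase integration.
#'
#' @param spec A [sim_spec()].
#' @param base_level Mean channel value (default 120, 8-bit scale).
#' @param pulse_amplitude Pulse amplitude in channel units (default 1).
#' @return List with `trace` (an [roi_trace()]) and `truth_bpm`
#'   (per-minute true heart rate).
#' @export
gen_roi_trace <- function(spec, base_level = 120, pulse_amplitude = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  if (any(spec$hr_bpm < 36 | spec$hr_bpm > 132)) {
    warning("heart rate outside the 0.6-2.2 Hz detection band",
            call. = FALSE)
  }
  with_seed(spec$seed, {
    fps <- spec$fps
    n <- round(spec$duration_s * fps)
    t <- (0:(n - 1)) / fps
    minute <- pmin(length(spec$hr_bpm), floor(t / 60) + 1L)
    f_inst <- spec$hr_bpm[minute] / 60
    phase <- 2 * pi * cumsum(f_inst) / fps
    a <- pulse_amplitude
    ph0 <- stats::runif(2, 0, 2 * pi)
    pulse <- a * sin(phase + ph0[1]) + 0.3 * a * sin(2 * phase + ph0[2])
    fd <- stats::runif(3, 0.02, 0.1)
    phd <- stats::runif(3, 0, 2 * pi)
    drift <- rowSums(vapply(1:3, function(i) sin(2 * pi * fd[i] * t + phd[i]),
                            numeric(n)))
    dsd <- stats::sd(drift)
    if (dsd > 0) {
      drift <- drift / dsd * spec$drift_amplitude_ratio * a / sqrt(2)
    }
    sdn <- sqrt(mean(pulse^2)) / 10^(spec$snr_db / 20)
    noise <- function() stats::rnorm(n, 0, sdn)
    tr <- roi_trace(
      r_left = base_level + pulse + drift + noise(),
      g_left = base_level + drift + noise(),
      b_left = base_level + drift + noise(),
      r_right = base_level + pulse + drift + noise(),
      g_right = base_level + drift + noise(),
      b_right = base_level + drift + noise(),
      fps = fps)
    n_min <- ceiling(spec$duration_s / 60)
    truth <- spec$hr_bpm[pmin(length(spec$hr_bpm), seq_len(n_min))]
    list(trace = tr, truth_bpm = truth)
  })
}

#' Synthetic landmark frames with a fixed face geometry
#'
#' Builds a 68-point landmark table for a frontal face in a
#' `width x height` frame, with the eyelid aperture of both eyes driven
#' by `aperture_px` (one value per frame). Useful for testing the
#' eyelid-distance extraction without a video.
#'
#' @param aperture_px Per-frame eyelid aperture in pixels.
#' @param width,height Frame size (default 640 x 480).
#' @param valid Logical per-frame validity flags (default all TRUE).
#' @return Landmark data frame (columns `frame_index`, `x0..y67`,
#'   `valid`).
#' @export
gen_landmark_frames <- function(aperture_px, width = 640, height = 480,
                                valid = rep(TRUE, length(aperture_px))) {
  n <- length(aperture_px)
  pts <- matrix(0, nrow = 68, ncol = 2)
  cx <- width / 2
  cy <- height / 2
  # jaw 0-16, brows 17-26, nose 27-35: static, schematic
  pts[1:17, 1] <- seq(cx - 100, cx + 100, length.out = 17)
  pts[1:17, 2] <- cy + 80 + 40 * sin(seq(0, pi, length.out = 17))
  pts[18:27, 1] <- seq(cx - 70, cx + 70, length.out = 10)
  pts[18:27, 2] <- cy - 70
  pts[28:36, 1] <- cx
  pts[28:36, 2] <- seq(cy - 50, cy + 10, length.out = 9)
  eye <- function(ex, ey, ap) {
    rbind(c(ex - 20, ey),
          c(ex - 8, ey - ap / 2), c(ex + 8, ey - ap / 2),
          c(ex + 20, ey),
          c(ex + 8, ey + ap / 2), c(ex - 8, ey + ap / 2))
  }
  pts[49:68, 1] <- cx + 30 * cos(seq(0, 2 * pi, length.out = 20))
  pts[49:68, 2] <- cy + 60 + 12 * sin(seq(0, 2 * pi, length.out = 20))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts
    p[37:42, ] <- eye(cx - 45, cy - 40, aperture_px[i])
    p[43:48, ] <- eye(cx + 45, cy - 40, aperture_px[i])
    row <- c(frame_index = i - 1L, as.vector(t(p)), valid = as.integer(valid[i]))
    out[[i]] <- row
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("frame_index",
                 as.vector(t(outer(0:67, c("x", "y"),
                                   function(i, a) paste0(a, i)))),
                 "valid")
  df
}
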