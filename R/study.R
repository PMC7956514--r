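#' Virtual device-agreement study
#'
#' Runs the full validation experiment on synthetic participants: for
#' each virtual subject, paired "laboratory" (EOG, ECG) and "video"
#' (eyelid-distance, cheek-ROI) recordings are generated from one shared
#' physiological truth per condition -- a resting (nominal) and an active
#' (non-nominal) state plus a one-minute baseline -- and every recording
#' is pushed through its estimation pipeline. The result feeds the
#' statistics layer: baseline-normalised method agreement (paired tests),
#' per-minute repeated-measures correlation between technologies, and
#' percentage differences.
#'
#' The state manipulation follows the usual psychophysiology: engagement
#' lowers the blink rate (here by 4--8 blinks/min) and raises heart rate
#' (by 5--10 bpm). Heart rate also drifts minute-to-minute as a small
#' random walk so the repeated-measures correlation has within-subject
#' variance to work with.
#'
#' @param n_subjects Number of virtual participants (default 15).
#' @param seed RNG seed for the whole study.
#' @param condition_s Condition duration, seconds (default 120).
#' @param baseline_s Baseline duration, seconds (default 60).
#' @param snr_db Recording quality for all modalities (default 15).
#' @param drift_amplitude_ratio Illumination drift in the ROI traces
#'   relative to pulse amplitude (default 2).
#' @return A list:
#' \describe{
#'   \item{measures}{long condition-measure table (one row per subject x
#'     task x condition x method x metric).}
#'   \item{per_minute}{per-minute paired estimates by method and metric.}
#'   \item{report}{[compare_methods()] output on `measures`.}
#'   \item{rmcorr_ebr, rmcorr_hr}{[rmcorr()] results between
#'     technologies on the per-minute values.}
#' }
#' @export
agreement_study <- function(n_subjects = 15, seed = 1, condition_s = 120,
                            baseline_s = 60, snr_db = 15,
                            drift_amplitude_ratio = 2) {
  pad <- 4
  measures <- list()
  per_min <- list()
  eog_band <- bandpass_spec(2, 10, 5)

  run_ebr <- function(rate, dur, seed_lab, seed_vid) {
    # one truth, two modalities
    truth <- with_seed(seed_lab * 7919L + 11L,
                       draw_blink_times(dur, rate, pad))
    sp_lab <- sim_spec(dur, seed = seed_lab, blink_rate_per_min = rate,
                       snr_db = snr_db, edge_pad_s = pad)
    sp_vid <- sim_spec(dur, seed = seed_vid, blink_rate_per_min = rate,
                       snr_db = snr_db, edge_pad_s = pad)
    eog <- gen_eog(sp_lab, blink_times = truth)
    eyelid <- gen_eyelid_trace(sp_vid, blink_times = truth)
    xf <- bandpass(eog$signal, eog_band)
    thr <- compute_blink_threshold(bandpass(eog$calibration, eog_band))
    ev_lab <- detect_blinks_eog(xf, thr, blink_template(sp_lab$fs),
                                band = eog_band)
    ev_vid <- ebr_video_pipeline(eyelid$trace)$events
    list(lab = ev_lab, vid = ev_vid, dur = dur)
  }

  run_hr <- function(hr_profile, dur, seed_lab, seed_vid) {
    sp_lab <- sim_spec(dur, seed = seed_lab, hr_bpm = hr_profile,
                       snr_db = snr_db)
    sp_vid <- sim_spec(dur, seed = seed_vid, hr_bpm = hr_profile,
                       snr_db = snr_db,
                       drift_amplitude_ratio = drift_amplitude_ratio)
    ecg <- gen_ecg(sp_lab)
    roi <- gen_roi_trace(sp_vid)
    hr_lab <- hr_ecg_pipeline(ecg$signal)$hr
    hr_vid <- hr_video_pipeline(roi$trace)$hr
    list(lab = hr_lab, vid = hr_vid)
  }

  minute_counts <- function(ev, dur) {
    tp <- ev$t_peak_s
    n_min <- floor(dur / 60)
    vapply(seq_len(n_min) - 1L, function(m) {
      sum(tp >= m * 60 & tp < (m + 1) * 60)
    }, numeric(1))
  }

  with_seed(seed, {
    subj_par <- data.frame(
      id = sprintf("S%02d", seq_len(n_subjects)),
      ebr_base = stats::runif(n_subjects, 10, 18),
      ebr_drop = stats::runif(n_subjects, 4, 8),
      hr_base = stats::runif(n_subjects, 60, 75),
      hr_rise = stats::runif(n_subjects, 5, 10))
  })

  for (i in seq_len(n_subjects)) {
    sp <- subj_par[i, ]
    sd_i <- seed * 1000L + i * 17L
    ebr_rate <- c(baseline = sp$ebr_base,
                  nominal = sp$ebr_base,
                  non_nominal = max(3, sp$ebr_base - sp$ebr_drop))
    hr_walk <- function(start, n_min, s) {
      with_seed(s, pmin(132, pmax(45, cumsum(c(start,
        stats::rnorm(n_min - 1, 0, 2))))))
    }
    hr_prof <- list(baseline = hr_walk(sp$hr_base, 1, sd_i + 1L),
                    nominal = hr_walk(sp$hr_base, condition_s / 60, sd_i + 2L),
                    non_nominal = hr_walk(sp$hr_base + sp$hr_rise,
                                          condition_s / 60, sd_i + 3L))
    for (cond in c("baseline", "nominal", "non_nominal")) {
      dur <- if (cond == "baseline") baseline_s + 2 * pad else condition_s + 2 * pad
      eb <- run_ebr(ebr_rate[[cond]], dur, sd_i + match(cond, names(ebr_rate)),
                    sd_i + 100L + match(cond, names(ebr_rate)))
      hr <- run_hr(hr_prof[[cond]], dur - 2 * pad,
                   sd_i + 200L + match(cond, names(ebr_rate)),
                   sd_i + 300L + match(cond, names(ebr_rate)))
      measures[[length(measures) + 1L]] <- data.frame(
        subject_id = sp$id, task = "VS", condition = cond,
        method = c("laboratory", "video", "laboratory", "video"),
        metric = c("EBR", "EBR", "HR", "HR"),
        value = c(compute_ebr(eb$lab, dur), compute_ebr(eb$vid, dur),
                  mean(hr$lab$bpm[hr$lab$valid]),
                  mean(hr$vid$bpm[hr$vid$valid])))
      if (cond != "baseline") {
        mc_lab <- minute_counts(eb$lab, dur)
        mc_vid <- minute_counts(eb$vid, dur)
        n_min <- min(length(mc_lab), length(mc_vid),
                     sum(hr$lab$valid), sum(hr$vid$valid))
        per_min[[length(per_min) + 1L]] <- data.frame(
          subject_id = sp$id, condition = cond,
          minute = seq_len(n_min) - 1L,
          ebr_lab = mc_lab[seq_len(n_min)],
          ebr_vid = mc_vid[seq_len(n_min)],
          hr_lab = hr$lab$bpm[seq_len(n_min)],
          hr_vid = hr$vid$bpm[seq_len(n_min)])
      }
    }
  }
  measures <- do.call(rbind, measures)
  per_min <- do.call(rbind, per_min)
  list(measures = measures,
       per_minute = per_min,
       report = compare_methods(measures),
       rmcorr_ebr = rmcorr(per_min$subject_id, per_min$ebr_lab,
                           per_min$ebr_vid),
       rmcorr_hr = rmcorr(per_min$subject_id, per_min$hr_lab,
                          per_min$hr_vid))
}
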