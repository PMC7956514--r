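#' Baseline subtraction
#'
#' Normalises a condition measurement by subtracting the same subject's
#' resting-baseline value, making distributions comparable across sensor
#' technologies before testing.
#'
#' @param value Condition measurement (finite scalar or vector).
#' @param baseline Matching baseline measurement(s).
#' @return `value - baseline`.
#' @export
baseline_normalize <- function(value, baseline) {
  if (any(!is.finite(value)) || any(!is.finite(baseline))) {
    stop("missing baseline or value", call. = FALSE)
  }
  value - baseline
}

# Exact two-sided signed-rank p-value by dynamic programming over the
# achievable rank sums. Midranks (ties) are handled by working on
# doubled ranks, which are integers. Complexity O(n * sum(2r)) --
# comfortably fast for the n <= 25 exact regime.
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s+1] = #assignments with 2*W+ == s
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w_plus)
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences. Zero differences are
#' dropped; ties get midranks. For `n <= exact_max` non-zero differences
#' the null distribution of the positive-rank sum is enumerated exactly
#' (dynamic programming, valid under ties); otherwise the normal
#' approximation with continuity correction and tie-corrected variance
#' is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for the exact enumeration (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w_plus)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w_plus, p_value = p, n = n, method = method)
}

#' Normality-gated paired comparison
#'
#' Shapiro--Wilk on the paired differences decides the test: when
#' normality is not rejected at `alpha` a two-sided paired t-test is
#' used, otherwise the two-sided Wilcoxon signed-rank test
#' ([wilcoxon_signed_rank()]). With `gate = "both"` the gate instead
#' requires both samples to pass Shapiro--Wilk.
#'
#' @param x,y Paired numeric vectors (equal length, n >= 5).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @param gate `"differences"` (default) or `"both"`.
#' @return An object of class `paired_test_result`: `test_name`
#'   (`"t_paired"` or `"wilcoxon_signed_rank"`), `statistic`, `p_value`,
#'   `n_pairs`, `normality_p_values`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05,
                           gate = c("differences", "both")) {
  gate <- match.arg(gate)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(test_name = "degenerate", statistic = NA_real_,
                          p_value = 1, n_pairs = n,
                          normality_p_values = c(NA_real_, NA_real_),
                          degenerate = TRUE),
                     class = "paired_test_result"))
  }
  norm_p <- if (gate == "differences") {
    c(stats::shapiro.test(d)$p.value, NA_real_)
  } else {
    c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  }
  normal_ok <- all(norm_p >= alpha, na.rm = TRUE)
  if (normal_ok) {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(test_name = "t_paired",
                statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- wilcoxon_signed_rank(x, y)
    res <- list(test_name = "wilcoxon_signed_rank",
                statistic = wt$statistic, p_value = wt$p_value)
  }
  structure(c(res, list(n_pairs = n, normality_p_values = norm_p,
                        degenerate = FALSE)),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test> %s: statistic %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' Repeated-measures correlation
#'
#' The common within-subject association between two variables, from the
#' analysis-of-covariance model with subject-specific intercepts and a
#' shared slope. With `xc`, `yc` the within-subject centred variables,
#' the shared slope is `sum(xc*yc)/sum(xc^2)` and
#' `r = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))`, which
#' reduces to the Pearson correlation of the centred variables. Degrees
#' of freedom are `N_obs - N_subjects - 1`;
#' `p = 2 * pt(-|r| * sqrt(dof / (1 - r^2)), dof)`.
#'
#' Subjects with constant `x` contribute no slope information (their
#' centred values are zero); if no subject varies, an error is raised.
#'
#' @param subject Subject identifier (factor or vector).
#' @param x,y Paired observations.
#' @return An object of class `rmcorr_result`: `r`, `dof`, `p_value`,
#'   `n_subjects`, `n_obs`.
#' @export
rmcorr <- function(subject, x, y) {
  stopifnot(length(subject) == length(x), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  subject <- factor(subject[ok])
  x <- x[ok]; y <- y[ok]
  if (nlevels(subject) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (any(table(subject) < 2L)) {
    stop("every subject needs at least 2 paired observations", call. = FALSE)
  }
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  ssx <- sum(xc^2)
  if (ssx == 0) stop("no within-subject variation in x", call. = FALSE)
  slope <- sum(xc * yc) / ssx
  ss_measure <- slope^2 * ssx
  ss_error <- sum((yc - slope * xc)^2)
  r <- sign(slope) * sqrt(ss_measure / (ss_measure + ss_error))
  if (!is.finite(r)) r <- 0
  dof <- length(x) - nlevels(subject) - 1L
  if (dof < 1L) stop("not enough observations for the model", call. = FALSE)
  p <- if (abs(r) >= 1) 0 else {
    tval <- abs(r) * sqrt(dof / (1 - r^2))
    2 * stats::pt(-tval, dof)
  }
  structure(list(r = r, dof = dof, p_value = p,
                 n_subjects = nlevels(subject), n_obs = length(x)),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("<rmcorr> r = %.4f, dof = %d, p = %.3g (%d subjects, %d obs)\n",
              x$r, x$dof, x$p_value, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Percentage difference between methods
#'
#' Mean over subjects of `|video - lab| / |lab| * 100`, taking the
#' laboratory value as the reference. Pairs with a zero laboratory value
#' are excluded with a warning.
#'
#' @param video_values,lab_values Per-subject means, paired.
#' @return Percentage (scalar).
#' @export
percent_difference <- function(video_values, lab_values) {
  stopifnot(length(video_values) == length(lab_values))
  zero <- lab_values == 0
  if (any(zero)) {
    warning(sprintf("%d pair(s) with zero laboratory value excluded",
                    sum(zero)), call. = FALSE)
    video_values <- video_values[!zero]
    lab_values <- lab_values[!zero]
  }
  if (!length(lab_values)) stop("no usable pairs", call. = FALSE)
  mean(abs(video_values - lab_values) / abs(lab_values)) * 100
}

#' Method-agreement report from a condition-measure table
#'
#' Takes the long table of one measurement per (subject, task, condition,
#' method, metric) and produces, per task and metric: baseline-normalised
#' values, the normality-gated paired test between methods, the paired
#' test between conditions for the video method, and the percentage
#' difference between methods on the raw condition values.
#'
#' @param measures Data frame with columns `subject_id`, `task`,
#'   `condition` (`"nominal"`, `"non_nominal"`, `"baseline"`), `method`
#'   (`"video"`, `"laboratory"`), `metric` (`"HR"`, `"EBR"`), `value`.
#' @param alpha Significance level (default 0.05).
#' @return Nested list keyed by metric then task with elements
#'   `method_agreement` (per condition), `condition_discrimination`
#'   (video method), `percent_difference` (per condition).
#' @export
compare_methods <- function(measures, alpha = 0.05) {
  needed <- c("subject_id", "task", "condition", "method", "metric", "value")
  if (!all(needed %in% names(measures))) {
    stop("measures table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(measures$value))) {
    stop("non-finite values in measures table", call. = FALSE)
  }
  get_vals <- function(task, condition, method, metric) {
    sel <- measures$task == task & measures$condition == condition &
      measures$method == method & measures$metric == metric
    v <- measures$value[sel]
    names(v) <- measures$subject_id[sel]
    v[order(names(v))]
  }
  normalized <- function(task, condition, method, metric) {
    v <- get_vals(task, condition, method, metric)
    b <- get_vals(task, "baseline", method, metric)
    if (!all(names(v) %in% names(b))) {
      stop(sprintf("missing baseline for subject(s) %s (task %s, %s, %s)",
                   paste(setdiff(names(v), names(b)), collapse = ","),
                   task, method, metric), call. = FALSE)
    }
    baseline_normalize(v, b[names(v)])
  }
  out <- list()
  for (metric in unique(measures$metric)) {
    for (task in setdiff(unique(measures$task), NA)) {
      conds <- setdiff(unique(measures$condition[measures$task == task &
                                                 measures$metric == metric]),
                       "baseline")
      agree <- list(); pdiff <- list()
      for (cond in conds) {
        v_vid <- normalized(task, cond, "video", metric)
        v_lab <- normalized(task, cond, "laboratory", metric)
        stopifnot(identical(names(v_vid), names(v_lab)))
        agree[[cond]] <- paired_compare(v_vid, v_lab, alpha = alpha)
        pdiff[[cond]] <- percent_difference(
          get_vals(task, cond, "video", metric),
          get_vals(task, cond, "laboratory", metric))
      }
      disc <- NULL
      if (all(c("nominal", "non_nominal") %in% conds)) {
        disc <- paired_compare(normalized(task, "nominal", "video", metric),
                               normalized(task, "non_nominal", "video", metric),
                               alpha = alpha)
      }
      out[[metric]][[task]] <- list(method_agreement = agree,
                                    condition_discrimination = disc,
                                    percent_difference = pdiff)
    }
  }
  out
}
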