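test_that("baseline normalisation is a plain subtraction", {
  expect_equal(baseline_normalize(80, 70), 10)
  expect_equal(baseline_normalize(15, 15), 0)
  expect_equal(baseline_normalize(12.5, 15), -2.5)
  expect_error(baseline_normalize(NA, 1), "missing")
})

test_that("signed-rank statistic and exact p match an independent oracle", {
  set.seed(8)
  for (rep in 1:10) {
    d <- sample(c(-3:-1, 1:3), 12, replace = TRUE)  # ties, no zeros
    mine <- wilcoxon_signed_rank(d, rep(0, 12))
    # statistic by direct rank computation
    r <- rank(abs(d))
    expect_equal(mine$statistic, sum(r[d > 0]))
    # brute force over all 2^12 sign assignments
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_brute <- min(1, 2 * min(mean(w_all <= mine$statistic),
                              mean(w_all >= mine$statistic)))
    expect_equal(mine$p_value, p_brute, tolerance = 1e-12)
  }
})

test_that("exact signed-rank p agrees with the reference implementation", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    # continuous data: no ties, exact regime
    mine <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation stays close to the reference
  set.seed(10)
  x <- rnorm(60)
  y <- rnorm(60, 0.3)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the normality gate routes to the right test", {
  set.seed(11)
  x <- rnorm(20, 5, 1)
  y <- x - rnorm(20, 0.5, 0.5)         # clearly normal differences
  res <- paired_compare(x, y)
  expect_equal(res$test_name, "t_paired")
  expect_equal(res$p_value,
               stats::t.test(x, y, paired = TRUE)$p.value)

  # heavy-tailed differences fail Shapiro-Wilk and go to Wilcoxon
  set.seed(12)
  d <- stats::rcauchy(30)
  x2 <- rnorm(30)
  res2 <- paired_compare(x2 + d, x2)
  expect_equal(res2$test_name, "wilcoxon_signed_rank")

  # identical samples: degenerate, p = 1
  z <- rnorm(10)
  res3 <- paired_compare(z, z)
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)

  expect_error(paired_compare(1:3, 3:1), "at least 5")
})

test_that("paired comparison is symmetric in its arguments", {
  set.seed(13)
  x <- rnorm(14)
  y <- rnorm(14, 0.4)
  expect_equal(paired_compare(x, y)$p_value, paired_compare(y, x)$p_value)
  xh <- x + stats::rcauchy(14)
  expect_equal(paired_compare(xh, y)$p_value, paired_compare(y, xh)$p_value)
})

test_that("rmcorr is exact on perfect common-slope data", {
  subj <- rep(1:4, each = 5)
  x <- rep(1:5, 4)
  up <- 2 * x + subj * 10
  expect_equal(rmcorr(subj, x, up)$r, 1.0)
  down <- -x + subj * 3
  expect_equal(rmcorr(subj, x, down)$r, -1.0)
  expect_equal(rmcorr(subj, x, up)$dof, 20 - 4 - 1)
})

test_that("rmcorr matches the ANCOVA normal-equations oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n_s <- sample(3:6, 1)
    n_o <- sample(4:8, 1)
    subj <- factor(rep(seq_len(n_s), each = n_o))
    x <- rnorm(n_s * n_o)
    y <- 0.6 * x + rnorm(n_s * n_o) + as.numeric(subj)
    mine <- rmcorr(subj, x, y)
    # oracle: least-squares fit of y ~ subject + x via normal equations
    mm <- cbind(stats::model.matrix(~ subj - 1), x)
    beta <- solve(t(mm) %*% mm, t(mm) %*% y)
    fit_full <- mm %*% beta
    mm0 <- stats::model.matrix(~ subj - 1)
    beta0 <- solve(t(mm0) %*% mm0, t(mm0) %*% y)
    ss_err <- sum((y - fit_full)^2)
    ss_measure <- sum((y - mm0 %*% beta0)^2) - ss_err
    r_oracle <- sign(beta[length(beta)]) *
      sqrt(ss_measure / (ss_measure + ss_err))
    expect_equal(mine$r, as.numeric(r_oracle), tolerance = 1e-10)
    # p from the t transform
    tval <- abs(mine$r) * sqrt(mine$dof / (1 - mine$r^2))
    expect_equal(mine$p_value, 2 * stats::pt(-tval, mine$dof))
  }
})

test_that("rmcorr ignores per-subject constant shifts", {
  set.seed(15)
  subj <- rep(1:5, each = 6)
  x <- rnorm(30)
  y <- 0.8 * x + rnorm(30, 0, 0.3)
  base <- rmcorr(subj, x, y)
  shifted <- rmcorr(subj, x + subj * 100, y - subj * 55)
  expect_equal(base$r, shifted$r, tolerance = 1e-12)
})

test_that("rmcorr validates its design", {
  expect_error(rmcorr(c(1, 1, 2, 2), 1:4, 1:4), "3 subjects")
  subj <- rep(1:3, each = 3)
  expect_error(rmcorr(subj, rep(c(1, 2, 3), each = 3), rnorm(9)),
               "within-subject")
})

test_that("percentage difference uses the laboratory reference", {
  expect_equal(percent_difference(62.8, 60), 100 * 2.8 / 60)
  expect_equal(percent_difference(c(5, 7), c(5, 7)), 0)
  expect_equal(percent_difference(10, 8), 25)
  expect_warning(pd <- percent_difference(c(10, 3), c(8, 0)), "zero")
  expect_equal(pd, 25)
})

test_that("a null method effect rejects at the nominal 5% rate", {
  set.seed(16)
  rejections <- 0L
  n_runs <- 400
  for (i in seq_len(n_runs)) {
    x <- rnorm(12)
    y <- x + rnorm(12)
    if (paired_compare(x, y)$p_value < 0.05) rejections <- rejections + 1L
  }
  # 99% binomial band around 5% of 400
  expect_gte(rejections, stats::qbinom(0.005, n_runs, 0.05))
  expect_lte(rejections, stats::qbinom(0.995, n_runs, 0.05))
})
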