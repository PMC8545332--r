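test_that("alert runs are segmented and merged by the gap rule", {
  t <- seq(0, 3, by = 0.1)
  alert <- t >= 1.0 & t <= 1.4 | t >= 1.5 & t <= 2.0
  ev <- segment_alerts(t, alert, min_gap_s = 0.2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 1.0)
  expect_equal(ev$end_s, 2.0)

  ev2 <- segment_alerts(t, alert, min_gap_s = 0)   # no merging
  expect_equal(nrow(ev2), 2)

  expect_equal(nrow(segment_alerts(t, rep(FALSE, length(t)))), 0)

  # alternating single-sample alerts at 100 Hz: one event per flagged sample
  t3 <- (0:9) / 100
  a3 <- rep(c(TRUE, FALSE), 5)
  ev3 <- segment_alerts(t3, a3)
  expect_equal(nrow(ev3), 5)
  expect_equal(ev3$duration_s, rep(0, 5))

  expect_error(segment_alerts(c(0, 2, 1), c(TRUE, TRUE, TRUE)),
               "strictly increasing")
})

test_that("the 1-second threshold splits touch attempts from contacts", {
  ev <- classify_touch(c(0.8, 2.5, 1.0))
  expect_equal(ev$kind, c("TA", "HC", "HC"))
  expect_equal(ev$recorded_duration_s, c(0.8, 1.5, 0))
  expect_error(classify_touch(-0.1), "negative")

  # partition is exhaustive and exclusive
  set.seed(3)
  d <- stats::runif(100, 0, 3)
  ev <- classify_touch(d)
  expect_equal(sum(ev$kind == "TA") + sum(ev$kind == "HC"), 100)
})

test_that("detection metrics count alerted gestures per class", {
  mk <- function(label, alerted, contact = c(1.0, 1.5)) {
    t <- seq(0, 2, by = 0.01)
    alert <- if (alerted) t >= 1.1 & t <= 1.3 else rep(FALSE, length(t))
    list(label = label, contact = if (label == "face_touch") contact,
         t = t, alert = alert)
  }
  results <- c(lapply(1:27, function(i) mk("face_touch", TRUE)),
               lapply(1:3, function(i) mk("face_touch", FALSE)),
               lapply(1:30, function(i) mk("adl", FALSE)))
  m <- detection_metrics(results)
  expect_equal(m$correct_detection_pct, 90)   # 27 of 30
  expect_equal(m$false_positive_pct, 0)
  expect_equal(m$ta_per_hour,
               27 / (m$monitored_s / 3600))   # 0.2 s events are TAs

  # permutation invariance
  set.seed(8)
  m2 <- detection_metrics(results[sample(length(results))])
  expect_equal(m2$correct_detection_pct, m$correct_detection_pct)
  expect_equal(m2$false_positive_pct, m$false_positive_pct)

  # an alert outside the (tolerance-widened) window is not a detection
  off <- mk("face_touch", TRUE, contact = c(0.1, 0.2))
  m3 <- detection_metrics(list(off, mk("adl", FALSE)))
  expect_equal(m3$correct_detection_pct, 0)

  expect_error(detection_metrics(list(mk("adl", FALSE))), "undefined")
})

test_that("paired t summary matches the hand-computed example", {
  r <- paired_t(c(2, 4, 5), c(1, 2, 4))
  expect_equal(r$mean_diff, 4 / 3, tolerance = 1e-12)
  expect_equal(r$t, 4, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-4, 2), tolerance = 1e-12)

  # antisymmetry
  r2 <- paired_t(c(1, 2, 4), c(2, 4, 5))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$mean_diff, -r$mean_diff)
  expect_equal(r2$p, r$p)

  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("normality gate falls back to the square-root scale", {
  expect_equal(sqrt(c(4, 9, 25)), c(2, 3, 5))
  set.seed(1)
  x <- stats::rlnorm(60, 1, 0.8)
  g <- normality_gate(x)
  expect_true(g$transformed)
  expect_lte(g$p, 0.05)
  expect_gt(g$p_transformed, 0.05)
  expect_equal(g$W, unname(stats::shapiro.test(x)$statistic))
  expect_equal(g$W_transformed,
               unname(stats::shapiro.test(sqrt(x))$statistic))

  set.seed(2)
  y <- stats::rnorm(60)   # normal data: no transform
  expect_false(normality_gate(y)$transformed)

  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(-4, -1, 0, 1, 2, 3, 3.5, 9, 20, 80)),
               "negative")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("post-hoc power follows the noncentral t distribution", {
  # null limit: vanishing effect gives power ~ alpha
  expect_equal(posthoc_power(10, 1e-9), 0.05, tolerance = 1e-3)

  # monotone increasing in n at fixed effect size
  p <- vapply(2:50, function(n) posthoc_power(n, 0.6), numeric(1))
  expect_true(all(diff(p) > 0))

  # the observed effect of a strong paired test at n = 10 is well powered
  dz <- 4.77 / sqrt(10)
  expect_gte(posthoc_power(10, dz), 0.8)

  # cross-check against the standard power routine
  expect_equal(posthoc_power(10, 0.8),
               stats::power.t.test(n = 10, delta = 0.8, sd = 1,
                                   type = "paired", strict = TRUE)$power,
               tolerance = 1e-6)

  # Monte-Carlo oracle: simulate paired samples and count rejections
  n <- 10; dz <- 0.9
  set.seed(55)
  reps <- 2e4
  diffs <- matrix(stats::rnorm(reps * n, mean = dz, sd = 1), nrow = reps)
  tstat <- rowMeans(diffs) /
    (apply(diffs, 1, stats::sd) / sqrt(n))
  phat <- mean(abs(tstat) > stats::qt(0.975, n - 1))
  pow <- posthoc_power(n, dz)
  expect_lt(abs(phat - pow), 4 * sqrt(pow * (1 - pow) / reps))

  expect_error(posthoc_power(10, 0.5, alpha = 1.2), "alpha")
  expect_error(posthoc_power(1, 0.5), "n >= 2")
  expect_error(posthoc_power(10, 0), "positive")
})

test_that("coverage helper recovers the three-sigma rule on Gaussians", {
  set.seed(12)
  x <- stats::rnorm(2e4)
  expect_lt(abs(coverage_within(x, 3) - 0.9973), 0.002)
  # sd of (0,0,0,0,10) is sqrt(20); only the outlier exceeds one sd
  expect_equal(coverage_within(c(0, 0, 0, 0, 10), 1), 0.8)
})
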