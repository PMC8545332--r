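mk_mag_stream <- function(Phi, rate = 100) {
  n <- length(Phi)
  data.frame(t = (seq_len(n) - 1) / rate, mx = Phi, my = 0, mz = 0)
}

test_that("phase-1 calibration computes the background mean and sd", {
  s <- mk_mag_stream(rep(c(44, 46), 100))
  p1 <- mag_calibrate_phase1(s)
  expect_equal(p1$phi_bar, 45)
  expect_equal(length(p1$buffer), 200)

  # constant (noiseless) environment is degenerate
  expect_error(mag_calibrate_phase1(mk_mag_stream(rep(45, 200))),
               "degenerate")
  expect_error(mag_calibrate_phase1(mk_mag_stream(45)), "at least 2")

  # seeded Gaussian background vs an independent one-pass oracle
  set.seed(13)
  Phi <- stats::rnorm(200, 45, 2)
  p1 <- mag_calibrate_phase1(mk_mag_stream(Phi))
  ms <- oracle_mean_sd(Phi)
  expect_equal(p1$phi_bar, unname(ms["mean"]), tolerance = 1e-12)
  expect_equal(p1$sigma_phi, unname(ms["sd"]), tolerance = 1e-12)
  expect_lt(abs(p1$phi_bar - 45), 0.5)
  expect_lt(abs(p1$sigma_phi - 2), 0.4)
})

test_that("phase-2 calibration derives alpha from the peak excursion", {
  p1 <- list(phi_bar = 45, sigma_phi = 5,
             buffer = rep(c(40, 50), 100))
  peak <- mk_mag_stream(c(seq(45, 145, length.out = 150),
                          seq(145, 60, length.out = 150)))
  cal <- mag_calibrate_phase2(peak, p1)
  expect_s3_class(cal, "mag_calibration")
  expect_equal(cal$phi_hat, 145)
  expect_equal(cal$alpha, 20)   # (145 - 45) / 5

  # no field increase: alpha 0 and a warning
  flat <- mk_mag_stream(rep(c(44, 45), 100))
  expect_warning(cal0 <- mag_calibrate_phase2(flat, p1), "no field increase")
  expect_equal(cal0$alpha, 0)
})

test_that("calibration on a simulated approach matches the batch oracle", {
  cfg <- sim_config(seed = 31L)
  neck <- necklace_model()
  s <- make_calibration_stream(neck, cfg)
  cal <- mag_calibrate(s)

  Phi <- sqrt(s$mx^2 + s$my^2 + s$mz^2)
  ph1 <- Phi[s$t < 2]
  ph2 <- Phi[s$t >= 2 & s$t < 5]
  ms <- oracle_mean_sd(utils::tail(ph1, 200))
  expect_equal(cal$phi_bar, unname(ms["mean"]), tolerance = 1e-12)
  expect_equal(cal$sigma_phi, unname(ms["sd"]), tolerance = 1e-12)
  # alpha equals the max z-score of the phase-2 trace wrt the phase-1 model
  expect_equal(cal$alpha, max(abs(ph2 - ms["mean"]) / ms["sd"]),
               tolerance = 1e-12)
  expect_gt(cal$alpha, 3)   # magnets dominate pure sensor noise
})

test_that("monitoring updates the background only in safe orientation", {
  cal <- mag_calibration(phi_bar = 45, sigma_phi = 2, alpha = 3,
                         buffer = rep(45, 200))
  det <- new_mag_detector(cal)
  safe <- accel_for_angles(0, 0)      # phi = 0: outside the unsafe box
  unsafe <- accel_for_angles(0, 60)   # inside the unsafe box

  # safe branch: even a huge field enters the buffer, never alerts
  det1 <- mag_step(det, safe$ax, safe$ay, safe$az, 1000, 0, 0)
  expect_false(det1$alert)
  expect_false(det1$unsafe)
  expect_equal(det1$buffer[length(det1$buffer)], 1000)
  expect_gt(det1$sigma_phi, cal$sigma_phi)  # background absorbed the spike

  # unsafe branch: baseline frozen exactly where the safe branch left it
  det2 <- mag_step(det1, unsafe$ax, unsafe$ay, unsafe$az, 2000, 0, 0)
  expect_true(det2$unsafe)
  expect_equal(det2$phi_bar, det1$phi_bar)
  expect_equal(det2$sigma_phi, det1$sigma_phi)
  expect_identical(det2$buffer, det1$buffer)
})

test_that("the alert predicate is a strict z-score threshold", {
  cal <- mag_calibration(phi_bar = 45, sigma_phi = 2, alpha = 3,
                         buffer = rep(45, 200))
  det <- new_mag_detector(cal)
  u <- accel_for_angles(0, 60)

  above <- mag_step(det, u$ax, u$ay, u$az, 45 + (3 + 1) * 2, 0, 0)
  expect_true(above$alert)
  below <- mag_step(det, u$ax, u$ay, u$az, 45 + (3 / 2) * 2, 0, 0)
  expect_false(below$alert)
  tie <- mag_step(det, u$ax, u$ay, u$az, 45 + 3 * 2, 0, 0)   # ratio == alpha
  expect_false(tie$alert)
  # alert clears as soon as the predicate fails
  cleared <- mag_step(above, u$ax, u$ay, u$az, 45, 0, 0)
  expect_false(cleared$alert)
  # two-sided deviation: a field drop alerts too
  drop <- mag_step(det, u$ax, u$ay, u$az, 45 - 10 * 2, 0, 0)
  expect_true(drop$alert)
})

test_that("alerting is monotone in the absolute field deviation", {
  cal <- mag_calibration(phi_bar = 50, sigma_phi = 1.5, alpha = 4,
                         buffer = rep(50, 200))
  u <- accel_for_angles(-20, 70)
  dev <- seq(0, 15, by = 0.5)
  fired <- vapply(dev, function(d) {
    mag_step(new_mag_detector(cal), u$ax, u$ay, u$az, 50 + d, 0, 0)$alert
  }, logical(1))
  expect_true(all(diff(fired) >= 0))   # once on, stays on as |dev| grows
})

test_that("false-alert probability without magnets matches Gaussian theory", {
  # frozen baseline, alpha = 3: P(|z| > 3) = 2 * pnorm(-3) ~ 0.0027,
  # i.e. ~99.7% of samples inside mean +/- 3 sd
  cal <- mag_calibration(phi_bar = 45, sigma_phi = 1, alpha = 3,
                         buffer = rep(45, 200))
  u <- accel_for_angles(0, 60)
  n <- 1e5
  set.seed(97)
  Phi <- stats::rnorm(n, 45, 1)
  det <- new_mag_detector(cal)
  hits <- 0L
  for (i in seq_len(n)) {
    det <- mag_step(det, u$ax, u$ay, u$az, Phi[i], 0, 0)
    hits <- hits + det$alert
  }
  p0 <- 2 * stats::pnorm(-3)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(hits / n - p0), 3 * se)
})

test_that("an uncalibrated detector cannot be constructed or stepped", {
  expect_error(new_mag_detector(list(alpha = 3)), "calibration")
  expect_error(mag_step(list(), 0, 0, 9.81, 45, 0, 0), "mag_detector")
  expect_error(mag_calibration(45, 0, 3), "degenerate")
})
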