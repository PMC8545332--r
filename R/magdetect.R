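#' Magnetic field magnitude
#'
#' @param mx,my,mz Numeric vectors, magnetic components in \eqn{\mu}T.
#' @return Numeric vector \eqn{\Phi = \sqrt{m_x^2+m_y^2+m_z^2}}.
#' @export
field_magnitude <- function(mx, my, mz) {
  if (any(!is.finite(c(mx, my, mz))))
    stop("non-finite magnetometer reading")
  sqrt(mx^2 + my^2 + mz^2)
}

#' Construct a magnetometer calibration object
#'
#' Usually produced by [mag_calibrate()]; the constructor is exported so a
#' calibration can be assembled manually, e.g. to set the threshold
#' multiplier `alpha` by hand when the environment is degenerate (noiseless
#' synthetic input has `sigma_phi = 0` and cannot be calibrated).
#'
#' @param phi_bar Baseline mean field magnitude, \eqn{\mu}T.
#' @param sigma_phi Baseline sample standard deviation, \eqn{\mu}T; must be
#'   positive.
#' @param alpha Dimensionless threshold multiplier; an alert requires the
#'   z-score of the current magnitude to exceed `alpha`.
#' @param phi_hat Phase-2 maximum magnitude (optional, `NA` when alpha is
#'   set manually).
#' @param buffer Numeric vector priming the detector's background buffer;
#'   defaults to a constant buffer at `phi_bar`.
#' @param sample_rate_hz Sampling rate the calibration was acquired at.
#' @return Object of class `mag_calibration`.
#' @export
mag_calibration <- function(phi_bar, sigma_phi, alpha, phi_hat = NA_real_,
                            buffer = rep(phi_bar, 200),
                            sample_rate_hz = 100) {
  if (!is.finite(phi_bar) || !is.finite(sigma_phi) || !is.finite(alpha))
    stop("calibration values must be finite")
  if (sigma_phi <= 0)
    stop("degenerate environment: sigma_phi must be > 0 ",
         "(add sensor noise or set alpha manually)")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(
    list(phi_bar = phi_bar, sigma_phi = sigma_phi, phi_hat = phi_hat,
         alpha = alpha, buffer = as.numeric(buffer),
         sample_rate_hz = sample_rate_hz),
    class = "mag_calibration")
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat(sprintf(
    "Magnetometer calibration: phi_bar = %.3f uT, sigma_phi = %.4f uT,\n  phi_hat = %.3f uT, alpha = %.3f (buffer of %d samples)\n",
    x$phi_bar, x$sigma_phi, x$phi_hat, x$alpha, length(x$buffer)))
  invisible(x)
}

slice_by_time <- function(stream, from_s, duration_s) {
  if (!is.null(stream$t)) {
    t0 <- stream$t[1]
    stream[stream$t - t0 >= from_s & stream$t - t0 < from_s + duration_s, ,
           drop = FALSE]
  } else stream
}

#' Phase-1 calibration: environmental background model
#'
#' First half of the two-phase magnetometer calibration, performed with the
#' arm extended far from the magnets. Field magnitudes fill a ring buffer of
#' capacity `buffer_n` (oldest sample dropped once full); the baseline mean
#' \eqn{\bar\Phi} and sample standard deviation \eqn{\sigma_\Phi} (divisor
#' n-1) are computed over the final buffer contents.
#'
#' @param stream data.frame with columns `mx`, `my`, `mz` (\eqn{\mu}T) and
#'   optionally `t` (s). When `t` is present only the first `duration_s`
#'   seconds are used.
#' @param duration_s Calibration length in seconds (default 2).
#' @param buffer_n Buffer capacity (default 200, i.e. 2 s at 100 Hz).
#' @return A list with `phi_bar`, `sigma_phi` and the primed `buffer`.
#' @export
mag_calibrate_phase1 <- function(stream, duration_s = 2, buffer_n = 200) {
  stream <- slice_by_time(stream, 0, duration_s)
  if (is.null(stream$mx))
    stop("stream has no magnetometer columns (mx, my, mz)")
  phi <- field_magnitude(stream$mx, stream$my, stream$mz)
  if (length(phi) < 2)
    stop("calibration error: need at least 2 samples")
  buffer <- utils::tail(phi, buffer_n)
  phi_bar <- mean(buffer)
  sigma_phi <- stats::sd(buffer)
  if (sigma_phi == 0)
    stop("degenerate environment: zero field variance during calibration ",
         "(noiseless input; add noise or set alpha manually)")
  list(phi_bar = phi_bar, sigma_phi = sigma_phi, buffer = buffer)
}

#' Phase-2 calibration: threshold multiplier alpha
#'
#' Second half of the calibration: the user moves the watch toward the magnet
#' necklace, stopping about 20 cm away. The running maximum magnitude
#' \eqn{\hat\Phi} over this window yields
#' \eqn{\alpha = |\hat\Phi - \bar\Phi| / \sigma_\Phi}.
#' If no field increase is observed (\eqn{\hat\Phi \le \bar\Phi}) the
#' resulting alpha is near zero and the detector would alert almost
#' constantly, so a warning is emitted.
#'
#' @param stream data.frame with `mx`, `my`, `mz` and optionally `t`.
#' @param phase1 Result of [mag_calibrate_phase1()].
#' @param duration_s Phase length in seconds (default 3).
#' @inheritParams mag_calibration
#' @return A [mag_calibration()] object.
#' @export
mag_calibrate_phase2 <- function(stream, phase1, duration_s = 3,
                                 sample_rate_hz = 100) {
  stream <- slice_by_time(stream, 0, duration_s)
  if (is.null(stream$mx))
    stop("stream has no magnetometer columns (mx, my, mz)")
  phi <- field_magnitude(stream$mx, stream$my, stream$mz)
  if (length(phi) < 1) stop("calibration error: empty phase-2 stream")
  phi_hat <- max(phi)
  if (phi_hat <= phase1$phi_bar)
    warning("no field increase observed during phase 2; alpha near 0 ",
            "would trigger alerts constantly")
  alpha <- abs(phi_hat - phase1$phi_bar) / phase1$sigma_phi
  mag_calibration(phi_bar = phase1$phi_bar, sigma_phi = phase1$sigma_phi,
                  alpha = alpha, phi_hat = phi_hat, buffer = phase1$buffer,
                  sample_rate_hz = sample_rate_hz)
}

#' Two-phase magnetometer calibration
#'
#' Convenience wrapper running [mag_calibrate_phase1()] on the first
#' `phase1_s` seconds of a recorded stream (arm far from the magnets) and
#' [mag_calibrate_phase2()] on the following `phase2_s` seconds (watch moved
#' to about 20 cm from the necklace).
#'
#' @param stream data.frame with columns `t`, `mx`, `my`, `mz`.
#' @param phase1_s,phase2_s Phase durations in seconds (defaults 2 and 3).
#' @param buffer_n Background buffer capacity (default 200).
#' @param sample_rate_hz Nominal sampling rate (metadata only).
#' @return A [mag_calibration()] object.
#' @export
mag_calibrate <- function(stream, phase1_s = 2, phase2_s = 3,
                          buffer_n = 200, sample_rate_hz = 100) {
  if (is.null(stream$t)) stop("stream must have a time column t")
  p1 <- mag_calibrate_phase1(stream, duration_s = phase1_s,
                             buffer_n = buffer_n)
  s2 <- slice_by_time(stream, phase1_s, phase2_s)
  mag_calibrate_phase2(s2, p1, duration_s = phase2_s,
                       sample_rate_hz = sample_rate_hz)
}

#' Streaming magnetometer-based face-touch detector
#'
#' Builds the detector state for the magnetic-barrier algorithm. At each
#' sample the wrist orientation is estimated from the gravity vector; while
#' the orientation is safe the field magnitude feeds a ring buffer of
#' capacity `buffer_n` whose rolling statistics model the ambient field
#' (mean over the last `mean_window` entries; standard deviation of the full
#' buffer about that mean, divisor n-1). While the orientation is unsafe the
#' background model is frozen and an alert is raised whenever
#' \eqn{|\Phi - \bar\Phi| / \sigma_\Phi > \alpha} (strict). The alert clears
#' as soon as the predicate fails.
#'
#' @param calibration A [mag_calibration()] object.
#' @param bounds An [orientation_bounds()] object.
#' @param buffer_n Background buffer capacity (default 200).
#' @param mean_window Rolling-mean window over the newest buffer entries
#'   (default 50).
#' @return Object of class `mag_detector`; advance it with [mag_step()] or
#'   [run_detector()].
#' @export
new_mag_detector <- function(calibration, bounds = orientation_bounds(),
                             buffer_n = 200, mean_window = 50) {
  if (!inherits(calibration, "mag_calibration"))
    stop("detector state error: a completed mag_calibration is required")
  if (!inherits(bounds, "orientation_bounds"))
    stop("bounds must be an orientation_bounds object")
  if (mean_window < 1 || buffer_n < 2 || mean_window > buffer_n)
    stop("need 1 <= mean_window <= buffer_n and buffer_n >= 2")
  structure(
    list(
      buffer = utils::tail(calibration$buffer, buffer_n),
      buffer_n = buffer_n, mean_window = mean_window,
      phi_bar = calibration$phi_bar, sigma_phi = calibration$sigma_phi,
      alpha = calibration$alpha, bounds = bounds,
      theta = NA_real_, phi = NA_real_, zscore = NA_real_,
      unsafe = FALSE, alert = FALSE),
    class = "mag_detector")
}

#' Advance the magnetometer detector by one sample
#'
#' @param det A `mag_detector` state from [new_mag_detector()] (or a previous
#'   `mag_step()` call).
#' @param ax,ay,az Accelerometer components, m/s\eqn{^2}.
#' @param mx,my,mz Magnetometer components, \eqn{\mu}T.
#' @return The updated detector state; inspect `$alert`, `$unsafe`,
#'   `$zscore`.
#' @export
mag_step <- function(det, ax, ay, az, mx, my, mz) {
  if (!inherits(det, "mag_detector"))
    stop("detector state error: not a mag_detector")
  ang <- estimate_angles(ax, ay, az)
  det$theta <- ang$theta
  det$phi <- ang$phi
  det$unsafe <- is_unsafe(ang$theta, ang$phi, det$bounds)
  Phi <- field_magnitude(mx, my, mz)
  if (!det$unsafe) {
    buf <- det$buffer
    if (length(buf) >= det$buffer_n) buf <- buf[-1L]
    buf <- c(buf, Phi)
    det$buffer <- buf
    m <- min(det$mean_window, length(buf))
    det$phi_bar <- mean(buf[(length(buf) - m + 1L):length(buf)])
    det$sigma_phi <- sqrt(sum((buf - det$phi_bar)^2) / (length(buf) - 1L))
    det$zscore <- abs(Phi - det$phi_bar) / det$sigma_phi
    det$alert <- FALSE
  } else {
    det$zscore <- abs(Phi - det$phi_bar) / det$sigma_phi
    det$alert <- det$zscore > det$alpha
  }
  det
}
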