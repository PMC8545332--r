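#' Construct an inertial-only calibration object
#'
#' Usually produced by [imu_calibrate()]. The pitch-rate threshold is
#' \eqn{\beta = 3\,\sigma_{\dot\phi}} where \eqn{\sigma_{\dot\phi}} is the
#' sample standard deviation of the per-sample pitch difference while the arm
#' is held still. Note that \eqn{\dot\phi} is a raw successive difference in
#' degrees per sample (not divided by \eqn{\Delta t}), so `beta` scales with
#' the sampling rate.
#'
#' @param beta Pitch-rate threshold, degrees per sample; must be >= 0.
#' @param sigma_phidot Still-arm pitch-rate standard deviation, degrees per
#'   sample.
#' @param sample_rate_hz Sampling rate the calibration was acquired at.
#' @return Object of class `imu_calibration`.
#' @export
imu_calibration <- function(beta, sigma_phidot = beta / 3,
                            sample_rate_hz = 100) {
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0")
  structure(list(beta = beta, sigma_phidot = sigma_phidot,
                 sample_rate_hz = sample_rate_hz),
            class = "imu_calibration")
}

#' @export
print.imu_calibration <- function(x, ...) {
  cat(sprintf(
    "Inertial calibration: beta = %.4f deg/sample (3 x sigma_phidot = 3 x %.4f)\n",
    x$beta, x$sigma_phidot))
  invisible(x)
}

#' Inertial-only calibration (still arm)
#'
#' The user holds the hand at rest for `duration_s` seconds. The wrist pitch
#' is computed per sample from the gravity vector; the per-sample pitch
#' differences fill a buffer of capacity `buffer_n`, whose sample standard
#' deviation (divisor n-1) gives \eqn{\sigma_{\dot\phi}} and the threshold
#' \eqn{\beta = 3\,\sigma_{\dot\phi}}.
#'
#' @param stream data.frame with columns `ax`, `ay`, `az` (m/s\eqn{^2}) and
#'   optionally `t` (s). When `t` is present only the first `duration_s`
#'   seconds are used.
#' @param duration_s Calibration length in seconds (default 2).
#' @param buffer_n Buffer capacity for the pitch-rate samples (default 200).
#' @param sample_rate_hz Nominal sampling rate (metadata only).
#' @return An [imu_calibration()] object. Perfectly still (noiseless) input
#'   yields `beta = 0` with a warning: every nonzero pitch change would then
#'   count as movement.
#' @export
imu_calibrate <- function(stream, duration_s = 2, buffer_n = 200,
                          sample_rate_hz = 100) {
  stream <- slice_by_time(stream, 0, duration_s)
  if (is.null(stream$ax))
    stop("stream has no accelerometer columns (ax, ay, az)")
  if (nrow(stream) < 2)
    stop("calibration error: need at least 2 samples")
  pitch <- estimate_angles(stream$ax, stream$ay, stream$az)$phi
  phidot <- diff(pitch)
  buffer <- utils::tail(phidot, buffer_n)
  sigma <- if (length(buffer) >= 2) stats::sd(buffer) else 0
  if (sigma == 0)
    warning("degenerate input: zero pitch-rate variance, beta = 0")
  imu_calibration(beta = 3 * sigma, sigma_phidot = sigma,
                  sample_rate_hz = sample_rate_hz)
}

#' Streaming accelerometer-only face-touch detector
#'
#' Builds the detector state for the inertial-only algorithm. At each sample
#' the pitch difference \eqn{\dot\phi} is compared with the calibrated
#' threshold \eqn{\beta}: a `+1` mark is pushed into a fixed-length slope
#' ring if \eqn{\dot\phi > \beta}, else `-1`. The hand counts as rising when
#' the ring mean is strictly positive (a 25/25 split is not rising). The
#' alert predicate is `unsafe orientation AND rising`; it clears as soon as
#' either condition fails.
#'
#' The ring is pre-filled with `-1` so a fresh detector starts in the
#' non-rising state, and the first sample contributes \eqn{\dot\phi = 0}
#' (there is no previous pitch to difference against).
#'
#' @param calibration An [imu_calibration()] object.
#' @param bounds An [orientation_bounds()] object.
#' @param slope_window Slope-ring length (default 50).
#' @return Object of class `imu_detector`; advance it with [imu_step()] or
#'   [run_detector()].
#' @export
new_imu_detector <- function(calibration, bounds = orientation_bounds(),
                             slope_window = 50) {
  if (!inherits(calibration, "imu_calibration"))
    stop("detector state error: a completed imu_calibration is required")
  if (!inherits(bounds, "orientation_bounds"))
    stop("bounds must be an orientation_bounds object")
  if (slope_window < 1) stop("slope_window must be >= 1")
  structure(
    list(
      beta = calibration$beta, bounds = bounds,
      ring = rep(-1, slope_window), slope_window = slope_window,
      prev_phi = NA_real_, phidot = NA_real_,
      theta = NA_real_, phi = NA_real_,
      rising = FALSE, unsafe = FALSE, alert = FALSE),
    class = "imu_detector")
}

#' Advance the inertial-only detector by one sample
#'
#' @param det An `imu_detector` state from [new_imu_detector()] (or a
#'   previous `imu_step()` call).
#' @param ax,ay,az Accelerometer components, m/s\eqn{^2}.
#' @return The updated detector state; inspect `$alert`, `$rising`,
#'   `$unsafe`.
#' @export
imu_step <- function(det, ax, ay, az) {
  if (!inherits(det, "imu_detector"))
    stop("detector state error: not an imu_detector")
  ang <- estimate_angles(ax, ay, az)
  det$theta <- ang$theta
  det$phi <- ang$phi
  det$phidot <- if (is.na(det$prev_phi)) 0 else ang$phi - det$prev_phi
  det$prev_phi <- ang$phi
  mark <- if (det$phidot > det$beta) 1 else -1
  det$ring <- c(det$ring[-1L], mark)
  det$rising <- mean(det$ring) > 0
  det$unsafe <- is_unsafe(ang$theta, ang$phi, det$bounds)
  det$alert <- det$unsafe && det$rising
  det
}

#' Run a streaming detector over a recorded stream
#'
#' Feeds every row of a sensor stream through the detector's step function
#' and collects the per-sample diagnostics.
#'
#' @param det A `mag_detector` or `imu_detector` state object.
#' @param stream data.frame with columns `t`, `ax`, `ay`, `az` and, for the
#'   magnetometer detector, `mx`, `my`, `mz`.
#' @return A data.frame with one row per sample: `t`, `theta`, `phi`,
#'   `unsafe`, `alert` plus `zscore` (magnetometer) or `phidot`/`rising`
#'   (inertial). The final detector state is attached as attribute
#'   `"detector"`.
#' @export
run_detector <- function(det, stream) UseMethod("run_detector")

#' @export
run_detector.mag_detector <- function(det, stream) {
  if (is.null(stream$mx))
    stop("magnetometer detector needs mx, my, mz columns")
  n <- nrow(stream)
  out <- data.frame(t = stream$t, theta = numeric(n), phi = numeric(n),
                    unsafe = logical(n), zscore = numeric(n),
                    alert = logical(n))
  for (i in seq_len(n)) {
    det <- mag_step(det, stream$ax[i], stream$ay[i], stream$az[i],
                    stream$mx[i], stream$my[i], stream$mz[i])
    out$theta[i] <- det$theta; out$phi[i] <- det$phi
    out$unsafe[i] <- det$unsafe; out$zscore[i] <- det$zscore
    out$alert[i] <- det$alert
  }
  attr(out, "detector") <- det
  out
}

#' @export
run_detector.imu_detector <- function(det, stream) {
  n <- nrow(stream)
  out <- data.frame(t = stream$t, theta = numeric(n), phi = numeric(n),
                    unsafe = logical(n), phidot = numeric(n),
                    rising = logical(n), alert = logical(n))
  for (i in seq_len(n)) {
    det <- imu_step(det, stream$ax[i], stream$ay[i], stream$az[i])
    out$theta[i] <- det$theta; out$phi[i] <- det$phi
    out$unsafe[i] <- det$unsafe; out$phidot[i] <- det$phidot
    out$rising[i] <- det$rising; out$alert[i] <- det$alert
  }
  attr(out, "detector") <- det
  out
}
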