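# Independent oracles used to cross-check the streaming implementations.
# These deliberately avoid the package's step functions and ring-buffer
# mechanics: statistics are recomputed from scratch at every sample from the
# full history.

# one-pass (Welford) mean and sample sd
oracle_mean_sd <- function(x) {
  m <- 0; s <- 0; k <- 0
  for (v in x) {
    k <- k + 1
    d <- v - m
    m <- m + d / k
    s <- s + d * (v - m)
  }
  c(mean = m, sd = if (k > 1) sqrt(s / (k - 1)) else 0)
}

# accelerometer reading that encodes a given roll/pitch (degrees)
accel_for_angles <- function(theta_deg, phi_deg, g = 9.81) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  data.frame(ax = -g * sin(ph),
             ay = g * sin(th) * cos(ph),
             az = g * cos(th) * cos(ph))
}

# build a minimal stream data.frame from angles and field magnitudes
stream_from_angles <- function(theta, phi, Phi = NULL, rate = 100) {
  n <- length(theta)
  acc <- accel_for_angles(theta, phi)
  df <- data.frame(t = (seq_len(n) - 1) / rate, acc)
  if (!is.null(Phi)) {
    df$mx <- Phi; df$my <- 0; df$mz <- 0
  }
  df
}

oracle_angles <- function(ax, ay, az) {
  data.frame(theta = atan2(ay, az) * 180 / pi,
             phi = atan2(-ax, sqrt(ay^2 + az^2)) * 180 / pi)
}

oracle_unsafe <- function(theta, phi, b) {
  theta > b$theta_min & theta < b$theta_max &
    phi > b$phi_min & phi < b$phi_max
}

# batch re-implementation of the magnetometer algorithm
batch_mag_alerts <- function(stream, cal, bounds = orientation_bounds(),
                             buffer_n = 200, mean_window = 50) {
  ang <- oracle_angles(stream$ax, stream$ay, stream$az)
  unsafe <- oracle_unsafe(ang$theta, ang$phi, bounds)
  Phi <- sqrt(stream$mx^2 + stream$my^2 + stream$mz^2)
  safe_hist <- cal$buffer
  phi_bar <- cal$phi_bar
  sigma <- cal$sigma_phi
  alert <- logical(nrow(stream))
  for (i in seq_along(alert)) {
    if (!unsafe[i]) {
      safe_hist <- c(safe_hist, Phi[i])
      buf <- utils::tail(safe_hist, buffer_n)
      m <- min(mean_window, length(buf))
      phi_bar <- mean(utils::tail(buf, m))
      sigma <- sqrt(sum((buf - phi_bar)^2) / (length(buf) - 1))
      alert[i] <- FALSE
    } else {
      alert[i] <- abs(Phi[i] - phi_bar) / sigma > cal$alpha
    }
  }
  alert
}

# batch re-implementation of the accelerometer-only algorithm
batch_imu_alerts <- function(stream, cal, bounds = orientation_bounds(),
                             slope_window = 50) {
  ang <- oracle_angles(stream$ax, stream$ay, stream$az)
  unsafe <- oracle_unsafe(ang$theta, ang$phi, bounds)
  phidot <- c(0, diff(ang$phi))
  marks <- ifelse(phidot > cal$beta, 1, -1)
  hist <- c(rep(-1, slope_window), marks)
  n <- nrow(stream)
  rising <- vapply(seq_len(n), function(i) {
    mean(hist[(i + 1):(i + slope_window)]) > 0
  }, logical(1))
  unsafe & rising
}
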