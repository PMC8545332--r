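#' Permanent-magnet specification
#'
#' Describes one disc magnet of the necklace. The default geometry is a
#' 10 mm x 5 mm N42 neodymium disc. Its dipole moment can be
#' `"calibrated"` (default) -- chosen so the on-axis field magnitude at 5 cm
#' equals the measured 420 \eqn{\mu}T -- or `"nominal"` -- derived from the
#' N42 remanence (1.32 T) and the disc volume, which over-predicts the
#' measured near field -- or any positive number in A m\eqn{^2}.
#'
#' @param diameter_mm,thickness_mm Disc dimensions, mm.
#' @param grade Magnet grade label (metadata).
#' @param moment `"calibrated"`, `"nominal"`, or a positive numeric moment in
#'   A m\eqn{^2}.
#' @return Object of class `magnet_spec` with field `moment_Am2`.
#' @export
magnet_spec <- function(diameter_mm = 10, thickness_mm = 5, grade = "N42",
                        moment = c("calibrated", "nominal")) {
  if (is.numeric(moment)) {
    m <- moment
  } else {
    moment <- match.arg(moment)
    m <- if (moment == "calibrated") {
      # on-axis |B| = 2e-7 * m / r^3 ; solve for 420 uT at r = 5 cm
      420e-6 * 0.05^3 / (2e-7)
    } else {
      Br <- 1.32  # N42 remanence, Tesla
      vol <- pi * (diameter_mm / 2000)^2 * (thickness_mm / 1000)
      Br * vol / (4 * pi * 1e-7)
    }
  }
  if (!is.finite(m) || m <= 0) stop("dipole moment must be positive")
  structure(list(diameter_mm = diameter_mm, thickness_mm = thickness_mm,
                 grade = grade, moment_Am2 = m),
            class = "magnet_spec")
}

#' Point-dipole magnetic field
#'
#' Standard point-dipole field
#' \deqn{B(r) = \frac{\mu_0}{4\pi}\frac{3\hat r (m\cdot\hat r) - m}{|r|^3},}
#' returned in \eqn{\mu}T for a moment in A m\eqn{^2} and positions in
#' metres. The field decays as \eqn{1/r^3} and doubles of the on-axis
#' distance reduce the magnitude by a factor 8.
#'
#' @param moment Length-3 numeric: dipole moment vector, A m\eqn{^2}.
#' @param source Length-3 numeric: dipole position, m.
#' @param point Length-3 numeric: evaluation point, m.
#' @return Length-3 numeric field vector in \eqn{\mu}T.
#' @export
dipole_field <- function(moment, source, point) {
  r <- point - source
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("singularity: field evaluated at the dipole position")
  rh <- r / rn
  # mu0/(4 pi) = 1e-7 T m / A ; 1e6 uT / T  =>  0.1
  0.1 * (3 * rh * sum(moment * rh) - moment) / rn^3
}

#' Magnet-necklace model
#'
#' Places `n_magnets` identical disc magnets on a shallow circular arc of
#' radius `arc_radius_m` lying in the horizontal plane of the necklace frame
#' (origin at the central magnet, x pointing forward away from the chest,
#' z up). Neighbouring magnets are separated by the chord `spacing_m`;
#' dipole moments point radially outward, i.e. through the disc thickness
#' away from the body.
#'
#' @param magnet A [magnet_spec()].
#' @param n_magnets Number of magnets (default 5).
#' @param spacing_m Neighbour separation in metres (default 0.045).
#' @param arc_radius_m Arc radius in metres (default 0.10).
#' @return Object of class `necklace_model` with matrices `positions` and
#'   `moments` (one row per magnet).
#' @export
necklace_model <- function(magnet = magnet_spec(), n_magnets = 5,
                           spacing_m = 0.045, arc_radius_m = 0.10) {
  if (n_magnets < 1) stop("need at least one magnet")
  if (spacing_m >= 2 * arc_radius_m)
    stop("spacing must be smaller than the arc diameter")
  dg <- 2 * asin(spacing_m / (2 * arc_radius_m))
  gam <- (seq_len(n_magnets) - (n_magnets + 1) / 2) * dg
  positions <- cbind((cos(gam) - 1) * arc_radius_m,
                     sin(gam) * arc_radius_m,
                     rep(0, n_magnets))
  moments <- magnet$moment_Am2 * cbind(cos(gam), sin(gam), rep(0, n_magnets))
  structure(list(magnet = magnet, n_magnets = n_magnets,
                 spacing_m = spacing_m, arc_radius_m = arc_radius_m,
                 positions = positions, moments = moments),
            class = "necklace_model")
}

#' Total field of the necklace (plus an ambient field) at a point
#'
#' Superposition of the point-dipole fields of all magnets, plus an optional
#' constant ambient (Earth) field vector.
#'
#' @param necklace A [necklace_model()], or `NULL` for no magnets.
#' @param point Length-3 numeric evaluation point, m (necklace frame).
#' @param earth Length-3 ambient field vector in \eqn{\mu}T (default zero).
#' @return Length-3 field vector, \eqn{\mu}T.
#' @export
necklace_field <- function(necklace, point, earth = c(0, 0, 0)) {
  B <- as.numeric(earth)
  if (!is.null(necklace)) {
    for (i in seq_len(necklace$n_magnets)) {
      B <- B + dipole_field(necklace$moments[i, ], necklace$positions[i, ],
                            point)
    }
  }
  B
}

#' Simulation configuration
#'
#' Fixes the sensor model of the synthetic smartwatch stream: sampling rate,
#' ambient (Earth) magnetic field, per-axis Gaussian sensor noise, an
#' optional electromagnetic-disturbance burst model, and the mandatory
#' random seed.
#'
#' Defaults: 100 Hz; Earth field 45 \eqn{\mu}T (must lie in the surface
#' range 25--60 \eqn{\mu}T) with inclination -60 degrees and azimuth 0 in the
#' necklace frame; accelerometer noise 0.02 m/s\eqn{^2} per axis (typical of
#' a gravity-filtered consumer IMU channel); magnetometer noise 1 \eqn{\mu}T
#' per axis; EMF bursts off (`emf_rate_hz = 0`). Bursts, when enabled, occur
#' at Poisson times and add an exponentially decaying field of amplitude
#' `emf_amp_uT` and time constant `emf_tau_s` in a random direction.
#'
#' @param sample_rate_hz Samples per second for both sensors.
#' @param earth_field_uT Ambient field magnitude, \eqn{\mu}T, in \[25, 60\].
#' @param earth_inclination_deg,earth_azimuth_deg Ambient field direction in
#'   the necklace frame (negative inclination points above the horizon).
#' @param accel_noise_sd,mag_noise_sd Per-axis Gaussian noise standard
#'   deviations (m/s\eqn{^2}, \eqn{\mu}T).
#' @param emf_rate_hz,emf_amp_uT,emf_tau_s Burst disturbance model.
#' @param proximity_radius_m Radius around the necklace centre within which a
#'   gesture counts as reaching the face region (used to validate scripts).
#' @param seed Integer seed; mandatory, all stream randomness flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 100, earth_field_uT = 45,
                       earth_inclination_deg = -60, earth_azimuth_deg = 0,
                       accel_noise_sd = 0.02, mag_noise_sd = 1.0,
                       emf_rate_hz = 0, emf_amp_uT = 30, emf_tau_s = 0.05,
                       proximity_radius_m = 0.15, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("sim_config requires an explicit integer seed")
  if (earth_field_uT < 25 || earth_field_uT > 60)
    stop("earth_field_uT must lie in the surface range [25, 60]")
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  incl <- earth_inclination_deg * pi / 180
  az <- earth_azimuth_deg * pi / 180
  earth_vec <- earth_field_uT *
    c(cos(incl) * cos(az), cos(incl) * sin(az), -sin(incl))
  structure(list(sample_rate_hz = sample_rate_hz,
                 earth_field_uT = earth_field_uT,
                 earth_inclination_deg = earth_inclination_deg,
                 earth_azimuth_deg = earth_azimuth_deg,
                 earth_vec = earth_vec,
                 accel_noise_sd = accel_noise_sd,
                 mag_noise_sd = mag_noise_sd,
                 emf_rate_hz = emf_rate_hz, emf_amp_uT = emf_amp_uT,
                 emf_tau_s = emf_tau_s,
                 proximity_radius_m = proximity_radius_m,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Declarative wrist-trajectory script
#'
#' A gesture is a sequence of keyframes, each giving the wrist position in
#' the necklace frame (metres) and the wrist roll/pitch (degrees) at a time
#' point; the generator interpolates between them (minimum-jerk position,
#' linear angles). Face-touch scripts must end strictly inside the unsafe
#' orientation box and within `proximity_radius_m` of the necklace centre,
#' and must declare a `contact_window`.
#'
#' @param label One of `"face_touch"`, `"adl"`, `"rest"`,
#'   `"calibration_phase1"`, `"calibration_phase2"`.
#' @param duration_s Script duration in seconds (> 0).
#' @param keyframes data.frame with columns `time`, `x`, `y`, `z`, `theta`,
#'   `phi`; times strictly increasing within \[0, `duration_s`\].
#' @param contact_window Length-2 numeric \[start, end\] in seconds, the
#'   ground-truth contact interval (face-touch scripts only).
#' @param bounds Orientation bounds used to validate face-touch end poses.
#' @param proximity_radius_m Face-region radius used for validation.
#' @param script_id Optional identifier carried into generated streams.
#' @return Object of class `gesture_script`.
#' @export
gesture_script <- function(label, duration_s, keyframes,
                           contact_window = NULL,
                           bounds = orientation_bounds(),
                           proximity_radius_m = 0.15,
                           script_id = label) {
  labels_ok <- c("face_touch", "adl", "rest",
                 "calibration_phase1", "calibration_phase2")
  if (!label %in% labels_ok)
    stop("unknown script label: ", label)
  if (duration_s <= 0) stop("script duration must be positive")
  need <- c("time", "x", "y", "z", "theta", "phi")
  if (!all(need %in% names(keyframes)))
    stop("keyframes need columns ", paste(need, collapse = ", "))
  kt <- keyframes$time
  if (any(diff(kt) <= 0) || kt[1] < 0 || kt[length(kt)] > duration_s)
    stop("keyframe times must be strictly increasing within [0, duration]")
  if (label == "face_touch") {
    last <- keyframes[nrow(keyframes), ]
    if (!is_unsafe(last$theta, last$phi, bounds))
      stop("face_touch script must end inside the unsafe orientation box")
    if (sqrt(last$x^2 + last$y^2 + last$z^2) >= proximity_radius_m)
      stop("face_touch script must end within the proximity radius (",
           proximity_radius_m, " m) of the necklace")
    if (is.null(contact_window))
      stop("face_touch script needs a contact_window")
  }
  if (!is.null(contact_window) &&
      (length(contact_window) != 2 || contact_window[1] > contact_window[2]))
    stop("contact_window must be c(start, end) with start <= end")
  structure(list(label = label, duration_s = duration_s,
                 keyframes = keyframes, contact_window = contact_window,
                 script_id = script_id),
            class = "gesture_script")
}

# minimum-jerk time-scaling between consecutive keyframes (position);
# linear interpolation for angles
interp_pose <- function(keyframes, t) {
  kt <- keyframes$time
  nk <- length(kt)
  if (nk == 1) {
    one <- keyframes[rep(1, length(t)), c("x", "y", "z", "theta", "phi")]
    rownames(one) <- NULL
    return(one)
  }
  seg <- findInterval(t, kt, rightmost.closed = TRUE)
  seg[seg < 1] <- 1L
  seg[seg >= nk] <- nk - 1L
  tau <- (t - kt[seg]) / (kt[seg + 1L] - kt[seg])
  tau <- pmin(pmax(tau, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  lerp <- function(col, w) {
    v0 <- keyframes[[col]][seg]
    v0 + w * (keyframes[[col]][seg + 1L] - v0)
  }
  data.frame(x = lerp("x", s), y = lerp("y", s), z = lerp("z", s),
             theta = lerp("theta", tau), phi = lerp("phi", tau))
}

# world -> sensor frame rotation Rx(-theta) Ry(-phi) Rz(-psi), angles in deg;
# vectorised over samples, v is an n x 3 matrix in the world (necklace) frame
rotate_to_sensor <- function(v, theta_deg, phi_deg, psi_deg = 0) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  ps <- psi_deg * pi / 180
  # Rz(-psi)
  x1 <- cos(ps) * v[, 1] + sin(ps) * v[, 2]
  y1 <- -sin(ps) * v[, 1] + cos(ps) * v[, 2]
  z1 <- v[, 3]
  # Ry(-phi)
  x2 <- cos(ph) * x1 - sin(ph) * z1
  z2 <- sin(ph) * x1 + cos(ph) * z1
  # Rx(-theta)
  y3 <- cos(th) * y1 + sin(th) * z2
  z3 <- -sin(th) * y1 + cos(th) * z2
  cbind(x2, y3, z3, deparse.level = 0)
}

#' Generate a synthetic smartwatch sensor stream
#'
#' Renders a [gesture_script()] into a labelled sensor stream: the wrist pose
#' is interpolated (minimum-jerk position, linear angles), the accelerometer
#' reads the gravity vector rotated into the sensor frame, the magnetometer
#' reads the necklace-plus-Earth field at the wrist position rotated into the
#' sensor frame, and per-axis Gaussian noise (plus optional EMF bursts) is
#' added. Gravity is taken as 9.81 m/s\eqn{^2}.
#'
#' @param script A [gesture_script()].
#' @param necklace A [necklace_model()], or `NULL` to simulate a wearer
#'   without magnets.
#' @param cfg A [sim_config()].
#' @param seed Seed for this stream; defaults to `cfg$seed`.
#' @return data.frame with columns `t`, `ax`, `ay`, `az` (m/s\eqn{^2}),
#'   `mx`, `my`, `mz` (\eqn{\mu}T), `label`, `contact` (logical, inside the
#'   script's contact window). The script is attached as attribute
#'   `"script"`.
#' @export
generate_stream <- function(script, necklace = NULL, cfg, seed = cfg$seed) {
  if (!inherits(script, "gesture_script")) stop("script must be a gesture_script")
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  n <- round(script$duration_s * cfg$sample_rate_hz)
  if (n < 1) stop("empty stream: zero-duration script")
  t <- (seq_len(n) - 1) / cfg$sample_rate_hz
  pose <- interp_pose(script$keyframes, t)
  th <- pose$theta * pi / 180
  ph <- pose$phi * pi / 180
  g <- 9.81
  accel <- cbind(-g * sin(ph), g * sin(th) * cos(ph), g * cos(th) * cos(ph))
  B_world <- matrix(rep(cfg$earth_vec, each = n), ncol = 3)
  if (!is.null(necklace)) {
    for (i in seq_len(necklace$n_magnets)) {
      src <- necklace$positions[i, ]
      mom <- necklace$moments[i, ]
      rx <- pose$x - src[1]; ry <- pose$y - src[2]; rz <- pose$z - src[3]
      rn <- sqrt(rx^2 + ry^2 + rz^2)
      if (any(rn == 0)) stop("singularity: trajectory crosses a magnet")
      mdotr <- (mom[1] * rx + mom[2] * ry + mom[3] * rz) / rn
      B_world[, 1] <- B_world[, 1] + 0.1 * (3 * rx / rn * mdotr - mom[1]) / rn^3
      B_world[, 2] <- B_world[, 2] + 0.1 * (3 * ry / rn * mdotr - mom[2]) / rn^3
      B_world[, 3] <- B_world[, 3] + 0.1 * (3 * rz / rn * mdotr - mom[3]) / rn^3
    }
  }
  mag <- rotate_to_sensor(B_world, pose$theta, pose$phi)
  withr::with_seed(seed, {
    if (cfg$accel_noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, 0, cfg$accel_noise_sd),
                              ncol = 3)
    if (cfg$mag_noise_sd > 0)
      mag <- mag + matrix(stats::rnorm(3 * n, 0, cfg$mag_noise_sd), ncol = 3)
    if (cfg$emf_rate_hz > 0) {
      n_ev <- stats::rpois(1, cfg$emf_rate_hz * script$duration_s)
      if (n_ev > 0) {
        te <- sort(stats::runif(n_ev, 0, script$duration_s))
        for (k in seq_len(n_ev)) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          amp <- cfg$emf_amp_uT * exp(-(t - te[k]) / cfg$emf_tau_s)
          amp[t < te[k]] <- 0
          mag <- mag + outer(amp, dir)
        }
      }
    }
  })
  contact <- if (is.null(script$contact_window)) rep(FALSE, n) else
    (t >= script$contact_window[1] & t <= script$contact_window[2])
  out <- data.frame(t = t, ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    mx = mag[, 1], my = mag[, 2], mz = mag[, 3],
                    label = script$label, contact = contact)
  attr(out, "script") <- script
  out
}

#' Built-in gesture script library
#'
#' Script builders for the simulated benchmark protocol. All positions are in
#' the necklace frame (origin at the central magnet, x forward, z up), all
#' angles in degrees.
#'
#' `script_face_touch()` raises the hand from a lowered rest pose to the face
#' region (about 11 cm above/in front of the necklace centre) in roughly one
#' second -- face-touch attempts are short -- rotating the wrist into the
#' unsafe box, then holds at the face; the contact window spans the hold.
#' `script_adl()` builds one of four confounder gestures (spoon-to-mouth, mug
#' drink, hair comb, shirt pull) that rotate the wrist into the unsafe box
#' with a rising pitch but keep the watch outside the face region.
#' `script_rest()` holds a still pose far from the necklace (used for the
#' inertial calibration), and `script_calibration()` returns the two-phase
#' magnetometer calibration movement (2 s still far from the magnets, then a
#' 3 s approach stopping about 20 cm away).
#'
#' @param rest_s,rise_s,hold_s Segment durations, s.
#' @param end_pos Length-3 end position, m.
#' @param end_angles Length-2 end `c(theta, phi)`, degrees.
#' @param proximity_radius_m Face-region radius for validation.
#' @param script_id Identifier carried into the stream.
#' @return A [gesture_script()].
#' @name gesture_library
NULL

#' @rdname gesture_library
#' @export
script_face_touch <- function(rest_s = 0.6, rise_s = 1.1, hold_s = 0.9,
                              end_pos = c(0.06, 0.02, 0.09),
                              end_angles = c(-15, 70),
                              proximity_radius_m = 0.15,
                              script_id = "face_touch") {
  start_pos <- c(0.30, -0.10, -0.30)
  dur <- rest_s + rise_s + hold_s
  kf <- data.frame(
    time = c(0, rest_s, rest_s + rise_s, dur),
    x = c(start_pos[1], start_pos[1], end_pos[1], end_pos[1]),
    y = c(start_pos[2], start_pos[2], end_pos[2], end_pos[2]),
    z = c(start_pos[3], start_pos[3], end_pos[3], end_pos[3]),
    theta = c(0, 0, end_angles[1], end_angles[1]),
    phi = c(0, 0, end_angles[2], end_angles[2]))
  gesture_script("face_touch", dur, kf,
                 contact_window = c(rest_s + rise_s, dur),
                 proximity_radius_m = proximity_radius_m,
                 script_id = script_id)
}

adl_poses <- list(
  spoon = list(end_pos = c(0.22, 0.05, 0.12), end_angles = c(-10, 60)),
  mug   = list(end_pos = c(0.24, -0.06, 0.10), end_angles = c(10, 55)),
  comb  = list(end_pos = c(0.15, 0.08, 0.28), end_angles = c(-30, 75)),
  shirt = list(end_pos = c(0.10, 0.00, -0.25), end_angles = c(-30, 40)))

#' @rdname gesture_library
#' @param type ADL type: `"spoon"`, `"mug"`, `"comb"` or `"shirt"`.
#' @export
script_adl <- function(type = c("spoon", "mug", "comb", "shirt"),
                       rest_s = 0.6, rise_s = 0.9, hold_s = 1.0,
                       end_pos = NULL, end_angles = NULL,
                       script_id = NULL) {
  type <- match.arg(type)
  base <- adl_poses[[type]]
  if (is.null(end_pos)) end_pos <- base$end_pos
  if (is.null(end_angles)) end_angles <- base$end_angles
  start_pos <- c(0.35, -0.10, -0.20)
  dur <- rest_s + rise_s + hold_s
  kf <- data.frame(
    time = c(0, rest_s, rest_s + rise_s, dur),
    x = c(start_pos[1], start_pos[1], end_pos[1], start_pos[1]),
    y = c(start_pos[2], start_pos[2], end_pos[2], start_pos[2]),
    z = c(start_pos[3], start_pos[3], end_pos[3], start_pos[3]),
    theta = c(0, 0, end_angles[1], 0),
    phi = c(0, 0, end_angles[2], 0))
  gesture_script("adl", dur, kf,
                 script_id = if (is.null(script_id)) paste0("adl_", type)
                             else script_id)
}

#' @rdname gesture_library
#' @param duration_s Script duration, s.
#' @param pos Still wrist position, m.
#' @export
script_rest <- function(duration_s = 2, pos = c(0.35, -0.05, -0.25)) {
  kf <- data.frame(time = 0, x = pos[1], y = pos[2], z = pos[3],
                   theta = 0, phi = 0)
  gesture_script("rest", duration_s, kf, script_id = "rest")
}

#' @rdname gesture_library
#' @param phase1_s,phase2_s Durations of the still phase and of the approach
#'   phase, s.
#' @export
script_calibration <- function(phase1_s = 2, phase2_s = 3) {
  p1_pos <- c(0.35, 0, -0.05)
  p2_pos <- c(0.19, 0, 0.055)   # about 20 cm from the necklace centre
  list(
    phase1 = gesture_script(
      "calibration_phase1", phase1_s,
      data.frame(time = 0, x = p1_pos[1], y = p1_pos[2], z = p1_pos[3],
                 theta = 0, phi = 0),
      script_id = "calibration_phase1"),
    phase2 = gesture_script(
      "calibration_phase2", phase2_s,
      data.frame(time = c(0, phase2_s),
                 x = c(p1_pos[1], p2_pos[1]), y = c(p1_pos[2], p2_pos[2]),
                 z = c(p1_pos[3], p2_pos[3]),
                 theta = c(0, 0), phi = c(0, 20)),
      script_id = "calibration_phase2"))
}

#' Simulate the two-phase magnetometer calibration movement
#'
#' Generates the concatenated phase-1 (still, far) and phase-2 (approach to
#' about 20 cm) streams as one time-continuous recording, ready for
#' [mag_calibrate()].
#'
#' @param necklace A [necklace_model()].
#' @param cfg A [sim_config()].
#' @param seed Seed for the stream noise; defaults to `cfg$seed`.
#' @return A sensor-stream data.frame spanning both phases.
#' @export
make_calibration_stream <- function(necklace, cfg, seed = cfg$seed) {
  sc <- script_calibration()
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, 2))
  s1 <- generate_stream(sc$phase1, necklace, cfg, seed = seeds[1])
  s2 <- generate_stream(sc$phase2, necklace, cfg, seed = seeds[2])
  s2$t <- s2$t + sc$phase1$duration_s
  out <- rbind(s1, s2)
  attr(out, "script") <- NULL
  out
}

#' Simulated benchmark: face-touch and ADL trials
#'
#' Generates, in silico, the laboratory comparison protocol: `n_touch`
#' face-touch gestures and `n_adl` activity-of-daily-living gestures (drawn
#' from the built-in spoon / mug / comb / shirt library), in pseudorandom
#' order, with jittered timing, end poses and angles. All randomness flows
#' from `seed`; the same seed reproduces the benchmark bit for bit.
#'
#' @param n_touch,n_adl Trial counts (>= 1).
#' @param necklace A [necklace_model()].
#' @param cfg A [sim_config()].
#' @param seed Master seed; defaults to `cfg$seed`.
#' @return Object of class `ft_benchmark`: a list of trials, each with
#'   `stream`, `script`, `label`, `contact_window`, `script_id`.
#' @export
make_benchmark <- function(n_touch = 30, n_adl = 30,
                           necklace = necklace_model(), cfg,
                           seed = cfg$seed) {
  if (n_touch < 1 || n_adl < 1) stop("counts must be >= 1")
  n <- n_touch + n_adl
  plan <- withr::with_seed(seed, {
    jit <- function(lo, hi, k) stats::runif(k, lo, hi)
    scripts <- vector("list", n)
    for (i in seq_len(n_touch)) {
      scripts[[i]] <- script_face_touch(
        rise_s = 1.1 * jit(0.85, 1.15, 1),
        end_pos = c(0.06, 0.02, 0.09) + jit(-0.015, 0.015, 3),
        end_angles = c(-15, 70) + jit(-8, 8, 2),
        script_id = sprintf("touch_%02d", i))
    }
    types <- rep(c("spoon", "mug", "comb", "shirt"), length.out = n_adl)
    for (j in seq_len(n_adl)) {
      base <- adl_poses[[types[j]]]
      scripts[[n_touch + j]] <- script_adl(
        types[j],
        rise_s = 0.9 * jit(0.85, 1.15, 1),
        end_pos = base$end_pos + jit(-0.015, 0.015, 3),
        end_angles = base$end_angles + jit(-8, 8, 2),
        script_id = sprintf("adl_%02d_%s", j, types[j]))
    }
    list(scripts = scripts,
         order = sample.int(n),
         seeds = sample.int(2^31 - 2, n))
  })
  trials <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- plan$order[k]
    sc <- plan$scripts[[idx]]
    stream <- generate_stream(sc, necklace, cfg, seed = plan$seeds[idx])
    trials[[k]] <- list(stream = stream, script = sc, label = sc$label,
                        contact_window = sc$contact_window,
                        script_id = sc$script_id)
  }
  structure(trials, class = "ft_benchmark",
            seed = seed, n_touch = n_touch, n_adl = n_adl)
}
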