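#' Wrist roll and pitch from the sensed gravity vector
#'
#' Reconstructs the wrist orientation from the gravity components measured by
#' a triaxial accelerometer at (quasi-)static instants. Roll is the rotation
#' about the longitudinal (x) sensor axis, pitch about the transverse (y)
#' axis; yaw is deliberately not estimated, since any yaw is compatible with a
#' hand-to-face movement.
#'
#' The decomposition is the standard gravity-vector one,
#' \deqn{\theta = \mathrm{atan2}(a_y, a_z)\,180/\pi, \qquad
#'       \phi   = \mathrm{atan2}(-a_x, \sqrt{a_y^2 + a_z^2})\,180/\pi,}
#' so pitch lies in \[-90, 90\] by construction and roll in (-180, 180\].
#' Only ratios of the components enter the arctangents, so readings in
#' m/s\eqn{^2} or in g-units give identical angles.
#'
#' @param ax,ay,az Numeric vectors of equal length: acceleration components in
#'   the sensor frame (m/s\eqn{^2} or any common unit).
#' @return A data.frame with columns `theta` (roll, degrees) and `phi`
#'   (pitch, degrees), one row per input sample.
#' @examples
#' estimate_angles(0, 0, 9.81)    # flat wrist: theta = 0, phi = 0
#' estimate_angles(-9.81, 0, 0)   # hand pointing up: phi = 90
#' @export
estimate_angles <- function(ax, ay, az) {
  if (!is.numeric(ax) || !is.numeric(ay) || !is.numeric(az))
    stop("accelerometer components must be numeric")
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop("ax, ay, az must have equal length")
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(!is.finite(mag)))
    stop("non-finite accelerometer reading")
  if (any(mag == 0))
    stop("zero-magnitude accelerometer reading (sensor dropout)")
  data.frame(
    theta = atan2(ay, az) * 180 / pi,
    phi   = atan2(-ax, sqrt(ay^2 + az^2)) * 180 / pi
  )
}

#' Safe/unsafe wrist-orientation bounds
#'
#' The unsafe box is the set of roll/pitch combinations compatible with a
#' natural face-touch, determined empirically for a watch worn on the
#' non-dominant arm. Defaults are
#' right-handed: \eqn{-90 < \theta < 70}, \eqn{30 < \phi < 100};
#' left-handed: \eqn{-70 < \theta < 90}, \eqn{-100 < \phi < -30}
#' (the mirrored box, because the watch is worn the other way up).
#' Any bound can be overridden, e.g. to narrow the box for nail-biting
#' monitoring.
#'
#' @param handedness `"right"` or `"left"`.
#' @param theta_min,theta_max,phi_min,phi_max Optional numeric overrides in
#'   degrees; `NULL` keeps the handedness default.
#' @return An object of class `orientation_bounds`.
#' @seealso [is_unsafe()], [read_bounds_config()]
#' @export
orientation_bounds <- function(handedness = c("right", "left"),
                               theta_min = NULL, theta_max = NULL,
                               phi_min = NULL, phi_max = NULL) {
  if (!is.character(handedness) ||
      !all(handedness %in% c("right", "left")))
    stop("unknown handedness: must be \"right\" or \"left\"")
  handedness <- match.arg(handedness)
  defaults <- if (handedness == "right") {
    c(theta_min = -90, theta_max = 70, phi_min = 30, phi_max = 100)
  } else {
    c(theta_min = -70, theta_max = 90, phi_min = -100, phi_max = -30)
  }
  b <- list(
    theta_min = if (is.null(theta_min)) defaults[["theta_min"]] else theta_min,
    theta_max = if (is.null(theta_max)) defaults[["theta_max"]] else theta_max,
    phi_min   = if (is.null(phi_min)) defaults[["phi_min"]] else phi_min,
    phi_max   = if (is.null(phi_max)) defaults[["phi_max"]] else phi_max,
    handedness = handedness
  )
  if (!(b$theta_min < b$theta_max) || !(b$phi_min < b$phi_max))
    stop("invalid bounds: need theta_min < theta_max and phi_min < phi_max")
  structure(b, class = "orientation_bounds")
}

#' @export
print.orientation_bounds <- function(x, ...) {
  cat(sprintf(
    "Orientation bounds (%s-handed): %g < theta < %g, %g < phi < %g [deg]\n",
    x$handedness, x$theta_min, x$theta_max, x$phi_min, x$phi_max))
  invisible(x)
}

#' Classify a wrist orientation as unsafe (face-touch compatible)
#'
#' Returns `TRUE` when the orientation lies strictly inside the unsafe box,
#' i.e. \eqn{\theta_{min} < \theta < \theta_{max}} and
#' \eqn{\phi_{min} < \phi < \phi_{max}}. Inequalities are strict, so angles
#' exactly on a boundary classify as safe.
#'
#' @param theta,phi Numeric vectors of roll and pitch in degrees.
#' @param bounds An [orientation_bounds()] object.
#' @return Logical vector: `TRUE` = unsafe (compatible with a face-touch).
#' @export
is_unsafe <- function(theta, phi, bounds = orientation_bounds()) {
  if (!inherits(bounds, "orientation_bounds"))
    stop("bounds must be an orientation_bounds object")
  (theta > bounds$theta_min & theta < bounds$theta_max &
     phi > bounds$phi_min & phi < bounds$phi_max)
}
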