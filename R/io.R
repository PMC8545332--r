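#' Read a sensor-stream CSV
#'
#' The stream format is a plain CSV with header
#' `t,ax,ay,az,mx,my,mz`: time in seconds, acceleration in m/s\eqn{^2},
#' magnetic field in \eqn{\mu}T. The magnetometer columns may be absent
#' (a watch without that sensor); the accelerometer-only detector still
#' works on such a stream.
#'
#' @param path File path.
#' @return data.frame with the stream columns, timestamps sorted.
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("stream CSV needs at least columns ", paste(need, collapse = ", "))
  if (is.unsorted(df$t, strictly = TRUE))
    stop("stream timestamps must be strictly increasing")
  df
}

#' Write a sensor stream (and optional labels sidecar) to CSV
#'
#' @param stream Stream data.frame (from [generate_stream()] or assembled
#'   manually).
#' @param path Output CSV for the sensor columns `t,ax,ay,az,mx,my,mz`.
#' @param labels_path Optional sidecar CSV receiving `t,label,script_id,
#'   contact` when the stream carries labels.
#' @param script_id Identifier written to the sidecar; defaults to the
#'   attached script's id.
#' @return Invisibly, `path`.
#' @export
write_stream_csv <- function(stream, path, labels_path = NULL,
                             script_id = NULL) {
  cols <- intersect(c("t", "ax", "ay", "az", "mx", "my", "mz"),
                    names(stream))
  utils::write.csv(stream[cols], path, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(stream$label))
      stop("stream carries no labels to write")
    if (is.null(script_id)) {
      sc <- attr(stream, "script")
      script_id <- if (!is.null(sc)) sc$script_id else "stream"
    }
    lab <- data.frame(t = stream$t, label = stream$label,
                      script_id = script_id,
                      contact = if (is.null(stream$contact)) FALSE
                                else stream$contact)
    utils::write.csv(lab, labels_path, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize a detector calibration to JSON
#'
#' @param cal A [mag_calibration()] or [imu_calibration()] object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_calibration_json <- function(cal, path) {
  if (inherits(cal, "mag_calibration")) {
    obj <- list(algo = "mag", phi_bar = cal$phi_bar,
                sigma_phi = cal$sigma_phi, phi_hat = cal$phi_hat,
                alpha = cal$alpha, buffer = cal$buffer,
                sample_rate_hz = cal$sample_rate_hz,
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  } else if (inherits(cal, "imu_calibration")) {
    obj <- list(algo = "imu", beta = cal$beta,
                sigma_phidot = cal$sigma_phidot,
                sample_rate_hz = cal$sample_rate_hz,
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  } else stop("cal must be a mag_calibration or imu_calibration")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detector calibration from JSON
#'
#' @param path JSON path written by [write_calibration_json()].
#' @return A [mag_calibration()] or [imu_calibration()] object, depending on
#'   the stored `algo` field.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$algo, "mag")) {
    mag_calibration(phi_bar = obj$phi_bar, sigma_phi = obj$sigma_phi,
                    alpha = obj$alpha,
                    phi_hat = if (is.null(obj$phi_hat)) NA_real_
                              else obj$phi_hat,
                    buffer = obj$buffer,
                    sample_rate_hz = obj$sample_rate_hz)
  } else if (identical(obj$algo, "imu")) {
    imu_calibration(beta = obj$beta, sigma_phidot = obj$sigma_phidot,
                    sample_rate_hz = obj$sample_rate_hz)
  } else stop("unknown calibration algo in ", path)
}

#' Write classified alert events to a textual log file
#'
#' One line per event, format `start_iso,end_iso,kind,duration_s` with
#' millisecond timestamps; `kind` is TA or HC and `duration_s` the recorded
#' duration (excess over 1 s for HCs).
#'
#' @param events Classified events from [classify_touch()].
#' @param path Output path.
#' @param origin POSIXct (or parseable string) mapping stream second 0 to
#'   wall-clock time.
#' @return Invisibly, `path`.
#' @export
write_event_log <- function(events, path,
                            origin = as.POSIXct("2026-01-01 00:00:00",
                                                tz = "UTC")) {
  origin <- as.POSIXct(origin, tz = "UTC")
  iso <- function(s) format(origin + s, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  df <- data.frame(start_iso = iso(events$start_s),
                   end_iso = iso(events$end_s),
                   kind = events$kind,
                   duration_s = events$recorded_duration_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a textual event log
#'
#' @param path Path written by [write_event_log()].
#' @return data.frame with `start_iso`, `end_iso`, `kind`, `duration_s` and
#'   parsed `start_s`/`end_s` relative to the first event's day start.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_iso", "end_iso", "kind", "duration_s")
  if (!all(need %in% names(df)))
    stop("event log needs columns ", paste(need, collapse = ", "))
  parse <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS",
                                  tz = "UTC")
  start <- parse(df$start_iso)
  end <- parse(df$end_iso)
  df$start_s <- as.numeric(start) - as.numeric(trunc(start[1], "days"))
  df$end_s <- as.numeric(end) - as.numeric(trunc(start[1], "days"))
  df
}

#' Read an orientation-bounds config file (YAML or JSON)
#'
#' Recognized keys: `handedness`, `theta_min`, `theta_max`, `phi_min`,
#' `phi_max` (degrees). Missing keys fall back to the handedness defaults.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return An [orientation_bounds()] object.
#' @export
read_bounds_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  orientation_bounds(
    handedness = if (is.null(cfg$handedness)) "right" else cfg$handedness,
    theta_min = cfg$theta_min, theta_max = cfg$theta_max,
    phi_min = cfg$phi_min, phi_max = cfg$phi_max)
}

#' Read a simulator config file (YAML)
#'
#' Any key of [sim_config()] may appear; `seed` is mandatory.
#'
#' @param path YAML path.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  do.call(sim_config, cfg[intersect(names(cfg), known)])
}
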