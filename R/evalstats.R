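#' Segment a per-sample alert series into alert events
#'
#' Maximal runs of `TRUE` become events spanning from the first to the last
#' flagged sample; consecutive events separated by a gap shorter than
#' `min_gap_s` are merged (default 0: no merging, so isolated flagged
#' samples become zero-duration events).
#'
#' @param t Numeric vector of strictly increasing timestamps, s.
#' @param alert Logical vector of the same length.
#' @param min_gap_s Gaps shorter than this merge adjacent events, s.
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`.
#' @export
segment_alerts <- function(t, alert, min_gap_s = 0) {
  if (length(t) != length(alert)) stop("t and alert must have equal length")
  if (length(t) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0)))
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  alert <- as.logical(alert)
  r <- rle(alert)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ev <- data.frame(start_s = t[starts[keep]], end_s = t[ends[keep]])
  if (nrow(ev) > 1 && min_gap_s > 0) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev$start_s[i] - merged$end_s[nrow(merged)] < min_gap_s) {
        merged$end_s[nrow(merged)] <- ev$end_s[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  ev$duration_s <- ev$end_s - ev$start_s
  rownames(ev) <- NULL
  ev
}

#' Classify alert events as touch attempts or happened contacts
#'
#' Events shorter than 1 second are Touch Attempts (TA): the gesture was
#' aborted in time. Events lasting 1 second or more are Happened Contacts
#' (HC), and the recorded duration is the time in excess of the 1-second
#' threshold (an event of exactly 1 s is an HC of recorded duration 0).
#'
#' @param events data.frame from [segment_alerts()] (columns `start_s`,
#'   `end_s`, `duration_s`), or a numeric vector of durations.
#' @param threshold_s TA/HC boundary, s (default 1).
#' @return The events data.frame with added columns `kind` (`"TA"`/`"HC"`)
#'   and `recorded_duration_s` (raw duration for TAs, excess over the
#'   threshold for HCs).
#' @export
classify_touch <- function(events, threshold_s = 1) {
  if (is.numeric(events))
    events <- data.frame(start_s = 0, end_s = events, duration_s = events)
  d <- events$duration_s
  if (any(d < 0)) stop("negative event duration")
  events$kind <- ifelse(d < threshold_s, "TA", "HC")
  events$recorded_duration_s <- ifelse(d < threshold_s, d, d - threshold_s)
  events
}

#' Detection-accuracy metrics over a labelled benchmark
#'
#' Computes the laboratory comparison metrics: the correct-detection
#' percentage is the share of face-touch trials with at least one alert
#' sample inside the trial's contact window (widened by `contact_tol_s` on
#' each side, since the ground-truth window edge is itself approximate), and
#' the false-positive percentage is the share of ADL trials with at least
#' one alert anywhere. Alert events across all trials are additionally
#' segmented and classified into TA/HC rates per monitored hour.
#'
#' @param results A list with one element per trial, each a list with
#'   `label` (`"face_touch"` or other), `contact` (length-2 window or
#'   `NULL`), `t`, `alert`.
#' @param contact_tol_s Matching tolerance around the contact window, s.
#' @param min_gap_s Event-merging gap passed to [segment_alerts()].
#' @return Object of class `metrics_report`: `correct_detection_pct`,
#'   `false_positive_pct`, `ta_per_hour`, `hc_per_hour`, `hc_durations`,
#'   `n_touch`, `n_adl`, `monitored_s`.
#' @export
detection_metrics <- function(results, contact_tol_s = 0.5, min_gap_s = 0) {
  is_touch <- vapply(results, function(r) identical(r$label, "face_touch"),
                     logical(1))
  n_touch <- sum(is_touch)
  n_adl <- sum(!is_touch)
  if (n_touch == 0 || n_adl == 0)
    stop("undefined metric: need at least one face-touch and one ADL trial")
  correct <- 0L
  fp <- 0L
  monitored_s <- 0
  all_events <- list()
  for (r in results) {
    monitored_s <- monitored_s + (r$t[length(r$t)] - r$t[1])
    if (identical(r$label, "face_touch")) {
      w <- r$contact
      hit <- any(r$alert & r$t >= w[1] - contact_tol_s &
                   r$t <= w[2] + contact_tol_s)
      correct <- correct + hit
    } else {
      fp <- fp + any(r$alert)
    }
    ev <- segment_alerts(r$t, r$alert, min_gap_s)
    if (nrow(ev) > 0) all_events[[length(all_events) + 1]] <- ev
  }
  events <- if (length(all_events)) classify_touch(do.call(rbind, all_events))
            else classify_touch(data.frame(start_s = numeric(0),
                                           end_s = numeric(0),
                                           duration_s = numeric(0)))
  hours <- monitored_s / 3600
  structure(list(
    correct_detection_pct = 100 * correct / n_touch,
    false_positive_pct = 100 * fp / n_adl,
    ta_per_hour = sum(events$kind == "TA") / hours,
    hc_per_hour = sum(events$kind == "HC") / hours,
    hc_durations = events$recorded_duration_s[events$kind == "HC"],
    n_touch = n_touch, n_adl = n_adl, monitored_s = monitored_s),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("Detection metrics over %d face-touch + %d ADL trials ",
           "(%.1f s monitored):\n  correct detections %.1f%%   ",
           "false positives %.1f%%\n  %.1f TA/hour   %.1f HC/hour\n"),
    x$n_touch, x$n_adl, x$monitored_s, x$correct_detection_pct,
    x$false_positive_pct, x$ta_per_hour, x$hc_per_hour))
  invisible(x)
}

#' Run a detector over a benchmark and compute its metrics
#'
#' @param benchmark An `ft_benchmark` from [make_benchmark()].
#' @param det A freshly calibrated detector state; each trial is processed
#'   with its own copy, so trials are independent.
#' @param contact_tol_s,min_gap_s Passed to [detection_metrics()].
#' @return A `metrics_report`.
#' @export
evaluate_benchmark <- function(benchmark, det, contact_tol_s = 0.5,
                               min_gap_s = 0) {
  results <- lapply(benchmark, function(trial) {
    res <- run_detector(det, trial$stream)
    list(label = trial$label, contact = trial$contact_window,
         t = res$t, alert = res$alert)
  })
  detection_metrics(results, contact_tol_s = contact_tol_s,
                    min_gap_s = min_gap_s)
}

#' Paired-samples t-test summary
#'
#' Classical paired t-test on the differences `x - y`, two-sided.
#'
#' @param x,y Numeric vectors of equal length n >= 2 (paired conditions).
#' @return A list with `mean_diff`, `t`, `df` (= n - 1), `p`.
#' @export
paired_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2) stop("need at least 2 pairs")
  if (stats::sd(x - y) == 0)
    stop("degenerate input: zero variance of the paired differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(mean_diff = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Normality gate with square-root fallback
#'
#' Shapiro-Wilk test on the raw values; when normality is rejected at the
#' 0.05 level the values are square-root transformed (they must be
#' non-negative) and re-tested, flagging the transform.
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @param alpha Rejection level for the raw-scale test (default 0.05).
#' @return A list with `W`, `p` (raw scale), `transformed` (logical) and,
#'   when transformed, `W_transformed`, `p_transformed`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0)
    stop("undefined W: constant input")
  sw <- stats::shapiro.test(values)
  out <- list(W = unname(sw$statistic), p = sw$p.value, transformed = FALSE)
  if (sw$p.value <= alpha) {
    if (any(values < 0))
      stop("square-root transform requested for negative values")
    sw2 <- stats::shapiro.test(sqrt(values))
    out$transformed <- TRUE
    out$W_transformed <- unname(sw2$statistic)
    out$p_transformed <- sw2$p.value
  }
  out
}

#' Post-hoc power of a paired t-test
#'
#' Power computed from the noncentral t distribution with noncentrality
#' \eqn{\delta = d_z \sqrt{n}} and \eqn{n - 1} degrees of freedom, where
#' \eqn{d_z} is the standardized mean difference of the paired samples
#' (mean of differences over their standard deviation).
#'
#' @param n Number of pairs (>= 2).
#' @param effect_size_dz Standardized paired effect size \eqn{d_z > 0}.
#' @param alpha Significance level in (0, 1).
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Power in \[0, 1\].
#' @export
posthoc_power <- function(n, effect_size_dz, alpha = 0.05,
                          two_sided = TRUE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n < 2) stop("need n >= 2")
  if (effect_size_dz <= 0) stop("effect size must be positive")
  df <- n - 1
  ncp <- effect_size_dz * sqrt(n)
  if (two_sided) {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp = ncp)
  }
}

#' Fraction of values within k standard deviations of the mean
#'
#' For Gaussian data and `k = 3` this approaches 99.7%, the theoretical
#' basis for the minimum magnetometer threshold multiplier.
#'
#' @param x Numeric vector.
#' @param k Number of standard deviations (default 3).
#' @return Fraction of `x` within `mean(x) +/- k * sd(x)`.
#' @export
coverage_within <- function(x, k = 3) {
  mean(abs(x - mean(x)) <= k * stats::sd(x))
}
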