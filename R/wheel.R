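# A measurement that cannot be computed is reported as NA carrying the
# reason as an attribute, so scoring can propagate it per policy.
missing_value <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Reason a measurement is missing
#' @param x A numeric measurement result.
#' @return The reason string, or `NULL` if the value is present.
#' @export
missing_reason <- function(x) {
  if (length(x) == 1 && is.na(x)) {
    r <- attr(x, "reason")
    if (is.null(r)) "missing" else r
  } else {
    NULL
  }
}

#' Decode wheel-marker states by Viterbi
#'
#' Decodes per-frame wheel-marker classifier outputs into a
#' maximum-a-posteriori sequence of marker states over `{top, bottom}`
#' under a symmetric two-state hidden Markov model. The per-frame
#' observation likelihoods are `P(obs | top) = p_top` and
#' `P(obs | bottom) = 1 - p_top`; both transition directions share the
#' self-transition probability `p_stay`. Computation is in log space, so
#' sequences of a million frames or more decode without underflow. Ties
#' between staying and switching are broken toward staying.
#'
#' @param p_top Numeric vector of per-frame top-state probabilities in
#'   `[0, 1]`.
#' @param p_stay Self-transition probability in `(0, 1)`. Default 0.98.
#' @param init Initial state distribution `c(bottom, top)`; default
#'   uniform.
#' @return Character vector of states, `"bottom"`/`"top"`, one per frame.
#' @export
viterbi_decode <- function(p_top, p_stay = 0.98, init = c(0.5, 0.5)) {
  if (length(p_top) == 0) stop("empty emission sequence")
  if (any(is.na(p_top)) || any(p_top < 0) || any(p_top > 1)) {
    stop("p_top values must be in [0, 1]")
  }
  if (p_stay <= 0 || p_stay >= 1) stop("p_stay must be in (0, 1)")
  if (length(init) != 2 || any(init <= 0) || abs(sum(init) - 1) > 1e-8) {
    stop("init must be a 2-element distribution over (bottom, top)")
  }
  path <- .viterbi_core(as.numeric(p_top), p_stay, as.numeric(init))
  c("bottom", "top")[path + 1L]
}

#' Rotation events from a decoded state sequence
#'
#' The wheel carries a single marker stripe, so each full rotation
#' produces exactly one bottom-to-top marker transition (direction of
#' rotation is not distinguishable). Each such transition is emitted as
#' one rotation event, stamped with the time of the first `top` frame.
#'
#' @param states Character vector over `"bottom"`/`"top"`.
#' @param frame_times `POSIXct` or numeric times, one per frame.
#' @return Vector of event times (same type as `frame_times`), possibly
#'   empty.
#' @export
rotations_from_states <- function(states, frame_times) {
  if (length(states) != length(frame_times)) {
    stop("states and frame_times must have equal length")
  }
  n <- length(states)
  if (n < 2) return(frame_times[0])
  up <- which(states[-1] == "top" & states[-n] == "bottom") + 1L
  frame_times[up]
}

#' Average per-day wheel running distance
#'
#' @param events Rotation event times within the period.
#' @param period One row of a [derive_periods()] table (needs
#'   `n_full_days`).
#' @param calib A [cage_calibration()] supplying the wheel circumference.
#' @return Metres per day.
#' @export
wheel_distance_per_day <- function(events, period, calib) {
  stopifnot(inherits(calib, "cage_calibration"))
  length(events) * calib$wheel_circumference_m / period$n_full_days
}

#' Wheel gait speed
#'
#' Per-rotation speeds are the wheel circumference divided by the
#' inter-rotation interval, computed only within running bouts (intervals
#' of at most `bout_gap_s` seconds). The returned summary is a percentile
#' of those in-bout speeds — a peak-performance statistic robust to idle
#' time.
#'
#' @param events Rotation event times.
#' @param calib A [cage_calibration()].
#' @param bout_gap_s Maximum in-bout inter-rotation interval, seconds.
#'   Default 2.
#' @param percentile Percentile in (0, 1]. Default 0.9.
#' @return Speed in m/s, or a missing value (`NA` with a `reason`
#'   attribute) when no bout contains two rotations.
#' @export
wheel_gait_speed <- function(events, calib, bout_gap_s = 2, percentile = 0.9) {
  stopifnot(inherits(calib, "cage_calibration"))
  t <- as.numeric(events)
  if (length(t) < 2) return(missing_value("fewer than 2 rotation events"))
  dt <- diff(t)
  dt <- dt[dt <= bout_gap_s & dt > 0]
  if (length(dt) == 0) return(missing_value("no in-bout rotation pairs"))
  speeds <- calib$wheel_circumference_m / dt
  as.numeric(stats::quantile(speeds, percentile, names = FALSE, type = 7))
}

#' Dark-phase activity fraction
#'
#' The circadian summary used for both wheel and floor activity: the
#' fraction of total activity weight that falls in the dark phase of the
#' light cycle. Intact nocturnal rhythm gives values near 1; arrhythmic
#' activity spread uniformly over 24 h gives the dark-phase duty fraction
#' (0.5 under a 12:12 cycle).
#'
#' @param times Event or bin times (`POSIXct` or numeric UTC seconds).
#' @param weights Activity weight per time (default 1 per event; for floor
#'   activity, the per-bin distance).
#' @param cycle A [light_cycle()].
#' @param utc_offset_hours Local-time offset from UTC, hours.
#' @param min_activity Minimum total weight for the fraction to be
#'   reported. Default 10.
#' @return Fraction in `[0, 1]`, or a missing value with reason
#'   `"insufficient activity"`.
#' @export
circadian_dark_fraction <- function(times, weights = rep(1, length(times)),
                                    cycle = light_cycle(),
                                    utc_offset_hours = 0, min_activity = 10) {
  if (length(times) != length(weights)) {
    stop("times and weights must have equal length")
  }
  total <- sum(weights)
  if (length(times) == 0 || total <= min_activity) {
    return(missing_value("insufficient activity"))
  }
  dark <- is_dark_hour(local_hour(times, utc_offset_hours), cycle)
  sum(weights[dark]) / total
}
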