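#' Clean a centroid track into reliable segments
#'
#' Drops low-confidence detections, then splits the remaining samples into
#' contiguous segments wherever the time gap between adjacent frames
#' exceeds `max_gap_s` or the implied displacement exceeds `max_jump_cm`
#' (a physically impossible "teleport", usually a detector failure).
#'
#' @param ch A `track` [channel()].
#' @param conf_min Minimum detection confidence. Default 0.5.
#' @param max_jump_cm Maximum plausible between-frame displacement, cm.
#'   Default 20.
#' @param max_gap_s Maximum between-frame time gap, seconds. Default 2.
#' @param calib A [cage_calibration()].
#' @return List of data frames (`time`, `x_px`, `y_px`), possibly empty.
#' @export
clean_track <- function(ch, conf_min = 0.5, max_jump_cm = 20, max_gap_s = 2,
                        calib = cage_calibration()) {
  stopifnot(inherits(ch, "cage_channel"), ch$kind == "track",
            inherits(calib, "cage_calibration"))
  keep <- ch$samples$confidence >= conf_min
  tm <- ch$samples$time[keep]
  x <- ch$samples$x_px[keep]
  y <- ch$samples$y_px[keep]
  n <- length(x)
  if (n == 0) return(list())
  t <- as.numeric(tm)
  if (n == 1) return(list(fast_df(list(time = tm, x_px = x, y_px = y))))
  step_cm <- sqrt(diff(x)^2 + diff(y)^2) / calib$px_per_cm
  brk <- which(diff(t) > max_gap_s | step_cm > max_jump_cm)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    fast_df(list(time = tm[idx], x_px = x[idx], y_px = y[idx]))
  })
}

#' Per-bin floor distance
#'
#' Sums Euclidean step lengths within fixed time bins. A step between two
#' adjacent samples is assigned to the bin containing the earlier sample.
#'
#' @param segments List of track segments from [clean_track()].
#' @param bin_s Bin width, seconds. Default 3600.
#' @param calib A [cage_calibration()].
#' @param t0,t1 Bin range bounds (`POSIXct` or numeric UTC seconds);
#'   defaults to the span of the segments.
#' @return Data frame with `bin_start` (`POSIXct` UTC) and `distance_cm`,
#'   one row per bin covering `[t0, t1)`.
#' @export
distance_binned <- function(segments, bin_s = 3600,
                            calib = cage_calibration(),
                            t0 = NULL, t1 = NULL) {
  stopifnot(inherits(calib, "cage_calibration"))
  all_t <- unlist(lapply(segments, function(s) as.numeric(s$time)))
  if (is.null(t0)) t0 <- if (length(all_t)) min(all_t) else 0
  if (is.null(t1)) t1 <- if (length(all_t)) max(all_t) + bin_s else bin_s
  t0 <- as.numeric(t0); t1 <- as.numeric(t1)
  nbins <- max(1L, as.integer(ceiling((t1 - t0) / bin_s)))
  dist <- numeric(nbins)
  for (seg in segments) {
    if (nrow(seg) < 2) next
    t <- as.numeric(seg$time)
    step <- sqrt(diff(seg$x_px)^2 + diff(seg$y_px)^2) / calib$px_per_cm
    idx <- floor((t[-length(t)] - t0) / bin_s) + 1
    keep <- idx >= 1 & idx <= nbins
    if (any(keep)) {
      acc <- rowsum(step[keep], idx[keep])
      at <- as.integer(rownames(acc))
      dist[at] <- dist[at] + acc[, 1]
    }
  }
  data.frame(
    bin_start = as.POSIXct(t0 + (seq_len(nbins) - 1) * bin_s,
                           origin = "1970-01-01", tz = "UTC"),
    distance_cm = dist)
}

#' Floor gait speed
#'
#' Sliding-window mean speeds are computed within each track segment: for
#' every sample, the window covers samples up to `window_s` seconds later,
#' and its speed is the path distance divided by the elapsed time. Windows
#' whose speed does not exceed `move_threshold_cm_s` are treated as idle
#' and discarded; the configured percentile of the remaining window speeds
#' is returned as a peak-performance locomotion summary.
#'
#' @param segments List of track segments from [clean_track()].
#' @param window_s Window length, seconds. Default 1.
#' @param move_threshold_cm_s Idle threshold, cm/s. Default 0.5.
#' @param percentile Percentile in (0, 1]. Default 0.9.
#' @param calib A [cage_calibration()].
#' @return Speed in cm/s, or a missing value when no window qualifies.
#' @export
floor_gait_speed <- function(segments, window_s = 1,
                             move_threshold_cm_s = 0.5, percentile = 0.9,
                             calib = cage_calibration()) {
  stopifnot(inherits(calib, "cage_calibration"))
  speeds <- numeric(0)
  for (seg in segments) {
    n <- nrow(seg)
    if (n < 2) next
    t <- as.numeric(seg$time)
    cd <- c(0, cumsum(sqrt(diff(seg$x_px)^2 + diff(seg$y_px)^2))) /
      calib$px_per_cm
    # last sample index within window_s of each start (vectorised)
    j <- findInterval(t + window_s, t)
    i <- seq_len(n)
    ok <- j > i
    if (!any(ok)) next
    speeds <- c(speeds, (cd[j[ok]] - cd[i[ok]]) / (t[j[ok]] - t[i[ok]]))
  }
  speeds <- speeds[speeds > move_threshold_cm_s]
  if (length(speeds) == 0) {
    return(missing_value("no window above movement threshold"))
  }
  as.numeric(stats::quantile(speeds, percentile, names = FALSE, type = 7))
}

#' Floor circadian dark fraction
#'
#' Applies the dark-phase activity fraction to binned floor distances:
#' each bin's distance is the activity weight at the bin start time.
#'
#' @param bins Data frame from [distance_binned()].
#' @param cycle A [light_cycle()].
#' @param utc_offset_hours Local-time offset from UTC, hours.
#' @param min_distance_cm Minimum total distance for the fraction to be
#'   reported. Default 10.
#' @return Fraction in `[0, 1]`, or a missing value.
#' @export
floor_circadian <- function(bins, cycle = light_cycle(),
                            utc_offset_hours = 0, min_distance_cm = 10) {
  circadian_dark_fraction(bins$bin_start, bins$distance_cm, cycle,
                          utc_offset_hours, min_activity = min_distance_cm)
}
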