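#' Threshold-linear frailty parameterization
#'
#' Maps a raw measurement onto the `[0, 1]` frailty scale: the value
#' `v_healthy` maps to 0, `v_frail` maps to 1, intermediate values are
#' linearly interpolated by their relative proximity to the two anchors,
#' and values beyond either anchor are clamped. The ordering of the
#' anchors encodes the frailty direction (e.g. `v_frail < v_healthy`
#' scores low activity as frail).
#'
#' @param value Numeric measurement (vectorised); `NA` passes through.
#' @param v_healthy,v_frail Threshold anchors; must differ.
#' @return Score(s) in `[0, 1]` (or `NA` where `value` is `NA`).
#' @export
parameterize <- function(value, v_healthy, v_frail) {
  if (v_healthy == v_frail) {
    stop("config error: v_healthy and v_frail must differ")
  }
  pmin(pmax((value - v_healthy) / (v_frail - v_healthy), 0), 1)
}

#' Aggregate component scores into an overall DFI
#'
#' The overall DFI is the arithmetic mean of the 8 parameterized component
#' scores. Under the `"strict"` policy all 8 must be present; under
#' `"lenient"` the mean is taken over the present scores provided at least
#' `min_components` are available.
#'
#' @param scores Named numeric vector of component scores in `[0, 1]`
#'   (`NA` = missing).
#' @param policy `"strict"` or `"lenient"`.
#' @param min_components Minimum present scores under `"lenient"`.
#' @return List with `overall`, `n_used`, and `missing` (character vector
#'   of missing component names).
#' @export
aggregate_dfi <- function(scores, policy = c("strict", "lenient"),
                          min_components = 6) {
  policy <- match.arg(policy)
  present <- !is.na(scores)
  missing <- names(scores)[!present]
  if (policy == "strict" && length(missing) > 0) {
    stop("missing component(s) under strict policy: ",
         paste(missing, collapse = ", "))
  }
  if (sum(present) < if (policy == "strict") length(scores) else min_components) {
    stop("only ", sum(present), " component scores present; need ",
         if (policy == "strict") length(scores) else min_components)
  }
  list(overall = mean(scores[present]), n_used = sum(present),
       missing = missing)
}

#' Optimized DFI over a 5-component selection
#'
#' The mean of the parameterized scores for a named subset of 5
#' components (intended for the best-performing components of a study).
#'
#' @param scores Named numeric vector of component scores.
#' @param selected Character vector of exactly 5 component names.
#' @return Mean of the 5 selected scores.
#' @export
optimized_dfi <- function(scores, selected) {
  if (length(selected) != 5) {
    stop("optimized DFI requires exactly 5 selected components, got ",
         length(selected))
  }
  if (!all(selected %in% names(scores))) {
    stop("unknown component(s): ",
         paste(setdiff(selected, names(scores)), collapse = ", "))
  }
  sel <- scores[selected]
  if (any(is.na(sel))) {
    stop("selected component(s) missing: ",
         paste(selected[is.na(sel)], collapse = ", "))
  }
  mean(sel)
}

#' Combined frailty index
#'
#' The mean of a paired manual FI value and digital FI value.
#'
#' @param mfi_overall,dfi_overall Values in `[0, 1]` (vectorised).
#' @return `(mfi + dfi) / 2`.
#' @export
combined_fi <- function(mfi_overall, dfi_overall) {
  if (any(is.na(mfi_overall)) || any(mfi_overall < 0 | mfi_overall > 1)) {
    stop("mfi_overall must be in [0, 1]")
  }
  if (any(is.na(dfi_overall)) || any(dfi_overall < 0 | dfi_overall > 1)) {
    stop("dfi_overall must be in [0, 1]")
  }
  (mfi_overall + dfi_overall) / 2
}

# Compute the 8 raw measurements for one mouse-period from its channels.
measure_period <- function(channels, period, config, calib) {
  cyc <- config$cycle
  off <- config$utc_offset_hours
  raw <- list()

  # wheel (3 measurements)
  if (!is.null(channels$wheel_emission) &&
      nrow(channels$wheel_emission$samples) > 0) {
    wh <- clip_channel(channels$wheel_emission, period$start, period$end)
    if (nrow(wh$samples) > 0) {
      states <- viterbi_decode(wh$samples$p_top, p_stay = config$p_stay)
      events <- rotations_from_states(states, wh$samples$time)
      raw$wheel_distance <- wheel_distance_per_day(events, period, calib)
      raw$wheel_gait_speed <- wheel_gait_speed(
        events, calib, config$wheel_bout_gap_s, config$gait_percentile)
      raw$wheel_circadian <- circadian_dark_fraction(
        events, cycle = cyc, utc_offset_hours = off,
        min_activity = config$wheel_min_rotations)
    }
  }
  if (is.null(raw$wheel_distance)) {
    for (nm in c("wheel_distance", "wheel_gait_speed", "wheel_circadian")) {
      raw[[nm]] <- missing_value("no wheel emission frames in period")
    }
  }

  # floor (2 measurements)
  if (!is.null(channels$track) && nrow(channels$track$samples) > 0) {
    tr <- clip_channel(channels$track, period$start, period$end)
    segs <- clean_track(tr, config$track_conf_min, config$track_max_jump_cm,
                        config$track_max_gap_s, calib)
    raw$floor_gait_speed <- floor_gait_speed(
      segs, config$floor_window_s, config$floor_move_threshold_cm_s,
      config$gait_percentile, calib)
    bins <- distance_binned(segs, config$floor_bin_s, calib,
                            t0 = period$start, t1 = period$end)
    raw$floor_circadian <- floor_circadian(bins, cyc, off,
                                           config$floor_min_distance_cm)
  } else {
    raw$floor_gait_speed <- missing_value("no track samples in period")
    raw$floor_circadian <- missing_value("no track samples in period")
  }

  # body condition (2 measurements)
  if (!is.null(channels$weight) && nrow(channels$weight$samples) > 0) {
    raw$weight_slope <- weight_rate_of_change(channels$weight, period)
  } else {
    raw$weight_slope <- missing_value("no weight samples in period")
  }
  if (!is.null(channels$coat) && nrow(channels$coat$samples) > 0) {
    raw$coat_roughness <- coat_metric(channels$coat, period,
                                      config$coat_min_samples)
  } else {
    raw$coat_roughness <- missing_value("no coat samples in period")
  }

  # nest (1 measurement)
  if (!is.null(channels$nest) && nrow(channels$nest$samples) > 0) {
    raw$nest_movement <- nest_displacement(channels$nest, calib, period,
                                           config$nest_min_area_px,
                                           config$nest_max_gap_h)
  } else {
    raw$nest_movement <- missing_value("no nest samples in period")
  }
  raw
}

#' Score one mouse-period into a DFI result
#'
#' Runs all 8 measurements (3 wheel, 2 floor, 2 body-condition, 1 nest)
#' on the period's channels, parameterizes each measurement with the
#' configured threshold anchors, and aggregates the scores into an
#' overall DFI. The result is a pure function of the inputs: repeated
#' calls with the same channels and configuration are identical.
#'
#' @param channels Named list of [channel()] objects (`wheel_emission`,
#'   `track`, `weight`, `coat`, `nest`); absent entries yield missing
#'   components.
#' @param period One row of a [derive_periods()] table.
#' @param config A [dfi_config()].
#' @param calib A [cage_calibration()].
#' @return An object of class `dfi_result`: list with `mouse_id`,
#'   `first_full_day`, `n_full_days`, `components` (data frame of
#'   component, units, raw value, score, missing reason), `overall`,
#'   `n_used`, and `missing`. Under the strict policy any missing
#'   component is an error listing the affected components.
#' @export
score_period <- function(channels, period, config = dfi_config(),
                         calib = cage_calibration()) {
  stopifnot(inherits(config, "dfi_config"),
            inherits(calib, "cage_calibration"))
  raw <- measure_period(channels, period, config, calib)
  comp <- config$components
  scores <- stats::setNames(rep(NA_real_, nrow(comp)), comp$component)
  raw_v <- scores
  reasons <- stats::setNames(rep(NA_character_, nrow(comp)), comp$component)
  for (i in seq_len(nrow(comp))) {
    nm <- comp$component[i]
    v <- raw[[nm]]
    if (is.null(v)) v <- missing_value("measurement not computed")
    raw_v[nm] <- as.numeric(v)
    if (is.na(v)) {
      reasons[nm] <- missing_reason(v)
    } else {
      scores[nm] <- parameterize(as.numeric(v), comp$v_healthy[i],
                                 comp$v_frail[i])
    }
  }
  agg <- aggregate_dfi(scores, config$missing_policy, config$min_components)
  structure(list(
    mouse_id = period$mouse_id,
    first_full_day = period$first_full_day,
    n_full_days = period$n_full_days,
    components = data.frame(component = comp$component, units = comp$units,
                            raw = unname(raw_v), score = unname(scores),
                            missing_reason = unname(reasons),
                            stringsAsFactors = FALSE),
    overall = agg$overall, n_used = agg$n_used, missing = agg$missing
  ), class = "dfi_result")
}

#' @export
print.dfi_result <- function(x, ...) {
  cat("<dfi_result>", x$mouse_id, "-", format(x$first_full_day), "-",
      x$n_full_days, "full days\n")
  print(x$components, row.names = FALSE)
  cat("overall DFI:", format(x$overall, digits = 4),
      sprintf("(%d/%d components)\n", x$n_used, nrow(x$components)))
  invisible(x)
}

#' Flatten DFI results into a table
#'
#' @param results List of `dfi_result` objects.
#' @return Data frame with one row per result: `mouse_id`, `date`
#'   (first full day), `n_full_days`, one `raw_*` and one `score_*`
#'   column per component, and `dfi` (overall).
#' @export
dfi_table <- function(results) {
  rows <- lapply(results, function(r) {
    comp <- r$components
    row <- data.frame(mouse_id = r$mouse_id, date = r$first_full_day,
                      n_full_days = r$n_full_days,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(comp))) {
      row[[paste0("raw_", comp$component[i])]] <- comp$raw[i]
      row[[paste0("score_", comp$component[i])]] <- comp$score[i]
    }
    row$dfi <- r$overall
    row
  })
  do.call(rbind, rows)
}

#' Score every period of a multi-mouse dataset
#'
#' @param channel_sets Named list (by mouse id) of channel lists as
#'   accepted by [score_period()].
#' @param periods A [derive_periods()] table.
#' @param config A [dfi_config()].
#' @param calib A [cage_calibration()].
#' @return Data frame as [dfi_table()].
#' @export
score_dataset <- function(channel_sets, periods, config = dfi_config(),
                          calib = cage_calibration()) {
  results <- lapply(seq_len(nrow(periods)), function(i) {
    p <- periods[i, , drop = FALSE]
    chans <- channel_sets[[p$mouse_id]]
    if (is.null(chans)) stop("no channels for mouse '", p$mouse_id, "'")
    score_period(chans, p, config, calib)
  })
  dfi_table(results)
}
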