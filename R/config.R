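#' Light-cycle specification
#'
#' Describes the dark phase of the vivarium light cycle in local time.
#' The circadian components of the DFI partition activity into dark-phase
#' versus light-phase weight using this object.
#'
#' @param dark_onset_hour Local hour of day at which the dark phase begins,
#'   in `[0, 24)`. Default 18 (lights off at 6 pm).
#' @param dark_duration_h Length of the dark phase in hours, in `(0, 24)`.
#'   Default 12.
#' @return An object of class `light_cycle`.
#' @examples
#' light_cycle(18, 12)
#' @export
light_cycle <- function(dark_onset_hour = 18, dark_duration_h = 12) {
  if (!is.numeric(dark_onset_hour) || length(dark_onset_hour) != 1L ||
      is.na(dark_onset_hour) || dark_onset_hour < 0 || dark_onset_hour >= 24) {
    stop("dark_onset_hour must be a single value in [0, 24)")
  }
  if (!is.numeric(dark_duration_h) || length(dark_duration_h) != 1L ||
      is.na(dark_duration_h) || dark_duration_h <= 0 || dark_duration_h >= 24) {
    stop("dark_duration_h must be a single value in (0, 24)")
  }
  structure(list(dark_onset_hour = as.numeric(dark_onset_hour),
                 dark_duration_h = as.numeric(dark_duration_h)),
            class = "light_cycle")
}

#' Is a local hour-of-day inside the dark phase?
#'
#' @param hour_local Numeric vector of local hours of day in `[0, 24)`.
#' @param cycle A [light_cycle()].
#' @return Logical vector.
#' @export
is_dark_hour <- function(hour_local, cycle) {
  stopifnot(inherits(cycle, "light_cycle"))
  rel <- (hour_local - cycle$dark_onset_hour) %% 24
  rel < cycle$dark_duration_h
}

#' Cage calibration constants
#'
#' Conversion constants between image coordinates and physical units.
#' Image convention: origin top-left, x rightward, y downward.
#'
#' @param px_per_cm Pixels per centimetre on the cage floor. Default 15.
#' @param wheel_circumference_m Metres of running distance per wheel
#'   rotation. Default 0.4 (a ~12.7 cm diameter mouse wheel).
#' @return An object of class `cage_calibration`.
#' @export
cage_calibration <- function(px_per_cm = 15, wheel_circumference_m = 0.4) {
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1L ||
      is.na(px_per_cm) || px_per_cm <= 0) {
    stop("px_per_cm must be a single positive number")
  }
  if (!is.numeric(wheel_circumference_m) || length(wheel_circumference_m) != 1L ||
      is.na(wheel_circumference_m) || wheel_circumference_m <= 0) {
    stop("wheel_circumference_m must be a single positive number")
  }
  structure(list(px_per_cm = as.numeric(px_per_cm),
                 wheel_circumference_m = as.numeric(wheel_circumference_m)),
            class = "cage_calibration")
}

#' Default frailty-threshold table for the eight DFI components
#'
#' Per-component `(v_healthy, v_frail)` anchors for the threshold-linear
#' parameterization. Direction is encoded by ordering: `v_frail <
#' v_healthy` scores low values (activity, speed, rhythm, nest movement,
#' weight gain) as frail, the reverse ordering scores high values (coat
#' roughness) as frail. These defaults are calibrated against the
#' synthetic-cage simulator's healthy and frail phenotype anchors (see
#' the methods vignette); real deployments should re-derive them from
#' age-stratified training data.
#'
#' @return Data frame with columns `component`, `units`, `v_healthy`,
#'   `v_frail`.
#' @export
default_component_table <- function() {
  data.frame(
    component = c("wheel_distance", "wheel_gait_speed", "wheel_circadian",
                  "floor_gait_speed", "floor_circadian", "weight_slope",
                  "coat_roughness", "nest_movement"),
    units     = c("m/day", "m/s", "fraction", "cm/s", "fraction",
                  "g/day", "a.u.", "cm/h"),
    v_healthy = c(1000, 0.120, 0.85, 7.0, 0.75,  0.00, 13, 1.5),
    v_frail   = c(  80, 0.065, 0.60, 2.5, 0.55, -0.25, 19, 0.3),
    stringsAsFactors = FALSE
  )
}

#' DFI scoring configuration
#'
#' Bundles every tunable parameter of the scoring pipeline: per-component
#' frailty thresholds, the light cycle, HMM decoding parameters, bout and
#' window settings, and the missing-component policy.
#'
#' @param components Data frame with columns `component`, `units`,
#'   `v_healthy`, `v_frail`: the threshold-linear anchors for each of the 8
#'   components. `v_healthy` maps to score 0, `v_frail` to score 1, and the
#'   ordering of the two encodes the frailty direction.
#' @param cycle A [light_cycle()].
#' @param utc_offset_hours Offset added to UTC to obtain local time, hours.
#' @param p_stay HMM self-transition probability for wheel-marker decoding,
#'   in `(0, 1)`. Default 0.98.
#' @param wheel_bout_gap_s Maximum inter-rotation gap (seconds) within a
#'   wheel-running bout. Default 8.
#' @param gait_percentile Percentile (0-1) summarising per-rotation and
#'   per-window speeds. Default 0.9.
#' @param wheel_min_rotations Minimum rotations for the wheel circadian
#'   fraction to be reported. Default 10.
#' @param track_conf_min Minimum track-sample confidence. Default 0.5.
#' @param track_max_jump_cm Maximum plausible between-frame displacement
#'   (cm); larger jumps split track segments. Default 20.
#' @param track_max_gap_s Maximum between-frame time gap (seconds) within a
#'   track segment. Default 2.
#' @param floor_window_s Sliding-window length (seconds) for floor gait
#'   speed. Default 1.
#' @param floor_move_threshold_cm_s Window mean speed below which a window
#'   is considered idle. Default 0.5.
#' @param floor_bin_s Bin width (seconds) for binned floor distance.
#'   Default 3600.
#' @param floor_min_distance_cm Minimum total floor distance for the floor
#'   circadian fraction. Default 10.
#' @param coat_min_samples Minimum coat samples per period. Default 100.
#' @param nest_min_area_px Minimum nest mask area for a sample to qualify.
#'   Default 100.
#' @param nest_max_gap_h Maximum gap (hours) between consecutive nest
#'   samples used for displacement. Default 2.
#' @param missing_policy `"strict"` (all 8 components required) or
#'   `"lenient"` (average over at least `min_components` present scores).
#' @param min_components Minimum present components under the lenient
#'   policy. Default 6.
#' @param optimized_components Character vector of 5 component names used
#'   by [optimized_dfi()]. Defaults to the gait/wheel and circadian
#'   components.
#' @return An object of class `dfi_config`.
#' @export
dfi_config <- function(components = default_component_table(),
                       cycle = light_cycle(),
                       utc_offset_hours = 0,
                       p_stay = 0.98,
                       wheel_bout_gap_s = 8,
                       gait_percentile = 0.9,
                       wheel_min_rotations = 10,
                       track_conf_min = 0.5,
                       track_max_jump_cm = 20,
                       track_max_gap_s = 2,
                       floor_window_s = 1,
                       floor_move_threshold_cm_s = 0.5,
                       floor_bin_s = 3600,
                       floor_min_distance_cm = 10,
                       coat_min_samples = 100,
                       nest_min_area_px = 100,
                       nest_max_gap_h = 2,
                       missing_policy = c("strict", "lenient"),
                       min_components = 6,
                       optimized_components = c("wheel_distance",
                                                "wheel_gait_speed",
                                                "floor_gait_speed",
                                                "wheel_circadian",
                                                "floor_circadian")) {
  missing_policy <- match.arg(missing_policy)
  req <- c("component", "units", "v_healthy", "v_frail")
  if (!is.data.frame(components) || !all(req %in% names(components))) {
    stop("components must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(components$component)) {
    stop("duplicate component names in threshold table")
  }
  if (any(components$v_healthy == components$v_frail)) {
    bad <- components$component[components$v_healthy == components$v_frail]
    stop("v_healthy must differ from v_frail for component(s): ",
         paste(bad, collapse = ", "))
  }
  if (p_stay <= 0 || p_stay >= 1) stop("p_stay must be in (0, 1)")
  cfg <- list(components = components, cycle = cycle,
              utc_offset_hours = utc_offset_hours,
              p_stay = p_stay,
              wheel_bout_gap_s = wheel_bout_gap_s,
              gait_percentile = gait_percentile,
              wheel_min_rotations = wheel_min_rotations,
              track_conf_min = track_conf_min,
              track_max_jump_cm = track_max_jump_cm,
              track_max_gap_s = track_max_gap_s,
              floor_window_s = floor_window_s,
              floor_move_threshold_cm_s = floor_move_threshold_cm_s,
              floor_bin_s = floor_bin_s,
              floor_min_distance_cm = floor_min_distance_cm,
              coat_min_samples = coat_min_samples,
              nest_min_area_px = nest_min_area_px,
              nest_max_gap_h = nest_max_gap_h,
              missing_policy = missing_policy,
              min_components = min_components,
              optimized_components = optimized_components)
  structure(cfg, class = "dfi_config")
}

#' Read or write a DFI configuration as YAML
#'
#' The YAML layout mirrors the [dfi_config()] argument list; the component
#' threshold table is stored as a list of per-component records, and the
#' cage calibration is stored alongside under a `calibration` key.
#'
#' @param path File path.
#' @param config A [dfi_config()].
#' @param calib Optional [cage_calibration()] stored with the config.
#' @return `read_dfi_config()` returns a list with elements `config` and
#'   `calib`; `write_dfi_config()` returns `path` invisibly.
#' @export
write_dfi_config <- function(config, path, calib = cage_calibration()) {
  stopifnot(inherits(config, "dfi_config"))
  x <- unclass(config)
  x$cycle <- unclass(x$cycle)
  comp <- x$components
  x$components <- lapply(seq_len(nrow(comp)), function(i) as.list(comp[i, ]))
  x$calibration <- unclass(calib)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_dfi_config
#' @export
read_dfi_config <- function(path) {
  x <- yaml::read_yaml(path)
  comp <- do.call(rbind, lapply(x$components, function(r) {
    data.frame(component = r$component, units = r$units,
               v_healthy = as.numeric(r$v_healthy),
               v_frail = as.numeric(r$v_frail),
               stringsAsFactors = FALSE)
  }))
  calib <- do.call(cage_calibration, x$calibration)
  args <- x[setdiff(names(x), c("components", "cycle", "calibration"))]
  args$components <- comp
  args$cycle <- do.call(light_cycle, x$cycle)
  list(config = do.call(dfi_config, args), calib = calib)
}

# local hour-of-day for POSIXct/numeric UTC times under a fixed offset
local_hour <- function(time, utc_offset_hours) {
  (as.numeric(time) / 3600 + utc_offset_hours) %% 24
}
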