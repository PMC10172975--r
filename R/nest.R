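#' Nest-material displacement rate
#'
#' Quantifies how much the nesting material is moved around the cage: the
#' mean, over consecutive qualifying sample pairs, of the nest-centroid
#' displacement (cm) divided by the elapsed time (hours). Samples whose
#' mask area is at or below `min_area_px` are discarded (unreliable
#' segmentations), and pairs spanning gaps longer than `max_gap_h` hours
#' are excluded.
#'
#' @param ch A `nest` [channel()].
#' @param calib A [cage_calibration()].
#' @param period One row of a [derive_periods()] table; when supplied the
#'   channel is clipped to it first.
#' @param min_area_px Minimum nest mask area, pixels. Default 100.
#' @param max_gap_h Maximum pair gap, hours. Default 2.
#' @return Mean centroid speed in cm/h (>= 0), or a missing value when
#'   fewer than two qualifying samples (or no qualifying pair) exist.
#' @export
nest_displacement <- function(ch, calib = cage_calibration(), period = NULL,
                              min_area_px = 100, max_gap_h = 2) {
  stopifnot(inherits(ch, "cage_channel"), ch$kind == "nest",
            inherits(calib, "cage_calibration"))
  if (!is.null(period)) ch <- clip_channel(ch, period$start, period$end)
  s <- ch$samples[ch$samples$area_px > min_area_px, , drop = FALSE]
  if (nrow(s) < 2) return(missing_value("fewer than 2 qualifying nest samples"))
  t <- as.numeric(s$time)
  dt_h <- diff(t) / 3600
  keep <- dt_h <= max_gap_h & dt_h > 0
  if (!any(keep)) return(missing_value("no qualifying nest sample pairs"))
  disp_cm <- sqrt(diff(s$centroid_x_px)^2 + diff(s$centroid_y_px)^2) /
    calib$px_per_cm
  mean(disp_cm[keep] / dt_h[keep])
}
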