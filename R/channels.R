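# data.frame construction without row-name bookkeeping (hot path: channels
# carry 10^5-10^6 rows and [.data.frame's row-name handling dominates)
fast_df <- function(cols) {
  n <- length(cols[[1]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

subset_df <- function(df, keep) {
  fast_df(lapply(df, function(col) col[keep]))
}

# Payload column specification per channel kind.  Each entry gives the
# payload columns (beyond `time`) and their validity ranges.
channel_payload_spec <- function(kind) {
  switch(kind,
    wheel_emission = list(cols = "p_top",
                          lo = c(p_top = 0), hi = c(p_top = 1)),
    track = list(cols = c("x_px", "y_px", "confidence"),
                 lo = c(x_px = -Inf, y_px = -Inf, confidence = 0),
                 hi = c(x_px = Inf, y_px = Inf, confidence = 1)),
    weight = list(cols = c("grams", "weight_w"),
                  lo = c(grams = 1e-12, weight_w = 0),
                  hi = c(grams = Inf, weight_w = Inf)),
    coat = list(cols = "roughness",
                lo = c(roughness = 0), hi = c(roughness = Inf)),
    nest = list(cols = c("centroid_x_px", "centroid_y_px", "area_px"),
                lo = c(centroid_x_px = -Inf, centroid_y_px = -Inf,
                       area_px = 0),
                hi = c(centroid_x_px = Inf, centroid_y_px = Inf,
                       area_px = Inf)),
    stop("unknown channel kind: ", kind)
  )
}

#' Channel kinds understood by the pipeline
#' @return Character vector of the five kinds.
#' @export
channel_kinds <- function() {
  c("wheel_emission", "track", "weight", "coat", "nest")
}

#' Construct an annotation channel
#'
#' An annotation channel is a time-stamped sample stream for one
#' sensor-derived quantity of one cage: per-frame wheel-marker top
#' probabilities, centroid tracks, per-minute body-weight estimates with
#' confidence weights, coat-roughness samples, or nest-material
#' centroid/area samples.
#'
#' @param kind One of [channel_kinds()].
#' @param samples Data frame with a `time` column (`POSIXct`, UTC, or
#'   numeric UTC seconds) strictly increasing, plus the payload columns for
#'   the kind: `p_top` (wheel_emission), `x_px`/`y_px`/`confidence`
#'   (track), `grams`/`weight_w` (weight), `roughness` (coat),
#'   `centroid_x_px`/`centroid_y_px`/`area_px` (nest).
#' @return An object of class `cage_channel`: a list with elements `kind`
#'   and `samples`.
#' @export
channel <- function(kind, samples) {
  kind <- match.arg(kind, channel_kinds())
  spec <- channel_payload_spec(kind)
  if (!is.data.frame(samples)) stop("samples must be a data frame")
  need <- c("time", spec$cols)
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("channel '", kind, "' samples missing column(s): ",
         paste(miss, collapse = ", "))
  }
  samples <- samples[, need, drop = FALSE]
  if (is.numeric(samples$time)) {
    samples$time <- as.POSIXct(samples$time, origin = "1970-01-01", tz = "UTC")
  }
  if (!inherits(samples$time, "POSIXct")) {
    stop("time column must be POSIXct or numeric UTC seconds")
  }
  n <- nrow(samples)
  if (n > 0) {
    t <- as.numeric(samples$time)
    if (anyNA(t)) stop("row ", which(is.na(t))[1], ": missing timestamp")
    if (n > 1 && any(diff(t) <= 0)) {
      stop("row ", which(diff(t) <= 0)[1] + 1L,
           ": timestamps must be strictly increasing")
    }
    for (col in spec$cols) {
      v <- samples[[col]]
      if (!is.numeric(v)) stop("column ", col, " must be numeric")
      bad <- which(is.na(v) | v < spec$lo[[col]] | v > spec$hi[[col]])
      if (length(bad) > 0) {
        stop("row ", bad[1], ": ", col, " = ", v[bad[1]],
             " out of range for kind '", kind, "'")
      }
    }
  }
  structure(list(kind = kind, samples = samples), class = "cage_channel")
}

#' @export
print.cage_channel <- function(x, ...) {
  n <- nrow(x$samples)
  cat("<cage_channel> kind:", x$kind, "-", n, "samples")
  if (n > 0) {
    cat(" [", format(x$samples$time[1], tz = "UTC"), "..",
        format(x$samples$time[n], tz = "UTC"), "UTC ]")
  }
  cat("\n")
  invisible(x)
}

fmt_time_iso <- function(t) {
  format(t, format = "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
}

parse_time_iso <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) {
    # fall back to space-separated or date-only forms
    t2 <- as.POSIXct(s, tz = "UTC")
    t[is.na(t)] <- t2[is.na(t)]
  }
  t
}

#' Read or write an annotation-channel CSV
#'
#' Files are UTF-8 comma-delimited with a header naming the `time` column
#' (ISO-8601, UTC) and the payload columns of the kind. Writing then
#' reading a channel reproduces its samples to microsecond printing
#' precision.
#'
#' @param path CSV file path.
#' @param kind One of [channel_kinds()].
#' @param ch A `cage_channel`.
#' @return `read_channel_table()` returns a `cage_channel`;
#'   `write_channel_table()` returns `path` invisibly.
#' @export
read_channel_table <- function(path, kind) {
  kind <- match.arg(kind, channel_kinds())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("channel file lacks a 'time' column")
  if (nrow(df) > 0) {
    tt <- parse_time_iso(as.character(df$time))
    if (anyNA(tt)) {
      stop("row ", which(is.na(tt))[1], ": unparseable timestamp")
    }
    df$time <- tt
  } else {
    df$time <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  }
  channel(kind, df)
}

#' @rdname read_channel_table
#' @export
write_channel_table <- function(ch, path) {
  stopifnot(inherits(ch, "cage_channel"))
  out <- ch$samples
  out$time <- fmt_time_iso(out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a channel to a time window
#'
#' @param ch A `cage_channel`.
#' @param start,end Window bounds (`POSIXct` or numeric UTC seconds);
#'   samples with `start <= time < end` are kept.
#' @return A `cage_channel` of the same kind.
#' @export
clip_channel <- function(ch, start, end) {
  stopifnot(inherits(ch, "cage_channel"))
  t <- as.numeric(ch$samples$time)
  keep <- t >= as.numeric(start) & t < as.numeric(end)
  # subsetting an already-validated channel preserves its invariants
  structure(list(kind = ch$kind, samples = subset_df(ch$samples, keep)),
            class = "cage_channel")
}
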