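#' Read a cage-occupancy table
#'
#' Occupancy records say which mouse occupied which cage position over
#' which time interval. Column names vary between facilities, so a
#' `column_map` can rename arbitrary headers onto the canonical
#' `mouse_id`, `cage_position`, `device_id` (optional), `start`, `end`.
#'
#' @param path CSV path with ISO-8601 UTC `start`/`end` columns.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(mouse_id = "animal", start = "t0")`.
#' @return Data frame with columns `mouse_id`, `cage_position`,
#'   `device_id`, `start`, `end` (`POSIXct` UTC), validated by
#'   [validate_occupancy()].
#' @export
read_occupancy_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("occupancy file lacks column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  need <- c("mouse_id", "cage_position", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("occupancy table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"device_id" %in% names(df)) df$device_id <- df$cage_position
  df$start <- parse_time_iso(as.character(df$start))
  df$end <- parse_time_iso(as.character(df$end))
  df <- df[, c("device_id", "cage_position", "mouse_id", "start", "end")]
  validate_occupancy(df)
  df
}

#' Validate occupancy records
#'
#' Checks `start < end` for every record and that intervals for one cage
#' position do not overlap.
#'
#' @param occupancy Occupancy data frame (see [read_occupancy_table()]).
#' @return The input, invisibly; errors on violation.
#' @export
validate_occupancy <- function(occupancy) {
  s <- as.numeric(occupancy$start)
  e <- as.numeric(occupancy$end)
  if (anyNA(s) || anyNA(e)) stop("occupancy records contain missing timestamps")
  if (any(s >= e)) {
    stop("occupancy record ", which(s >= e)[1], ": start must precede end")
  }
  for (cp in unique(occupancy$cage_position)) {
    i <- which(occupancy$cage_position == cp)
    o <- i[order(s[i])]
    if (length(o) > 1 && any(s[o][-1] < e[o][-length(o)])) {
      stop("overlapping occupancy intervals for cage_position '", cp, "'")
    }
  }
  invisible(occupancy)
}

# Merge per mouse+cage episodes separated by gaps shorter than bridge_gap_s
# (transient camera dropouts); longer gaps split episodes.
merge_episodes <- function(occupancy, bridge_gap_s = 60) {
  key <- paste(occupancy$mouse_id, occupancy$cage_position, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- occupancy[key == k, , drop = FALSE]
    rows <- rows[order(as.numeric(rows$start)), , drop = FALSE]
    s <- as.numeric(rows$start); e <- as.numeric(rows$end)
    cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] - ce < bridge_gap_s) {
        ce <- max(ce, e[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(
          mouse_id = rows$mouse_id[1], cage_position = rows$cage_position[1],
          start = cs, end = ce, stringsAsFactors = FALSE)
        cs <- s[i]; ce <- e[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      mouse_id = rows$mouse_id[1], cage_position = rows$cage_position[1],
      start = cs, end = ce, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Derive DFI measurement periods from occupancy records
#'
#' A measurement period is a contiguous run of full local calendar days
#' (midnight to midnight in the configured local zone) during which one
#' mouse was continuously recorded. Incomplete days at the beginning and
#' end of an occupancy episode are excluded.
#'
#' Two modes are supported. In `"jdo"` mode each occupancy episode yields
#' at most one period: the first `min(full_days, max_days)` full days,
#' dropped entirely if fewer than `min_days` full days are available; the
#' measurement date is the first full day. In `"consecutive"` mode up to
#' `max_periods` back-to-back periods of exactly `max_days` days are cut
#' from the start of the episode: the first begins on the first full day,
#' and each subsequent period begins where the previous one ended.
#'
#' @param occupancy Occupancy data frame (see [read_occupancy_table()]).
#' @param mode `"jdo"` or `"consecutive"`.
#' @param max_days Maximum days per period (default 6).
#' @param min_days Minimum full days for a `"jdo"` period (default 2).
#' @param max_periods Maximum consecutive periods (default 3).
#' @param utc_offset_hours Local-time offset from UTC, hours.
#' @param bridge_gap_s Occupancy gaps shorter than this (seconds) are
#'   bridged before deriving periods. Default 60.
#' @return Data frame with one row per period: `mouse_id`,
#'   `cage_position`, `first_full_day` (`Date`, local), `n_full_days`,
#'   `start`, `end` (`POSIXct` UTC midnight bounds in local time);
#'   `end - start == n_full_days * 86400` seconds.
#' @export
derive_periods <- function(occupancy, mode = c("jdo", "consecutive"),
                           max_days = 6, min_days = 2, max_periods = 3,
                           utc_offset_hours = 0, bridge_gap_s = 60) {
  mode <- match.arg(mode)
  validate_occupancy(occupancy)
  eps <- merge_episodes(occupancy, bridge_gap_s)
  off <- utc_offset_hours * 3600
  res <- list()
  for (i in seq_len(nrow(eps))) {
    s <- eps$start[i]; e <- eps$end[i]
    # first local midnight at/after s; last local midnight at/before e
    day0 <- ceiling((s + off) / 86400) * 86400 - off
    day1 <- floor((e + off) / 86400) * 86400 - off
    nfull <- floor((day1 - day0) / 86400)
    if (nfull < 1) next
    if (mode == "jdo") {
      n <- min(nfull, max_days)
      if (n < min_days) next
      res[[length(res) + 1L]] <- data.frame(
        mouse_id = eps$mouse_id[i], cage_position = eps$cage_position[i],
        first_full_day = as.Date(as.POSIXct(day0 + off, origin = "1970-01-01",
                                            tz = "UTC")),
        n_full_days = n, start = day0, end = day0 + n * 86400,
        stringsAsFactors = FALSE)
    } else {
      k <- min(max_periods, nfull %/% max_days)
      if (k < 1) next
      for (j in seq_len(k)) {
        p0 <- day0 + (j - 1) * max_days * 86400
        res[[length(res) + 1L]] <- data.frame(
          mouse_id = eps$mouse_id[i], cage_position = eps$cage_position[i],
          first_full_day = as.Date(as.POSIXct(p0 + off, origin = "1970-01-01",
                                              tz = "UTC")),
          n_full_days = max_days, start = p0, end = p0 + max_days * 86400,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(mouse_id = character(0), cage_position = character(0),
                      first_full_day = as.Date(character(0)),
                      n_full_days = integer(0),
                      start = as.POSIXct(numeric(0), origin = "1970-01-01",
                                         tz = "UTC"),
                      end = as.POSIXct(numeric(0), origin = "1970-01-01",
                                       tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$start <- as.POSIXct(out$start, origin = "1970-01-01", tz = "UTC")
  out$end <- as.POSIXct(out$end, origin = "1970-01-01", tz = "UTC")
  out
}

#' Chronological age in days
#'
#' Age is the calendar-day difference between the cohort's date of birth
#' and the event date (an MFI assay date or the first full day of a DFI
#' period).
#'
#' @param cohort_dob Date of birth (`Date` or parseable string).
#' @param event_date Event date (`Date` or parseable string).
#' @return Non-negative integer day count (vectorised).
#' @export
compute_age <- function(cohort_dob, event_date) {
  dob <- as.Date(cohort_dob)
  ev <- as.Date(event_date)
  d <- as.integer(ev - dob)
  if (any(is.na(d))) stop("unparseable date in age computation")
  if (any(d < 0)) stop("event date precedes date of birth")
  d
}
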