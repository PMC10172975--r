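#' Ground-truth mouse phenotype for simulation
#'
#' Describes the behavioural/physiological state the synthetic cage
#' emulates. Rates are expectations; the simulator draws stochastic
#' realisations around them.
#'
#' @param wheel_rate_dark,wheel_rate_light Expected wheel rotations per
#'   hour in the dark and light phases.
#' @param wheel_rev_s Mean seconds per wheel rotation within a running
#'   bout (sets wheel gait speed).
#' @param floor_speed_cm_s Mean locomotion speed during floor movement
#'   bouts, cm/s.
#' @param activity_bout_rate Expected floor movement bouts per hour in
#'   the dark phase.
#' @param floor_light_ratio Light:dark ratio of floor bout rates (0-1;
#'   1 = arrhythmic).
#' @param weight0_g Body weight at period start, grams.
#' @param weight_slope_g_day True body-weight rate of change, g/day.
#' @param coat_roughness_mean Mean per-frame coat roughness (a.u.).
#' @param nest_speed_cm_h Expected nest-centroid displacement rate, cm/h.
#' @param frailty_latent Latent frailty in `[0, 1]` (bookkeeping only).
#' @param sex `"F"` or `"M"`.
#' @param age_days Chronological age, days.
#' @return An object of class `mouse_phenotype`.
#' @export
mouse_phenotype <- function(wheel_rate_dark = 250, wheel_rate_light = 25,
                            wheel_rev_s = 3, floor_speed_cm_s = 8,
                            activity_bout_rate = 20, floor_light_ratio = 0.25,
                            weight0_g = 30, weight_slope_g_day = 0,
                            coat_roughness_mean = 12, nest_speed_cm_h = 2,
                            frailty_latent = 0, sex = "F", age_days = 400) {
  stopifnot(wheel_rate_dark >= 0, wheel_rate_light >= 0, wheel_rev_s > 0,
            floor_speed_cm_s >= 0, activity_bout_rate >= 0, weight0_g > 0,
            coat_roughness_mean >= 0, nest_speed_cm_h >= 0)
  structure(as.list(environment()), class = "mouse_phenotype")
}

# Healthy and frail phenotype anchors used by phenotype_for_frailty().
phenotype_anchors <- function() {
  list(healthy = c(wheel_rate_dark = 250, wheel_rate_light = 25,
                   wheel_rev_s = 3.0, floor_speed_cm_s = 8,
                   activity_bout_rate = 20, floor_light_ratio = 0.25,
                   weight_slope_g_day = 0, coat_roughness_mean = 12,
                   nest_speed_cm_h = 2),
       frail = c(wheel_rate_dark = 25, wheel_rate_light = 8,
                 wheel_rev_s = 6.0, floor_speed_cm_s = 3,
                 activity_bout_rate = 8, floor_light_ratio = 0.54,
                 weight_slope_g_day = -0.3, coat_roughness_mean = 20,
                 nest_speed_cm_h = 0.2))
}

#' Phenotype for a given latent frailty
#'
#' Linearly interpolates every behavioural parameter between a healthy
#' anchor (`frailty = 0`) and a frail anchor (`frailty = 1`).
#'
#' @param frailty Latent frailty in `[0, 1]`.
#' @param age_days Chronological age, days.
#' @param sex `"F"` or `"M"`.
#' @param weight0_g Baseline body weight, grams.
#' @return A [mouse_phenotype()].
#' @export
phenotype_for_frailty <- function(frailty, age_days = 400, sex = "F",
                                  weight0_g = 30) {
  stopifnot(frailty >= 0, frailty <= 1)
  a <- phenotype_anchors()
  p <- a$healthy * (1 - frailty) + a$frail * frailty
  mouse_phenotype(
    wheel_rate_dark = p[["wheel_rate_dark"]],
    wheel_rate_light = p[["wheel_rate_light"]],
    wheel_rev_s = p[["wheel_rev_s"]],
    floor_speed_cm_s = p[["floor_speed_cm_s"]],
    activity_bout_rate = p[["activity_bout_rate"]],
    floor_light_ratio = p[["floor_light_ratio"]],
    weight0_g = weight0_g,
    weight_slope_g_day = p[["weight_slope_g_day"]],
    coat_roughness_mean = p[["coat_roughness_mean"]],
    nest_speed_cm_h = p[["nest_speed_cm_h"]],
    frailty_latent = frailty, sex = sex, age_days = age_days)
}

#' Observation noise model for the synthetic cage
#'
#' @param emission_flip_prob Probability that a frame's wheel-marker
#'   emission is inverted (classifier error), in `[0, 0.5)`.
#' @param emission_strength Classifier confidence for a correct frame:
#'   `p_top = emission_strength` for a true top frame. Default 0.9.
#' @param track_jitter_px Standard deviation of per-frame centroid jitter
#'   during movement, pixels.
#' @param rest_twitch_prob Probability that a resting frame's detection
#'   twitches off the rest position.
#' @param weight_cv Coefficient of variation of per-frame weight
#'   estimates.
#' @param conf_drop_prob Probability that a track frame gets a
#'   low-confidence (discardable) detection.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(emission_flip_prob = 0.02, emission_strength = 0.93,
                        track_jitter_px = 0.6, rest_twitch_prob = 0.03,
                        weight_cv = 0.03, conf_drop_prob = 0.02) {
  stopifnot(emission_flip_prob >= 0, emission_flip_prob < 0.5,
            emission_strength > 0.5, emission_strength < 1,
            track_jitter_px >= 0, weight_cv >= 0)
  structure(as.list(environment()), class = "noise_model")
}

# reflect values into [lo, hi]
fold_reflect <- function(v, lo, hi) {
  rng <- 2 * (hi - lo)
  v <- (v - lo) %% rng
  v <- ifelse(v > hi - lo, rng - v, v)
  v + lo
}

# Simulate wheel rotation intervals (start u, duration d) over [t0, t1]:
# bout starts from a piecewise-constant Poisson process (dark vs light
# rates), geometric rotations per bout, jittered per-rotation durations.
simulate_rotations <- function(phen, t0, t1, cycle, utc_offset_hours,
                               frame_rate, bout_mean = 20) {
  # enforce >= 8 frames per rotation so the marker phase is observable
  rev_s <- max(phen$wheel_rev_s, 8 / frame_rate)
  hour_starts <- seq(t0, t1 - 3600, by = 3600)
  dark <- is_dark_hour(local_hour(hour_starts + 1800, utc_offset_hours), cycle)
  rate <- ifelse(dark, phen$wheel_rate_dark, phen$wheel_rate_light)
  nb <- stats::rpois(length(hour_starts), rate / bout_mean)
  if (sum(nb) == 0) return(list(u = numeric(0), d = numeric(0)))
  starts <- sort(rep(hour_starts, nb) + stats::runif(sum(nb)) * 3600)
  u_all <- vector("list", length(starts))
  d_all <- vector("list", length(starts))
  cur_end <- t0
  for (b in seq_along(starts)) {
    s <- max(starts[b], cur_end + 3)
    n <- 1L + stats::rgeom(1, 1 / bout_mean)
    d <- rev_s * stats::runif(n, 1, 1.3)
    ends <- s + cumsum(d)
    keep <- ends <= t1 - 1
    if (!any(keep)) next
    n <- sum(keep)
    u_all[[b]] <- s + c(0, cumsum(d))[seq_len(n)]
    d_all[[b]] <- d[seq_len(n)]
    cur_end <- ends[n]
  }
  list(u = unlist(u_all), d = unlist(d_all))
}

# Per-frame wheel emissions from rotation intervals.  The single marker
# stripe is in the bottom position except during the second half of each
# rotation, so each rotation produces exactly one bottom-to-top
# transition.
emissions_from_rotations <- function(rot, ft, noise) {
  top <- rep(FALSE, length(ft))
  if (length(rot$u) > 0) {
    ts <- rot$u + rot$d / 2
    te <- rot$u + rot$d
    idx <- findInterval(ft, ts)
    top <- idx > 0 & ft < te[pmax(idx, 1)]
  }
  q <- noise$emission_strength
  p <- rep(1 - q, length(ft))
  p[top] <- q
  flip <- stats::runif(length(ft)) < noise$emission_flip_prob
  p[flip] <- 1 - p[flip]
  list(p_top = p, true_top = top)
}

# Per-frame floor track: alternating rest and movement bouts with
# reflective cage bounds, detection jitter and confidence noise.
simulate_track <- function(phen, noise, t0, t1, ft, cycle, utc_offset_hours,
                           calib, cage_w_cm = 35, cage_h_cm = 20) {
  nf <- length(ft)
  px <- calib$px_per_cm
  W <- cage_w_cm * px; H <- cage_h_cm * px; margin <- 10
  hour_starts <- seq(t0, t1 - 3600, by = 3600)
  dark <- is_dark_hour(local_hour(hour_starts + 1800, utc_offset_hours), cycle)
  rate <- ifelse(dark, phen$activity_bout_rate,
                 phen$activity_bout_rate * phen$floor_light_ratio)
  nb <- stats::rpois(length(hour_starts), rate)
  starts <- sort(rep(hour_starts, nb) + stats::runif(sum(nb)) * 3600)
  frame_rate <- if (nf > 1) 1 / (ft[2] - ft[1]) else 1

  x <- numeric(nf); y <- numeric(nf)
  move <- logical(nf)
  rest <- c(stats::runif(1, margin, W - margin),
            stats::runif(1, margin, H - margin))
  last_idx <- 0L
  n_bouts <- 0L
  cur_end <- t0
  for (b in seq_along(starts)) {
    s <- max(starts[b], cur_end + 2)
    dur <- stats::runif(1, 5, 15)
    if (s + dur > t1) break
    i0 <- as.integer(ceiling((s - t0) * frame_rate)) + 1L
    i1 <- as.integer(floor((s + dur - t0) * frame_rate)) + 1L
    i1 <- min(i1, nf)
    if (i1 - i0 < 1L || i0 <= last_idx) { cur_end <- s + dur; next }
    if (i0 > last_idx + 1L) {
      x[(last_idx + 1L):(i0 - 1L)] <- rest[1]
      y[(last_idx + 1L):(i0 - 1L)] <- rest[2]
    }
    nfb <- i1 - i0 + 1L
    speed <- max(0.5, stats::rnorm(1, phen$floor_speed_cm_s,
                                   0.1 * phen$floor_speed_cm_s))
    tsec <- floor(ft[i0:i1] - s)
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(max(tsec) , 0, 0.8)))
    th <- theta[tsec + 1]
    step <- speed / frame_rate * px
    bx <- rest[1] + cumsum(step * cos(th))
    by <- rest[2] + cumsum(step * sin(th))
    bx <- fold_reflect(bx, margin, W - margin)
    by <- fold_reflect(by, margin, H - margin)
    x[i0:i1] <- bx; y[i0:i1] <- by
    move[i0:i1] <- TRUE
    rest <- c(bx[nfb], by[nfb])
    last_idx <- i1
    cur_end <- s + dur
    n_bouts <- n_bouts + 1L
  }
  if (last_idx < nf) {
    x[(last_idx + 1L):nf] <- rest[1]
    y[(last_idx + 1L):nf] <- rest[2]
  }
  # detection noise: continuous jitter while moving, sparse twitches at rest
  jit <- noise$track_jitter_px
  if (jit > 0) {
    mv <- which(move)
    x[mv] <- x[mv] + stats::rnorm(length(mv), 0, jit)
    y[mv] <- y[mv] + stats::rnorm(length(mv), 0, jit)
    rs <- which(!move & stats::runif(nf) < noise$rest_twitch_prob)
    x[rs] <- x[rs] + stats::rnorm(length(rs), 0, 1.5 * jit)
    y[rs] <- y[rs] + stats::rnorm(length(rs), 0, 1.5 * jit)
  }
  conf <- stats::runif(nf, 0.75, 1)
  drop <- stats::runif(nf) < noise$conf_drop_prob
  conf[drop] <- stats::runif(sum(drop), 0, 0.4)
  list(x = x, y = y, confidence = conf, n_bouts = n_bouts)
}

#' Simulate all annotation channels for one mouse-period
#'
#' Generates the five channel kinds the scoring pipeline consumes, with
#' full ground truth: wheel rotations from a piecewise-constant-rate
#' bout process (dark vs light rates) rendered as per-frame marker
#' emissions with classifier flip noise; a floor track of alternating
#' rest/movement bouts with detection jitter; per-minute body-weight
#' estimates following a linear trajectory with confidence weights;
#' coat-roughness samples around the phenotype mean; and a nest-centroid
#' random walk at the phenotype's displacement rate.
#'
#' All randomness flows from `seed`; two calls with identical arguments
#' produce identical channels.
#'
#' @param phenotype A [mouse_phenotype()].
#' @param noise A [noise_model()].
#' @param period List or one-row data frame with `start` and `end`
#'   (`POSIXct` UTC or numeric seconds); must span at least one hour.
#' @param cycle A [light_cycle()].
#' @param calib A [cage_calibration()].
#' @param seed Integer seed.
#' @param frame_rate Frames per second for wheel emissions and track
#'   samples. Default 4 (kept below video rate for tractable volumes;
#'   all downstream code is rate-agnostic).
#' @param utc_offset_hours Local-time offset from UTC, hours.
#' @param weight_sample_s,coat_sample_s,nest_sample_s Sampling cadences,
#'   seconds. Defaults 60, 60, 600.
#' @return List of class `cage_mouse_sim` with `channels` (named list of
#'   [channel()] objects) and `truth` (generating parameters plus the
#'   realised rotation count and bout count).
#' @export
simulate_mouse <- function(phenotype, noise = noise_model(), period,
                           cycle = light_cycle(),
                           calib = cage_calibration(), seed = 1,
                           frame_rate = 4, utc_offset_hours = 0,
                           weight_sample_s = 60, coat_sample_s = 60,
                           nest_sample_s = 600) {
  stopifnot(inherits(phenotype, "mouse_phenotype"),
            inherits(noise, "noise_model"))
  t0 <- as.numeric(period$start); t1 <- as.numeric(period$end)
  if (!is.finite(t0) || !is.finite(t1) || t1 - t0 < 3600) {
    stop("period must span at least one hour")
  }
  set.seed(seed)
  nf <- as.integer(floor((t1 - t0) * frame_rate))
  ft <- t0 + (seq_len(nf) - 1) / frame_rate

  rot <- simulate_rotations(phenotype, t0, t1, cycle, utc_offset_hours,
                            frame_rate)
  em <- emissions_from_rotations(rot, ft, noise)
  wheel_ch <- channel("wheel_emission",
                      data.frame(time = ft, p_top = em$p_top))

  tr <- simulate_track(phenotype, noise, t0, t1, ft, cycle,
                       utc_offset_hours, calib)
  track_ch <- channel("track", data.frame(time = ft, x_px = tr$x,
                                          y_px = tr$y,
                                          confidence = tr$confidence))

  wt <- seq(t0 + 30, t1, by = weight_sample_s)
  days <- (wt - t0) / 86400
  grams <- pmax(1, phenotype$weight0_g + phenotype$weight_slope_g_day * days +
                  stats::rnorm(length(wt), 0,
                               noise$weight_cv * phenotype$weight0_g))
  ww <- stats::runif(length(wt), 0.2, 1)
  ww[stats::runif(length(wt)) < 0.05] <- 0
  weight_ch <- channel("weight", data.frame(time = wt, grams = grams,
                                            weight_w = ww))

  ct <- seq(t0 + 45, t1, by = coat_sample_s)
  m <- phenotype$coat_roughness_mean
  rough <- if (m > 0) {
    stats::rgamma(length(ct), shape = (m / 2)^2, rate = m / 4)
  } else {
    rep(0, length(ct))
  }
  coat_ch <- channel("coat", data.frame(time = ct, roughness = rough))

  nt <- seq(t0 + 300, t1, by = nest_sample_s)
  dt_h <- nest_sample_s / 3600
  sigma <- phenotype$nest_speed_cm_h * dt_h / sqrt(pi / 2) * calib$px_per_cm
  nx <- cumsum(c(200, stats::rnorm(length(nt) - 1, 0, sigma)))
  ny <- cumsum(c(150, stats::rnorm(length(nt) - 1, 0, sigma)))
  area <- pmax(0, stats::rnorm(length(nt), 4000, 300))
  area[stats::runif(length(nt)) < 0.05] <- 10  # transient bad segmentations
  nest_ch <- channel("nest", data.frame(time = nt, centroid_x_px = nx,
                                        centroid_y_px = ny, area_px = area))

  structure(list(
    channels = list(wheel_emission = wheel_ch, track = track_ch,
                    weight = weight_ch, coat = coat_ch, nest = nest_ch),
    truth = list(phenotype = phenotype, noise = noise, seed = seed,
                 frame_rate = frame_rate,
                 n_rotations = length(rot$u),
                 n_floor_bouts = tr$n_bouts)),
    class = "cage_mouse_sim")
}

#' Simulate a frailty study cohort
#'
#' Generates a complete multi-mouse dataset: per-mouse annotation
#' channels, an occupancy table, a simulated MFI table, a
#' date-of-birth table, and a ground-truth table of latent frailty.
#' Ages are drawn uniformly over `age_range`; each mouse's latent
#' frailty is `base + effect * span * (age - min) / range` plus Gaussian
#' noise, clamped to `[0, 1]` — `effect = 0` gives an age-independent
#' (null) cohort. MFI items go non-zero with probability increasing in
#' a noisy copy of the same latent frailty, reproducing the sparse,
#' discrete structure of manual scores and the shared non-age latent
#' between MFI and DFI.
#'
#' @param n_mice Number of mice (>= 2).
#' @param seed Integer seed; all randomness derives from it.
#' @param age_range Age range in days, default `c(200, 900)`.
#' @param effect Age-to-frailty effect size in `[0, 1]`; 1 = strong
#'   linear effect, 0 = null.
#' @param latent_sd SD of the non-age latent frailty component. Default
#'   0.12.
#' @param base Latent frailty at the youngest age. Default 0.05.
#' @param span Latent frailty gain across the age range at `effect = 1`.
#'   Default 0.85.
#' @param noise A [noise_model()].
#' @param n_days Full observation days per mouse. Default 2 (the minimum
#'   qualifying period length).
#' @param frame_rate Frames per second for per-frame channels. Default 4.
#' @param cycle A [light_cycle()].
#' @param calib A [cage_calibration()].
#' @param mfi_noise_sd SD of the MFI-specific latent noise. Default 0.08.
#' @return List of class `cage_cohort`: `channels` (named by mouse id),
#'   `occupancy`, `mfi`, `dob`, `truth` data frames, plus the `cycle`,
#'   `calib`, `noise` used.
#' @export
generate_cohort <- function(n_mice = 60, seed = 1, age_range = c(200, 900),
                            effect = 1, latent_sd = 0.12, base = 0.05,
                            span = 0.85, noise = noise_model(), n_days = 2,
                            frame_rate = 4, cycle = light_cycle(),
                            calib = cage_calibration(), mfi_noise_sd = 0.08) {
  if (n_mice < 2) stop("n_mice must be at least 2")
  set.seed(seed)
  ids <- sprintf("m%03d", seq_len(n_mice))
  ages <- round(stats::runif(n_mice, age_range[1], age_range[2]))
  rel <- (ages - age_range[1]) / max(1, diff(age_range))
  latent <- pmin(pmax(base + effect * span * rel +
                        stats::rnorm(n_mice, 0, latent_sd), 0), 1)
  sexes <- sample(c("F", "M"), n_mice, replace = TRUE)
  mouse_seeds <- sample.int(.Machine$integer.max - 1, n_mice)

  study_day0 <- as.numeric(as.POSIXct("2026-01-05 00:00:00", tz = "UTC"))
  occ_start <- study_day0 + 14.5 * 3600          # mid-afternoon cage entry
  occ_end <- study_day0 + (n_days + 1) * 86400 + 2 * 3600
  p_start <- study_day0 + 86400
  p_end <- p_start + n_days * 86400
  period <- list(start = p_start, end = p_end, n_full_days = n_days)

  channels <- vector("list", n_mice)
  names(channels) <- ids
  truth_rows <- vector("list", n_mice)
  mfi_rows <- vector("list", n_mice)
  mfi_gap <- sample(-3:3, n_mice, replace = TRUE)
  mfi_latent <- pmin(pmax(latent + stats::rnorm(n_mice, 0, mfi_noise_sd), 0), 1)
  item_names <- sprintf("item_%02d", 1:29)
  dfi_date <- as.Date(as.POSIXct(p_start, origin = "1970-01-01", tz = "UTC"))

  for (i in seq_len(n_mice)) {
    phen <- phenotype_for_frailty(latent[i], age_days = ages[i],
                                  sex = sexes[i])
    sim <- simulate_mouse(phen, noise, period, cycle, calib,
                          seed = mouse_seeds[i], frame_rate = frame_rate)
    channels[[i]] <- sim$channels
    truth_rows[[i]] <- data.frame(
      mouse_id = ids[i], age_days = ages[i], sex = sexes[i],
      latent_frailty = latent[i], n_rotations = sim$truth$n_rotations,
      stringsAsFactors = FALSE)
  }

  set.seed(seed + 1)  # MFI draws independent of channel stream order
  for (i in seq_len(n_mice)) {
    p_item <- 0.02 + 0.45 * mfi_latent[i]
    nonzero <- stats::runif(29) < p_item
    vals <- ifelse(nonzero,
                   sample(c(0.5, 1), 29, replace = TRUE, prob = c(0.7, 0.3)),
                   0)
    row <- data.frame(mouse_id = ids[i],
                      date = dfi_date + mfi_gap[i],
                      stringsAsFactors = FALSE)
    row[item_names] <- as.list(vals)
    mfi_rows[[i]] <- row
  }

  occupancy <- data.frame(
    device_id = paste0("cam", seq_len(n_mice)),
    cage_position = paste0("pos", seq_len(n_mice)),
    mouse_id = ids,
    start = as.POSIXct(occ_start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(occ_end, origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE)
  dob <- data.frame(mouse_id = ids, dob = dfi_date - ages, sex = sexes,
                    stringsAsFactors = FALSE)
  mfi <- validate_mfi(do.call(rbind, mfi_rows))

  structure(list(channels = channels, occupancy = occupancy, mfi = mfi,
                 dob = dob, truth = do.call(rbind, truth_rows),
                 cycle = cycle, calib = calib, noise = noise,
                 n_days = n_days, frame_rate = frame_rate, seed = seed),
            class = "cage_cohort")
}

#' Write or read a cohort dataset as a directory of CSV files
#'
#' `write_cohort()` lays a [generate_cohort()] result out on disk:
#' `occupancy.csv`, `mfi.csv`, `dob.csv`, `truth.csv`, and one
#' `<mouse>_<kind>.csv` channel file per mouse and channel kind.
#' `read_cohort_dir()` loads such a directory back (the truth table is
#' optional, as real deployments have none).
#'
#' @param cohort A `cage_cohort`.
#' @param dir Directory path (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort_dir()`
#'   returns a list with `channels`, `occupancy`, `mfi`, `dob`, `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cage_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  occ <- cohort$occupancy
  occ$start <- fmt_time_iso(occ$start)
  occ$end <- fmt_time_iso(occ$end)
  utils::write.csv(occ, file.path(dir, "occupancy.csv"), row.names = FALSE)
  utils::write.csv(cohort$mfi, file.path(dir, "mfi.csv"), row.names = FALSE)
  utils::write.csv(cohort$dob, file.path(dir, "dob.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (id in names(cohort$channels)) {
    for (kind in names(cohort$channels[[id]])) {
      write_channel_table(cohort$channels[[id]][[kind]],
                          file.path(dir, paste0(id, "_", kind, ".csv")))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_dir <- function(dir) {
  occupancy <- read_occupancy_table(file.path(dir, "occupancy.csv"))
  mfi <- read_mfi_table(file.path(dir, "mfi.csv"))
  dob <- utils::read.csv(file.path(dir, "dob.csv"),
                         stringsAsFactors = FALSE)
  dob$dob <- as.Date(dob$dob)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  channels <- list()
  for (id in unique(occupancy$mouse_id)) {
    chans <- list()
    for (kind in channel_kinds()) {
      p <- file.path(dir, paste0(id, "_", kind, ".csv"))
      if (file.exists(p)) chans[[kind]] <- read_channel_table(p, kind)
    }
    channels[[id]] <- chans
  }
  list(channels = channels, occupancy = occupancy, mfi = mfi, dob = dob,
       truth = truth)
}

#' Score every mouse of a simulated cohort
#'
#' Derives measurement periods from the cohort's occupancy table and runs
#' the full scoring pipeline, attaching age and sex from the
#' date-of-birth table.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [dfi_config()]; its light cycle is taken from the
#'   cohort by default.
#' @return [dfi_table()]-style data frame with additional `age_days` and
#'   `sex` columns.
#' @export
score_cohort <- function(cohort, config = NULL) {
  stopifnot(inherits(cohort, "cage_cohort"))
  if (is.null(config)) config <- dfi_config(cycle = cohort$cycle)
  periods <- derive_periods(cohort$occupancy, mode = "jdo",
                            utc_offset_hours = config$utc_offset_hours)
  tab <- score_dataset(cohort$channels, periods, config, cohort$calib)
  idx <- match(tab$mouse_id, cohort$dob$mouse_id)
  tab$age_days <- compute_age(cohort$dob$dob[idx], tab$date)
  tab$sex <- cohort$dob$sex[idx]
  tab
}

#' Benchmark a DFI table against MFI and age
#'
#' Runs the full benchmarking battery: DFI~age and MFI~age regressions,
#' nearest-date MFI/DFI pairing, MFI~DFI regression on the pairs, and
#' the age-normalized residual correlation.
#'
#' @param dfi_records Data frame with `mouse_id`, `date`, `dfi` (and
#'   optionally `age_days`).
#' @param mfi_records Data frame with `mouse_id`, `date`, `overall`.
#' @param dob Data frame with `mouse_id`, `dob` used to compute ages.
#' @return List with `dfi_vs_age`, `mfi_vs_age`, `pairs`, `mfi_vs_dfi`,
#'   and `residual_analysis`.
#' @export
benchmark_cohort <- function(dfi_records, mfi_records, dob) {
  idx_d <- match(dfi_records$mouse_id, dob$mouse_id)
  dfi_records$age_days <- compute_age(dob$dob[idx_d], dfi_records$date)
  idx_m <- match(mfi_records$mouse_id, dob$mouse_id)
  mfi_age <- compute_age(dob$dob[idx_m], mfi_records$date)
  pairs <- pair_mfi_dfi(dfi_records, mfi_records)
  list(dfi_vs_age = linregress(dfi_records$age_days, dfi_records$dfi),
       mfi_vs_age = linregress(mfi_age, mfi_records$overall),
       pairs = pairs,
       mfi_vs_dfi = linregress(pairs$mfi, pairs$dfi),
       residual_analysis = age_residual_correlation(pairs))
}
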