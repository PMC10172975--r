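test_that("track cleaning drops low confidence and splits on jumps/gaps", {
  t0 <- as.numeric(utc("2026-01-06"))
  n <- 50
  ch <- make_track(t0 + 1:n, rep(100, n), rep(80, n), conf = rep(0, n))
  expect_equal(length(clean_track(ch)), 0)

  ch2 <- make_track(t0 + 1:n, rep(100, n), rep(80, n))
  segs <- clean_track(ch2)
  expect_equal(length(segs), 1)
  expect_equal(nrow(segs[[1]]), n)

  # one teleporting sample (> max_jump_cm) splits the segment
  x <- rep(100, n); x[25:n] <- 100 + 25 * 15  # 25 cm jump at 15 px/cm
  ch3 <- make_track(t0 + 1:n, x, rep(80, n))
  expect_equal(length(clean_track(ch3, max_jump_cm = 20)), 2)

  # a long gap also splits
  tt <- t0 + c(1:25, 36:60)
  ch4 <- make_track(tt, rep(100, 50), rep(80, 50))
  expect_equal(length(clean_track(ch4, max_gap_s = 2)), 2)
})

test_that("binned distance sums step lengths into the earlier sample's bin", {
  t0 <- utc("2026-01-06")
  calib <- cage_calibration(px_per_cm = 15)
  n <- 61
  still <- list(data.frame(time = t0 + 0:(n - 1),
                           x_px = rep(10, n), y_px = rep(10, n)))
  b <- distance_binned(still, bin_s = 60, calib = calib, t0 = t0, t1 = t0 + 120)
  expect_equal(b$distance_cm, c(0, 0))

  # straight line at 2 cm/s for 60 s -> 120 cm in the first bin
  seg <- data.frame(time = t0 + 0:60, x_px = 10 + 2 * 15 * (0:60),
                    y_px = rep(10, 61))
  b2 <- distance_binned(list(seg), bin_s = 60, calib = calib,
                        t0 = t0, t1 = t0 + 120)
  expect_equal(b2$distance_cm[1], 120)
  expect_equal(b2$distance_cm[2], 0)

  # random walk: total binned distance equals direct step resummation
  set.seed(21)
  m <- 500
  seg3 <- data.frame(time = t0 + sort(runif(m, 0, 3600)),
                     x_px = cumsum(rnorm(m, 0, 4)),
                     y_px = cumsum(rnorm(m, 0, 4)))
  b3 <- distance_binned(list(seg3), bin_s = 300, calib = calib,
                        t0 = t0, t1 = t0 + 3600)
  oracle <- sum(sqrt(diff(seg3$x_px)^2 + diff(seg3$y_px)^2)) / 15
  expect_equal(sum(b3$distance_cm), oracle, tolerance = 1e-9)
})

test_that("total distance is invariant to reversal/translation, scales with px_per_cm", {
  t0 <- utc("2026-01-06")
  set.seed(22)
  m <- 200
  seg <- data.frame(time = t0 + 1:m, x_px = cumsum(rnorm(m, 0, 3)),
                    y_px = cumsum(rnorm(m, 0, 3)))
  tot <- function(s, ppc = 15) {
    sum(distance_binned(list(s), 3600, cage_calibration(px_per_cm = ppc),
                        t0 = t0, t1 = t0 + m + 1)$distance_cm)
  }
  ref <- tot(seg)
  rev_seg <- data.frame(time = seg$time, x_px = rev(seg$x_px),
                        y_px = rev(seg$y_px))
  sh_seg <- data.frame(time = seg$time, x_px = seg$x_px + 500,
                       y_px = seg$y_px - 200)
  expect_equal(tot(rev_seg), ref, tolerance = 1e-9)
  expect_equal(tot(sh_seg), ref, tolerance = 1e-9)
  expect_equal(tot(seg, ppc = 30), ref / 2, tolerance = 1e-9)
})

test_that("floor gait speed summarises above-threshold window speeds", {
  t0 <- utc("2026-01-06")
  calib <- cage_calibration(px_per_cm = 15)
  # constant velocity 2 cm/s
  seg <- data.frame(time = t0 + (0:99) / 4, x_px = 10 + 2 * 15 * (0:99) / 4,
                    y_px = rep(5, 100))
  expect_equal(floor_gait_speed(list(seg), calib = calib), 2, tolerance = 1e-9)

  # entirely sub-threshold drift is missing, not zero
  slow <- data.frame(time = t0 + (0:99) / 4, x_px = 10 + 0.1 * 15 * (0:99) / 4,
                     y_px = rep(5, 100))
  r <- floor_gait_speed(list(slow), calib = calib,
                        move_threshold_cm_s = 0.5)
  expect_true(is.na(r))
  expect_match(missing_reason(r), "threshold")

  # two-speed track matches a brute-force window oracle
  v <- c(rep(8, 100), rep(1, 300))  # cm/s per frame interval, 4 Hz
  x_cm <- c(0, cumsum(v / 4))
  seg2 <- data.frame(time = t0 + (0:400) / 4, x_px = x_cm * 15,
                     y_px = rep(0, 401))
  got <- floor_gait_speed(list(seg2), window_s = 1,
                          move_threshold_cm_s = 0.5, percentile = 0.9,
                          calib = calib)
  tt <- (0:400) / 4
  cd <- x_cm
  sp <- c()
  for (i in 1:401) {
    j <- max(which(tt <= tt[i] + 1))
    if (j > i) sp <- c(sp, (cd[j] - cd[i]) / (tt[j] - tt[i]))
  }
  sp <- sp[sp > 0.5]
  expect_equal(got, percentile_oracle(sp, 0.9), tolerance = 1e-9)

  # monotone non-decreasing in the percentile parameter
  p_grid <- c(0.1, 0.5, 0.8, 0.95)
  vals <- vapply(p_grid, function(p) {
    floor_gait_speed(list(seg2), percentile = p, calib = calib)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("floor circadian fraction mirrors the wheel definition", {
  cyc <- light_cycle(18, 12)
  day0 <- utc("2026-01-06")
  bins <- data.frame(bin_start = day0 + (0:23) * 3600 + 1800,
                     distance_cm = rep(10, 24))
  expect_equal(floor_circadian(bins, cyc), 0.5)
  dark_only <- data.frame(bin_start = day0 + c(19, 20, 21) * 3600,
                          distance_cm = c(50, 60, 70))
  expect_equal(floor_circadian(dark_only, cyc), 1.0)
  none <- data.frame(bin_start = day0 + (0:23) * 3600,
                     distance_cm = rep(0, 24))
  expect_true(is.na(floor_circadian(none, cyc)))
})
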