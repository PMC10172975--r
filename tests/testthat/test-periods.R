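occ_row <- function(start, end, mouse = "m1", pos = "p1") {
  data.frame(device_id = "cam1", cage_position = pos, mouse_id = mouse,
             start = utc(start), end = utc(end), stringsAsFactors = FALSE)
}

test_that("jdo mode keeps only the first 6 full days", {
  # recording 13:00 day0 through 07:00 day8 -> 7 full days available
  occ <- occ_row("2026-01-01 13:00:00", "2026-01-09 07:00:00")
  p <- derive_periods(occ, mode = "jdo")
  expect_equal(nrow(p), 1)
  expect_equal(p$n_full_days, 6)
  expect_equal(p$first_full_day, as.Date("2026-01-02"))
  expect_equal(p$start, utc("2026-01-02 00:00:00"))
  expect_equal(as.numeric(p$end) - as.numeric(p$start), 6 * 86400)
})

test_that("episodes with fewer than 2 full days are dropped", {
  occ <- occ_row("2026-01-01 12:00:00", "2026-01-03 01:00:00")  # 1 full day
  expect_equal(nrow(derive_periods(occ, mode = "jdo")), 0)
  # exactly 2 full days qualifies
  occ2 <- occ_row("2026-01-01 12:00:00", "2026-01-04 01:00:00")
  p <- derive_periods(occ2, mode = "jdo")
  expect_equal(p$n_full_days, 2)
})

test_that("consecutive mode tiles three abutting 144-hour periods", {
  occ <- occ_row("2026-01-01 09:30:00", "2026-01-21 12:00:00")  # 20 days
  p <- derive_periods(occ, mode = "consecutive")
  expect_equal(nrow(p), 3)
  expect_true(all(as.numeric(p$end) - as.numeric(p$start) == 144 * 3600))
  # abutting: each period starts where the previous ended
  expect_equal(p$start[-1], p$end[-3])
})

test_that("full days follow the configured local midnight", {
  occ <- occ_row("2026-01-01 13:00:00", "2026-01-09 07:00:00")
  # UTC-8 local zone shifts the day boundary to 08:00 UTC
  p <- derive_periods(occ, mode = "jdo", utc_offset_hours = -8)
  expect_equal(p$start, utc("2026-01-02 08:00:00"))
})

test_that("short occupancy gaps are bridged, long ones split episodes", {
  occ <- rbind(occ_row("2026-01-01 10:00:00", "2026-01-03 12:00:00"),
               occ_row("2026-01-03 12:00:30", "2026-01-06 12:00:00"))
  p <- derive_periods(occ, mode = "jdo")  # 30 s dropout bridged
  expect_equal(nrow(p), 1)
  expect_equal(p$n_full_days, 4)
  occ2 <- rbind(occ_row("2026-01-01 10:00:00", "2026-01-04 12:00:00"),
                occ_row("2026-01-04 14:00:00", "2026-01-08 12:00:00"))
  p2 <- derive_periods(occ2, mode = "jdo")  # 2 h gap splits
  expect_equal(nrow(p2), 2)
  expect_equal(sort(p2$n_full_days), c(2, 3))
})

test_that("overlapping occupancy for one cage position is rejected", {
  occ <- rbind(occ_row("2026-01-01 10:00:00", "2026-01-05 10:00:00",
                       mouse = "m1"),
               occ_row("2026-01-04 10:00:00", "2026-01-08 10:00:00",
                       mouse = "m2"))
  expect_error(derive_periods(occ), "overlapping")
})

test_that("jdo yields at most one period per occupancy episode", {
  set.seed(11)
  occs <- do.call(rbind, lapply(1:20, function(i) {
    s <- utc("2026-01-01") + runif(1, 0, 30) * 86400
    occ_row(s, s + runif(1, 0.5, 10) * 86400, mouse = paste0("m", i),
            pos = paste0("p", i))
  }))
  p <- derive_periods(occs, mode = "jdo")
  expect_lte(nrow(p), nrow(occs))
  expect_true(all(p$n_full_days >= 2 & p$n_full_days <= 6))
  # whole local days: bounds at midnight
  expect_true(all(as.numeric(p$start) %% 86400 == 0))
})

test_that("age is the calendar-day difference from cohort birth date", {
  expect_equal(compute_age("2025-01-01", "2025-01-01"), 0L)
  expect_equal(compute_age("2025-01-01", as.Date("2025-01-01") + 148), 148L)
  # leap year: 2024 has 366 days
  expect_equal(compute_age("2024-01-01", "2025-01-01"), 366L)
  expect_equal(compute_age("2023-01-01", "2024-01-01"), 365L)
  expect_error(compute_age("2025-01-02", "2025-01-01"), "precedes")
})

test_that("MFI tables validate the 29-item 0/0.5/1 scheme", {
  items <- sprintf("item_%02d", 1:29)
  df <- data.frame(mouse_id = c("a", "b"), date = "2026-01-05")
  df[items] <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  m <- read_mfi_table(path)
  expect_equal(m$overall, c(0, 0))

  df2 <- df; df2[1, items[5]] <- 1
  write.csv(df2, path, row.names = FALSE)
  expect_equal(read_mfi_table(path)$overall[1], 1 / 29)

  df3 <- df; df3[2, items[3]] <- 0.7
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_mfi_table(path), "not in \\{0, 0.5, 1\\}")

  df4 <- df[, 1:30]  # only 28 items
  write.csv(df4, path, row.names = FALSE)
  expect_error(read_mfi_table(path), "exactly 29")
})
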