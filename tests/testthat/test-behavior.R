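# build a one-channel LD record from per-minute counts (light on ZT0-12)
toy_record <- function(x, days = NULL, light = NULL) {
  n <- length(x)
  stopifnot(n %% 1440 == 0)
  counts <- matrix(0L, n, 32L)
  counts[, 1] <- as.integer(x)
  mod <- rep(0:1439, n / 1440)
  if (is.null(light)) light <- as.integer(mod < 720)
  timsplice:::new_dam_record(counts, light, mod,
                             rep(seq_len(n / 1440), each = 1440))
}

test_that("simulated monitor files round-trip through the parser", {
  sim <- simulate_dam(n_channels = 4, days_ld = 2, days_dd = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam(sim$record, path)
  expect_length(readLines(path), 1440 * 3)
  back <- read_dam(path)
  expect_identical(back$counts, sim$record$counts)
  expect_identical(back$light, sim$record$light)
  expect_identical(back$day_phase, c("LD", "LD", "DD"))
})

test_that("gaps and malformed lines are caught with line numbers", {
  sim <- simulate_dam(n_channels = 2, days_ld = 1, days_dd = 0, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam(sim$record, path)
  lines <- readLines(path)

  writeLines(lines[-100], path)                      # missing minute
  expect_error(read_dam(path, gap_policy = "error"), "gap.*line 99")
  rec <- read_dam(path)                              # default: flag
  expect_identical(rec$gaps, 100L)
  expect_error(day_night_ratio(rec), "gap")
  rec2 <- read_dam(path, gap_policy = "zero_fill")
  expect_silent(day_night_ratio(rec2))

  writeLines(c(lines[1:50], substr(lines[51], 1, 40)), path)  # truncated
  expect_error(read_dam(path), "line 51")

  writeLines(lines[c(1:60, 60, 61)], path)           # repeated timestamp
  expect_error(read_dam(path), "non-monotone.*line 61")
})

test_that("day/night ratios follow the arithmetic and Poisson oracles", {
  expect_equal(day_night_ratio(toy_record(rep(2L, 1440)), channels = 1)$ratio, 1)

  # 300 day counts vs 100 night counts over equal phase lengths
  x <- withr::with_seed(4L, {
    v <- integer(1440)
    v[sample(1:720, 300)] <- 1L
    v[sample(721:1440, 100)] <- 1L
    v
  })
  expect_equal(day_night_ratio(toy_record(x), channels = 1)$ratio, 3)

  # 2:1 Poisson channel over 4 LD days
  pois <- withr::with_seed(5L, {
    rates <- rep(c(rep(0.5, 720), rep(0.25, 720)), 4)
    rpois(length(rates), rates)
  })
  r <- day_night_ratio(toy_record(pois), channels = 1)$ratio
  se <- 2 * sqrt(1 / (0.5 * 2880) + 1 / (0.25 * 2880))  # delta method
  expect_lt(abs(r - 2), 3 * se)

  expect_error(day_night_ratio(toy_record(pois), days = 9), "LD day")
  z <- toy_record(c(rep(1L, 720), rep(0L, 720)))
  expect_identical(day_night_ratio(z, channels = 1)$flag, "infinite")
})

test_that("day/night ratio is invariant to uniform count rescaling", {
  x <- withr::with_seed(6L, rpois(2880, rep(c(0.6, 0.2), each = 720)))
  r1 <- day_night_ratio(toy_record(x), channels = 1)$ratio
  r2 <- day_night_ratio(toy_record(5L * x), channels = 1)$ratio
  expect_equal(r1, r2)
})

profile_of <- function(values) {
  structure(list(values = values, bin = 30L, channel = 1L, days = 1L),
            class = "activity_profile")
}

test_that("onset detection handles the three canonical profile shapes", {
  # clean ramp: flat zero, then strictly increasing from bin 20 (ZT 9.5)
  ramp <- numeric(48); ramp[20:24] <- c(10, 20, 30, 40, 50)
  r <- detect_onset(profile_of(ramp), "evening")
  expect_true(r$detected)
  expect_equal(r$onset_min, (20 - 1) * 30)

  # an interior dip smaller than 10% is not an outlier: same onset
  dip <- numeric(48); dip[20:24] <- c(10, 20, 19, 30, 40)
  r2 <- detect_onset(profile_of(dip), "evening")
  expect_true(r2$detected)
  expect_equal(r2$onset_min, r$onset_min)
  expect_identical(r2$outliers, 0L)

  # a run where more than a third of the bins drop by >= 10%: no component
  bad <- numeric(48); bad[19:25] <- c(20, 17, 45, 38, 60, 54, 95)
  r3 <- detect_onset(profile_of(bad), "evening")
  expect_false(r3$detected)
  expect_gt(r3$outliers, floor(r3$run_length / 3))
})

test_that("onsets are recovered within one bin across simulated channels", {
  onsets <- withr::with_seed(12L, sample(480:590, 25, replace = TRUE))
  sim <- simulate_dam(n_channels = 25, days_ld = 4, days_dd = 0,
                      evening_onset = onsets, seed = 13)
  err <- vapply(1:25, function(ch) {
    r <- detect_onset(activity_profile(sim$record, ch), "evening")
    if (!r$detected) return(NA_real_)
    r$onset_min - onsets[ch]
  }, numeric(1))
  expect_true(all(!is.na(err)))
  expect_true(all(abs(err) <= 30))
})

test_that("morning onsets wrapping past midnight are found in the ZT18-36 window", {
  sim <- simulate_dam(n_channels = 3, days_ld = 4, days_dd = 0, seed = 17)
  for (ch in 1:3) {
    r <- detect_onset(activity_profile(sim$record, ch), "morning")
    expect_true(r$detected)
    expect_lte(abs(r$onset_min - 1320), 30)
  }
})

test_that("free-running period and RI recover planted DD rhythms", {
  sim24 <- simulate_dam(n_channels = 2, seed = 19)
  r <- estimate_period(sim24$record, 1)
  expect_true(r$rhythmic)
  expect_lte(abs(r$period_h - 24), 0.5)

  sim23 <- simulate_dam(n_channels = 2, free_running_period_h = 23, seed = 23)
  r23 <- estimate_period(sim23$record, 1)
  expect_lte(abs(r23$period_h - 23), 0.5)

  arr <- simulate_dam(n_channels = 2, arrhythmic_channels = 2, seed = 29)
  expect_false(estimate_period(arr$record, 2)$rhythmic)

  expect_error(estimate_period(simulate_dam(days_dd = 2, seed = 1)$record, 1),
               "3 DD days")
})

test_that("period estimation is invariant to offset and scale", {
  sim <- simulate_dam(n_channels = 1, seed = 31)
  r0 <- estimate_period(sim$record, 1)
  rec2 <- sim$record
  rec2$counts[, 1] <- rec2$counts[, 1] * 7L + 3L
  r1 <- estimate_period(rec2, 1)
  expect_equal(r0$period_h, r1$period_h)
  expect_equal(r0$ri, r1$ri, tolerance = 1e-12)
})
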