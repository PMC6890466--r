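MONTHS3 <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# truncated-Gaussian activity component: rate contribution at minute-of-day m
# for a component starting (first rising) at `onset`, spanning `width`
# minutes, peaking at onset + width/2 (sigma = width/4); wraps across
# midnight
component_rate <- function(m, onset, width, peak) {
  delta <- (m - onset) %% 1440
  g <- peak * exp(-(delta - width / 2)^2 / (2 * (width / 4)^2))
  g[delta > width] <- 0
  g
}

#' Simulate a Drosophila activity-monitor experiment
#'
#' Generates per-minute Poisson beam counts for up to 32 channels over
#' `days_ld` light:dark days followed by `days_dd` days of constant
#' darkness. During LD the rate is a baseline plus truncated-Gaussian
#' morning and evening components anchored at the programmed onsets (the
#' onset is the first minute at which a component raises the rate above
#' baseline). During DD the rate follows a sinusoid with the channel's
#' free-running period; channels listed in `arrhythmic_channels` get a
#' constant, mean-matched DD rate instead.
#'
#' @param n_channels Channels to populate (1..32).
#' @param days_ld,days_dd Days of LD entrainment and constant darkness.
#' @param lights_on,lights_off Clock minutes of the light phase (12:12 LD by
#'   default).
#' @param morning_onset,evening_onset Programmed component onsets in minutes
#'   within the day (scalar or per channel). Defaults: morning anticipation
#'   at ZT22, evening component at ZT9.
#' @param component_width Component span in minutes (default 240: a 4 h
#'   activity buildup, wide enough to rise over several 30-min bins).
#' @param baseline_rate,peak_rate Counts/min: tonic rate and component peak.
#' @param free_running_period_h DD period in hours (scalar or per channel).
#' @param dd_peak_zt Clock hour at which the DD sinusoid peaks.
#' @param arrhythmic_channels Integer channel indices with flat DD rate.
#' @param seed Integer seed.
#' @return List with `record` (a `dam_record`, see [read_dam()]) and `truth`
#'   (per-channel onsets, period, arrhythmic flag).
#' @export
simulate_dam <- function(n_channels = 32L, days_ld = 4L, days_dd = 5L,
                         lights_on = 0L, lights_off = 720L,
                         morning_onset = 1320L, evening_onset = 540L,
                         component_width = 240L, baseline_rate = 0.1,
                         peak_rate = 4, free_running_period_h = 24,
                         dd_peak_zt = 11, arrhythmic_channels = integer(0),
                         seed = 1L) {
  if (n_channels < 1L || n_channels > 32L) stopf("'n_channels' must be in 1..32")
  if (days_ld + days_dd < 1L) stopf("need at least one day (days_ld + days_dd > 0)")
  rep_ch <- function(x) if (length(x) == 1L) rep(x, n_channels) else x
  morning_onset <- rep_ch(morning_onset); evening_onset <- rep_ch(evening_onset)
  free_running_period_h <- rep_ch(free_running_period_h)
  if (any(c(morning_onset, evening_onset) < 0) ||
      any(c(morning_onset, evening_onset) >= 1440)) {
    stopf("onsets must be minutes in [0, 1440)")
  }
  if (baseline_rate < 0 || peak_rate < 0) stopf("rates must be non-negative")
  total_days <- days_ld + days_dd
  n_min <- 1440L * total_days
  minute_of_day <- rep(0:1439, total_days)
  day <- rep(seq_len(total_days), each = 1440L)
  is_ld <- day <= days_ld
  light <- as.integer(is_ld & minute_of_day >= lights_on &
                        minute_of_day < lights_off)
  counts <- matrix(0L, n_min, 32L)
  arr <- seq_len(n_channels) %in% arrhythmic_channels
  with_seed(seed, {
    for (ch in seq_len(n_channels)) {
      rate <- numeric(n_min)
      rate[is_ld] <- baseline_rate +
        component_rate(minute_of_day[is_ld], morning_onset[ch],
                       component_width, peak_rate) +
        component_rate(minute_of_day[is_ld], evening_onset[ch],
                       component_width, peak_rate)
      if (any(!is_ld)) {
        t_h <- (which(!is_ld) - 1L) / 60
        rate[!is_ld] <- if (arr[ch]) {
          baseline_rate + peak_rate / 2
        } else {
          baseline_rate + peak_rate *
            (1 + cos(2 * pi * (t_h - dd_peak_zt) / free_running_period_h[ch])) / 2
        }
      }
      counts[, ch] <- rpois(n_min, rate)
    }
    record <- new_dam_record(counts, light, minute_of_day, day)
    truth <- list(kind = "dam",
                  channel = seq_len(n_channels),
                  morning_onset = morning_onset,
                  evening_onset = evening_onset,
                  period_h = ifelse(arr, NA_real_, free_running_period_h),
                  arrhythmic = arr,
                  days_ld = days_ld, days_dd = days_dd,
                  lights_on = lights_on, lights_off = lights_off,
                  seed = as.integer(seed))
    list(record = record, truth = truth)
  })
}

new_dam_record <- function(counts, light, minute_of_day, day,
                           gaps = integer(0), gaps_accepted = TRUE) {
  phase <- unname(vapply(split(light, day),
                         function(l) if (any(l == 1L)) "LD" else "DD",
                         character(1)))
  structure(list(counts = counts, light = as.integer(light),
                 minute_of_day = as.integer(minute_of_day),
                 day = as.integer(day), day_phase = phase,
                 gaps = as.integer(gaps), gaps_accepted = gaps_accepted),
            class = "dam_record")
}

#' @export
print.dam_record <- function(x, ...) {
  cat(sprintf("dam_record: %d minutes (%d LD + %d DD days), %d channels%s\n",
              nrow(x$counts), sum(x$day_phase == "LD"),
              sum(x$day_phase == "DD"), ncol(x$counts),
              if (length(x$gaps)) sprintf(", %d gap-filled minutes", length(x$gaps))
              else ""))
  invisible(x)
}

#' Write a DAM record as a Trikinetics-style monitor file
#'
#' One tab-separated line per minute: running index, date (`DD Mon YY`),
#' time (`HH:MM:SS`), status code, five unused fields, light flag, then 32
#' channel counts. The recording is dated from 1 Jan 2020, 00:00.
#'
#' @param record A `dam_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dam <- function(record, path) {
  n <- nrow(record$counts)
  date0 <- as.Date("2020-01-01")
  dts <- date0 + (record$day - 1L)
  dstr <- sprintf("%02d %s %02d", as.integer(format(dts, "%d")),
                  MONTHS3[as.integer(format(dts, "%m"))],
                  as.integer(format(dts, "%Y")) %% 100)
  tstr <- sprintf("%02d:%02d:00", record$minute_of_day %/% 60L,
                  record$minute_of_day %% 60L)
  fields <- cbind(seq_len(n), dstr, tstr, 1L, 0L, 0L, 0L, 0L, 0L,
                  record$light, record$counts)
  writeLines(apply(fields, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a Trikinetics-style monitor file
#'
#' Parses the dialect written by [write_dam()] (42 tab-separated fields per
#' line). Timestamps must advance by exactly one minute; a missing minute is
#' a gap. Under the default `gap_policy = "flag"` gaps are zero-filled and
#' recorded, but downstream operations refuse the record; `"zero_fill"`
#' accepts the filled record for analysis; `"error"` rejects the file
#' outright. Malformed lines and non-monotone timestamps abort with the
#' offending line number.
#'
#' @param path Monitor file path.
#' @param gap_policy `"flag"` (default), `"error"`, or `"zero_fill"`.
#' @return A `dam_record`: per-minute `counts` (32 columns), `light` flag,
#'   `minute_of_day`, `day` index, per-day `day_phase` (`"LD"`/`"DD"`), and
#'   `gaps` (indices of filled minutes).
#' @export
read_dam <- function(path, gap_policy = c("flag", "error", "zero_fill")) {
  gap_policy <- match.arg(gap_policy)
  lines <- readLines(path)
  if (!length(lines)) stopf("empty monitor file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 42L)
  if (length(bad)) {
    stopf("malformed monitor line %d: expected 42 fields, found %d",
          bad[1], lengths(parts)[bad[1]])
  }
  m <- do.call(rbind, parts)
  dmy <- matrix(unlist(strsplit(m[, 2], " ", fixed = TRUE)), ncol = 3L,
                byrow = TRUE)
  mon <- match(dmy[, 2], MONTHS3)
  if (anyNA(mon)) stopf("unrecognized month name on line %d", which(is.na(mon))[1])
  dates <- as.Date(sprintf("20%02d-%02d-%02d", as.integer(dmy[, 3]), mon,
                           as.integer(dmy[, 1])))
  hm <- matrix(as.integer(unlist(strsplit(m[, 3], ":", fixed = TRUE))),
               ncol = 3L, byrow = TRUE)
  abs_min <- as.numeric(dates - dates[1]) * 1440 + hm[, 1] * 60 + hm[, 2]
  step <- diff(abs_min)
  if (any(step <= 0)) {
    stopf("non-monotone timestamp at line %d", which(step <= 0)[1] + 1L)
  }
  counts <- matrix(as.integer(m[, 11:42]), ncol = 32L)
  light <- as.integer(m[, 10])
  gaps <- integer(0)
  if (any(step > 1)) {
    if (gap_policy == "error") {
      stopf("gap in recording after line %d (%d missing minute(s)); re-read with gap_policy = \"zero_fill\" to proceed",
            which(step > 1)[1], as.integer(sum(step - 1)))
    }
    full <- seq(abs_min[1], abs_min[length(abs_min)])
    idx <- match(full, abs_min)
    gaps <- which(is.na(idx))
    cf <- matrix(0L, length(full), 32L)
    cf[!is.na(idx), ] <- counts[idx[!is.na(idx)], ]
    lf <- integer(length(full))
    lf[!is.na(idx)] <- light[idx[!is.na(idx)]]
    # carry the light flag across gaps
    for (g in gaps) lf[g] <- lf[max(1L, g - 1L)]
    counts <- cf; light <- lf; abs_min <- full
  }
  minute_of_day <- as.integer(abs_min %% 1440)
  day <- as.integer(abs_min %/% 1440) + 1L
  day <- day - min(day) + 1L
  new_dam_record(counts, light, minute_of_day, day, gaps = gaps,
                 gaps_accepted = gap_policy == "zero_fill")
}
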