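check_gaps <- function(record) {
  if (length(record$gaps) && !isTRUE(record$gaps_accepted)) {
    stopf("record contains %d gap minute(s); re-read with gap_policy = \"zero_fill\" to analyse it anyway",
          length(record$gaps))
  }
}

#' Average daily activity profile
#'
#' Mean activity per bin across the selected days: counts are summed within
#' each bin of the day and averaged over days.
#'
#' @param record A `dam_record` from [read_dam()] or [simulate_dam()].
#' @param channel Channel index (1..32).
#' @param days Day indices to average over; defaults to all LD days.
#' @param bin Bin width in minutes; must divide 1440 (default 30).
#' @return An `activity_profile`: list with `values` (mean counts per bin),
#'   `bin`, `channel`, `days`.
#' @export
activity_profile <- function(record, channel, days = NULL, bin = 30L) {
  check_gaps(record)
  if (1440L %% bin != 0L) stopf("'bin' must divide 1440")
  if (is.null(days)) days <- which(record$day_phase == "LD")
  if (!length(days)) stopf("no days selected")
  sel <- record$day %in% days
  x <- record$counts[sel, channel]
  mod <- record$minute_of_day[sel]
  dy <- record$day[sel]
  b <- mod %/% bin + 1L
  per_day <- tapply(x, list(b, dy), sum)
  structure(list(values = unname(rowMeans(per_day)), bin = as.integer(bin),
                 channel = channel, days = days),
            class = "activity_profile")
}

#' Day/night activity ratio
#'
#' Ratio of mean counts per minute during lights-on to mean counts per
#' minute during lights-off, over the selected LD days.
#'
#' @param record A `dam_record`.
#' @param days LD day indices; defaults to all LD days.
#' @param channels Channel indices; defaults to all 32.
#' @return Data frame with `channel`, `day_mean`, `night_mean`, `ratio`, and
#'   `flag` (`"infinite"` when the night mean is 0).
#' @export
day_night_ratio <- function(record, days = NULL, channels = seq_len(32L)) {
  check_gaps(record)
  ld_days <- which(record$day_phase == "LD")
  if (is.null(days)) days <- ld_days
  if (!length(days) || !all(days %in% ld_days)) {
    stopf("need at least one complete LD day (got: %s)",
          paste(days, collapse = ","))
  }
  sel <- record$day %in% days
  light <- record$light[sel] == 1L
  out <- do.call(rbind, lapply(channels, function(ch) {
    x <- record$counts[sel, ch]
    dmean <- mean(x[light]); nmean <- mean(x[!light])
    data.frame(channel = ch, day_mean = dmean, night_mean = nmean,
               ratio = if (nmean == 0) Inf else dmean / nmean,
               flag = if (nmean == 0) "infinite" else "ok",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect the onset of a morning or evening activity component
#'
#' Finds the beginning of an activity component in a binned daily profile.
#' The candidate onset is the first bin in the search window whose activity
#' exceeds the window baseline (lower quartile) by `onset_frac` of the
#' component height and rises above its preceding bin. The run from the
#' candidate to the window maximum is then validated by three criteria:
#' (1) a net increasing trend (last bin greater than the first), (2) at most
#' one third of the run's bins may be outliers, and (3) a bin is an outlier
#' only if it falls below its predecessor by at least 10% of the
#' predecessor's activity (smaller dips are tolerated). If the run fails, no
#' clearly distinguishable component exists and the result is flagged
#' not-detected.
#'
#' @param profile An [activity_profile()] (30-min bins by default).
#' @param component `"evening"` or `"morning"` (sets the default window).
#' @param window ZT-hour range searched, possibly wrapping past midnight;
#'   defaults: evening `c(4, 12)`, morning `c(18, 36)`.
#' @param min_run Minimum run length in bins.
#' @param onset_frac Fraction of the component height above baseline a
#'   candidate bin must reach.
#' @return One-row data frame: `channel`, `component`, `detected`,
#'   `onset_min` (ZT minutes, `NA` when not detected), `run_length`,
#'   `outliers`.
#' @export
detect_onset <- function(profile, component = c("evening", "morning"),
                         window = NULL, min_run = 3L, onset_frac = 0.1) {
  component <- match.arg(component)
  if (is.null(window)) {
    window <- if (component == "evening") c(4, 12) else c(18, 36)
  }
  if (window[2] <= window[1]) stopf("empty search window")
  p <- profile$values
  nb <- length(p)
  bph <- 60 / profile$bin                    # bins per hour
  idx0 <- seq(floor(window[1] * bph), ceiling(window[2] * bph) - 1L)
  win <- (idx0 %% nb) + 1L                   # wrap past midnight
  pw <- p[win]
  pkpos <- which.max(pw)
  base <- unname(quantile(pw, 0.25))
  thr <- base + onset_frac * (pw[pkpos] - base)
  cand <- NA_integer_
  for (i in seq_len(pkpos)) {
    prev <- p[((win[i] - 2L) %% nb) + 1L]    # bin before, wrapped
    if (pw[i] > thr && pw[i] > prev) { cand <- i; break }
  }
  not_detected <- function(run_length = NA_integer_, outliers = NA_integer_) {
    data.frame(channel = profile$channel, component = component,
               detected = FALSE, onset_min = NA_real_,
               run_length = run_length, outliers = outliers,
               stringsAsFactors = FALSE)
  }
  if (is.na(cand) || pkpos - cand + 1L < min_run) {
    return(not_detected(if (is.na(cand)) NA_integer_ else pkpos - cand + 1L))
  }
  run <- pw[cand:pkpos]
  L <- length(run)
  d <- diff(run)
  outliers <- sum(d < 0 & (-d) >= 0.10 * run[-L])
  if (!(run[L] > run[1]) || outliers > floor(L / 3)) {
    return(not_detected(L, outliers))
  }
  data.frame(channel = profile$channel, component = component,
             detected = TRUE,
             onset_min = ((win[cand] - 1L) * profile$bin) %% 1440,
             run_length = L, outliers = outliers, stringsAsFactors = FALSE)
}

#' Free-running period and rhythmicity index from constant darkness
#'
#' Computes the normalized autocorrelation of the binned DD activity trace.
#' The period estimate is the lag of the highest autocorrelation peak within
#' `period_range`; the rhythmicity index (RI) is the height of the third
#' autocorrelation peak, i.e. the peak nearest twice the estimated period
#' (counting the lag-0 peak as the first). A channel is called rhythmic when
#' a period peak exists and RI reaches `ri_threshold`.
#'
#' @param record A `dam_record`.
#' @param channel Channel index.
#' @param days DD day indices; defaults to all DD days (at least 3
#'   required).
#' @param bin Bin width in minutes.
#' @param period_range Lag range (hours) searched for the period peak.
#' @param ri_threshold RI above which a channel is called rhythmic.
#' @return One-row data frame: `channel`, `period_h`, `ri`, `rhythmic`.
#' @export
estimate_period <- function(record, channel, days = NULL, bin = 30L,
                            period_range = c(14, 34), ri_threshold = 0.25) {
  check_gaps(record)
  if (is.null(days)) days <- which(record$day_phase == "DD")
  if (length(days) < 3L) stopf("need at least 3 DD days")
  sel <- record$day %in% days
  x <- record$counts[sel, channel]
  b <- (seq_along(x) - 1L) %/% bin
  trace <- as.numeric(tapply(x, b, sum))
  bph <- 60 / bin
  lag_max <- ceiling((2 * period_range[2] + 2) * bph)
  if (length(trace) <= 2 * period_range[2] * bph) {
    stopf("trace too short: need more than 2 x %g h of data", period_range[2])
  }
  lag_max <- min(lag_max, length(trace) - 1L)
  a <- as.numeric(acf(trace, lag.max = lag_max, plot = FALSE)$acf)
  lags_h <- (seq_along(a) - 1L) / bph
  # the biased (1/n) autocorrelation tapers with lag and drags peak
  # locations to shorter lags; locate peaks on the unbiased estimate but
  # keep peak heights (RI) on the conventional scale
  nb <- length(trace)
  a_unb <- a * nb / (nb - (seq_along(a) - 1L))
  is_peak <- c(FALSE, diff(a_unb) >= 0) & c(diff(a_unb) <= 0, FALSE)
  cand <- which(is_peak & lags_h >= period_range[1] & lags_h <= period_range[2])
  if (!length(cand)) {
    return(data.frame(channel = channel, period_h = NA_real_, ri = NA_real_,
                      rhythmic = FALSE))
  }
  pk <- cand[which.max(a_unb[cand])]
  period_h <- lags_h[pk]
  ri_win <- which(abs(lags_h - 2 * period_h) <= 2)
  ri_peaks <- intersect(which(is_peak), ri_win)
  ri <- if (length(ri_peaks)) max(a[ri_peaks]) else max(a[ri_win])
  data.frame(channel = channel, period_h = period_h, ri = ri,
             rhythmic = ri >= ri_threshold)
}
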