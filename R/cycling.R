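#' Normalize a timecourse and apply the zero filter
#'
#' Reproduces the published preprocessing: each sample is divided by its
#' library size; then, within each replicate series, each gene is divided by
#' its maximum in that replicate, making the series scale-free so that
#' max/min amplitude folds are comparable across genes. Genes with more than
#' `max_zeros` zero counts are discarded, as are genes whose maximum in some
#' replicate is zero (normalization undefined).
#'
#' @param tc A [timecourse_matrix()].
#' @param max_zeros Zero-count budget (default 2: genes with three or more
#'   zeros are dropped).
#' @param zero_rule `"total"` counts zeros across all samples of a gene (the
#'   stricter, simpler reading); `"per_timepoint"` applies the budget within
#'   each timepoint's replicates.
#' @return List with `matrix` (normalized [timecourse_matrix()], library
#'   sizes reset to 1) and `discarded` (character vector of dropped genes).
#' @export
preprocess_timecourse <- function(tc, max_zeros = 2L,
                                  zero_rule = c("total", "per_timepoint")) {
  zero_rule <- match.arg(zero_rule)
  if (any(tc$library_sizes <= 0)) stopf("library sizes must be positive")
  counts <- tc$counts
  nz <- counts == 0
  drop <- if (zero_rule == "total") {
    rowSums(nz) > max_zeros
  } else {
    apply(nz, 1L, function(z)
      any(tapply(z, tc$timepoints, sum) > max_zeros))
  }
  norm <- sweep(counts, 2, tc$library_sizes, `/`)
  for (r in unique(tc$replicates)) {
    idx <- which(tc$replicates == r)
    mx <- apply(norm[, idx, drop = FALSE], 1L, max)
    drop <- drop | mx == 0
    norm[, idx] <- norm[, idx, drop = FALSE] / ifelse(mx == 0, NA, mx)
  }
  discarded <- rownames(counts)[drop]
  norm <- norm[!drop, , drop = FALSE]
  out <- timecourse_matrix(norm, tc$timepoints, tc$replicates,
                           library_sizes = rep(1, ncol(norm)))
  list(matrix = out, discarded = discarded)
}

#' Max/min amplitude fold of a normalized series
#'
#' Per-replicate fold = maximum / minimum of the gene's values in that
#' replicate; the combined amplitude is the arithmetic mean of the
#' per-replicate folds (the combination rule is this package's choice).
#' A zero minimum gives an infinite fold.
#'
#' @param values Numeric vector (one gene, all samples).
#' @param replicates Replicate index per value.
#' @return List with `per_replicate` (named folds) and `combined`.
#' @export
amplitude_fold <- function(values, replicates) {
  per <- vapply(split(values, replicates), function(v) {
    if (min(v) < 0) stopf("negative values in series")
    if (min(v) == 0) {
      if (max(v) == 0) NaN else Inf
    } else max(v) / min(v)
  }, numeric(1))
  list(per_replicate = per, combined = mean(per))
}

# exact null pmf of the Jonckheere-Terpstra statistic J (number of
# concordant cross-group pairs) for reference tie-groups of the given sizes,
# by convolution of independent Mann-Whitney U distributions (the
# generating-function factorization of the Gaussian multinomial)
jtk_null_pmf <- function(group_sizes) {
  key <- paste(sort(group_sizes), collapse = ",")
  cached <- .jtk_cache[[key]]
  if (!is.null(cached)) return(cached)
  pmf <- 1
  M <- group_sizes[1]
  for (nb in group_sizes[-1]) {
    u <- dwilcox(0:(M * nb), M, nb)
    acc <- rep(0, length(pmf) + length(u) - 1L)
    for (k in seq_along(u)) {
      if (u[k] > 0) {
        idx <- k:(k + length(pmf) - 1L)
        acc[idx] <- acc[idx] + u[k] * pmf
      }
    }
    pmf <- acc
    M <- M + nb
  }
  .jtk_cache[[key]] <- pmf
  pmf
}

.jtk_cache <- new.env(parent = emptyenv())

# per-phase scaffold reused across genes sharing a timepoint layout:
# pair indices with distinct reference values, pair orientation, tie-group
# sizes, and the exact null when small enough
jtk_scaffold <- function(timepoints, period, phase_step, exact_max_n) {
  if (is.null(phase_step)) phase_step <- min(diff(sort(unique(timepoints))))
  phases <- seq(0, period - phase_step, by = phase_step)
  n <- length(timepoints)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  scaf <- lapply(phases, function(ph) {
    r <- cos(2 * pi * (timepoints - ph) / period)
    sgn <- sign(round(r[pairs[, 2]] - r[pairs[, 1]], 12))
    keep <- sgn != 0
    sizes <- as.integer(table(round(r, 12)))
    list(phase = ph, ii = pairs[keep, 1], jj = pairs[keep, 2],
         sgn = sgn[keep], sizes = sizes, max_j = sum(keep),
         pmf = if (n <= exact_max_n) jtk_null_pmf(sizes) else NULL,
         pattern = paste(rank(r, ties.method = "average"), collapse = ","))
  })
  attr(scaf, "n_patterns") <- length(unique(vapply(scaf, `[[`, "", "pattern")))
  scaf
}

jtk_phase_p <- function(y, sc) {
  S <- sum(sc$sgn * sign(y[sc$jj] - y[sc$ii]))
  J <- (S + sc$max_j) / 2
  if (!is.null(sc$pmf)) {
    idx <- ceiling(J - 1e-9) + 1L
    sum(sc$pmf[idx:length(sc$pmf)])
  } else {
    n <- sum(sc$sizes)
    mu <- sc$max_j / 2
    v <- (n^2 * (2 * n + 3) - sum(sc$sizes^2 * (2 * sc$sizes + 3))) / 72
    stats::pnorm((J - mu - 0.5) / sqrt(v), lower.tail = FALSE)
  }
}

#' JTK rank-concordance test for one series
#'
#' Tests a series against cosine reference waveforms on a phase grid. For
#' each candidate phase, Kendall concordance between the data and the
#' reference is summarized by the Jonckheere-Terpstra statistic over pairs
#' with distinct reference values (replicates enter as repeated observations
#' at their timepoint, creating reference-side ties); a one-sided exact p is
#' read from the generating-function null. The reported p is the minimum
#' over phases, Bonferroni-multiplied by the number of distinct reference
#' rank patterns and capped at 1; the raw (unadjusted) minimum is reported
#' alongside.
#'
#' @param values Numeric series, one value per observation.
#' @param timepoints ZT hours, one per observation (repeats allowed).
#' @param period Period in hours (default 24).
#' @param phase_step Phase-grid step in hours; defaults to the sampling
#'   resolution.
#' @param exact_max_n Use the exact convolution null up to this many
#'   observations; larger series use a normal approximation with continuity
#'   correction.
#' @return List with `p` (phase-adjusted), `p_raw` (minimum one-sided p
#'   before the phase correction), `phase` (best-matching phase, hours; `NA`
#'   for a constant series), and `n_patterns`.
#' @export
jtk_test <- function(values, timepoints, period = 24, phase_step = NULL,
                     exact_max_n = 20L) {
  if (length(values) != length(timepoints)) {
    stopf("'values' and 'timepoints' must have the same length")
  }
  if (length(unique(timepoints)) < 4L) stopf("need at least 4 distinct timepoints")
  scaf <- jtk_scaffold(timepoints, period, phase_step, exact_max_n)
  if (length(unique(values)) == 1L) {
    return(list(p = 1, p_raw = 1, phase = NA_real_,
                n_patterns = attr(scaf, "n_patterns")))
  }
  ps <- vapply(scaf, function(sc) jtk_phase_p(values, sc), numeric(1))
  best <- which.min(ps)
  n_pat <- attr(scaf, "n_patterns")
  list(p = min(1, ps[best] * n_pat), p_raw = ps[best],
       phase = scaf[[best]]$phase, n_patterns = n_pat)
}

#' Detect cycling genes in a timecourse
#'
#' Runs the full published pipeline: [preprocess_timecourse()] (library-size
#' and per-replicate-max normalization plus the zero filter), per-replicate
#' max/min amplitude, the JTK test per gene, and the call rule of
#' [call_cycling()].
#'
#' @param tc A [timecourse_matrix()].
#' @param period,phase_step Passed to [jtk_test()].
#' @param alpha,min_amp,use_raw_p Passed to [call_cycling()].
#' @param max_zeros,zero_rule Passed to [preprocess_timecourse()].
#' @return Data frame with one row per retained gene: `gene`, `p`, `p_raw`,
#'   `phase`, per-replicate amplitudes `amp_rep_<r>`, `amp_combined`,
#'   `cycling`; discarded genes in attribute `discarded`.
#' @export
cycle_detect <- function(tc, period = 24, phase_step = NULL, alpha = 0.05,
                         min_amp = 1.5, use_raw_p = FALSE, max_zeros = 2L,
                         zero_rule = c("total", "per_timepoint")) {
  pre <- preprocess_timecourse(tc, max_zeros = max_zeros,
                               zero_rule = match.arg(zero_rule))
  ntc <- pre$matrix
  scaf <- jtk_scaffold(ntc$timepoints, period, phase_step, exact_max_n = 20L)
  n_pat <- attr(scaf, "n_patterns")
  reps <- sort(unique(ntc$replicates))
  res <- lapply(rownames(ntc$counts), function(g) {
    y <- ntc$counts[g, ]
    amp <- amplitude_fold(y, ntc$replicates)
    if (length(unique(y)) == 1L) {
      p_raw <- 1; p <- 1; phase <- NA_real_
    } else {
      ps <- vapply(scaf, function(sc) jtk_phase_p(y, sc), numeric(1))
      best <- which.min(ps)
      p_raw <- ps[best]
      p <- min(1, p_raw * n_pat)
      phase <- scaf[[best]]$phase
    }
    c(list(gene = g, p = p, p_raw = p_raw, phase = phase),
      setNames(as.list(amp$per_replicate), paste0("amp_rep_", reps)),
      list(amp_combined = amp$combined))
  })
  out <- do.call(rbind, lapply(res, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  out <- call_cycling(out, alpha = alpha, min_amp = min_amp,
                      use_raw_p = use_raw_p)
  attr(out, "discarded") <- pre$discarded
  attr(out, "zero_rule") <- match.arg(zero_rule)
  out
}

#' Apply the cycling call rule
#'
#' A gene is called cycling when its JTK p-value is below `alpha` and its
#' combined max/min amplitude exceeds `min_amp` (defaults are the published
#' thresholds: p < 0.05 and amplitude > 1.5). The phase-adjusted p is used
#' by default; `use_raw_p = TRUE` applies the rule to the unadjusted
#' minimum-phase p instead.
#'
#' @param results Data frame with columns `p`, `p_raw`, `amp_combined` (as
#'   produced by [cycle_detect()]).
#' @param alpha P-value threshold.
#' @param min_amp Amplitude threshold (fold).
#' @param use_raw_p Use `p_raw` instead of `p`.
#' @return `results` with a logical `cycling` column.
#' @export
call_cycling <- function(results, alpha = 0.05, min_amp = 1.5,
                         use_raw_p = FALSE) {
  pcol <- if (use_raw_p) results$p_raw else results$p
  results$cycling <- pcol < alpha & results$amp_combined > min_amp
  results
}
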