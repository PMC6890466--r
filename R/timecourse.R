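#' Gene-by-sample circadian count matrix
#'
#' Container for a timecourse of counts: a genes x samples matrix whose
#' columns are (Zeitgeber time, replicate) pairs, plus per-sample library
#' sizes used for normalization.
#'
#' @param counts Numeric matrix, genes as rows; column names are set to
#'   `ZT<time>_<replicate>`.
#' @param timepoints Numeric vector of ZT hours, one per column.
#' @param replicates Integer vector of replicate indices, one per column.
#' @param library_sizes Positive per-sample sizes; defaults to column sums.
#' @return An object of class `timecourse_matrix`.
#' @export
timecourse_matrix <- function(counts, timepoints, replicates,
                              library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(timepoints) != ncol(counts) || length(replicates) != ncol(counts)) {
    stopf("'timepoints' and 'replicates' must match the number of columns")
  }
  for (r in unique(replicates)) {
    tps <- timepoints[replicates == r]
    if (!identical(sort(unique(timepoints)), sort(tps))) {
      stopf("all replicates must share the same timepoint grid")
    }
  }
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  colnames(counts) <- sprintf("ZT%g_%d", timepoints, replicates)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, timepoints = as.numeric(timepoints),
                 replicates = as.integer(replicates),
                 library_sizes = as.numeric(library_sizes)),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("timecourse_matrix: %d genes, %d timepoints x %d replicates\n",
              nrow(x$counts), length(unique(x$timepoints)),
              length(unique(x$replicates))))
  invisible(x)
}

#' Read / write a timecourse matrix as TSV
#'
#' Genes as rows; columns named `ZT<time>_<replicate>`. Library sizes are not
#' stored in the file and default to column sums on read.
#'
#' @param tc A [timecourse_matrix()].
#' @param path File path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a [timecourse_matrix()].
#' @export
write_timecourse <- function(tc, path) {
  df <- data.frame(gene = rownames(tc$counts), tc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  m <- regmatches(colnames(counts),
                  regexec("^ZT([0-9.]+)_([0-9]+)$", colnames(counts)))
  if (any(lengths(m) != 3L)) stopf("column names must look like 'ZT<time>_<rep>'")
  timecourse_matrix(counts,
                    timepoints = as.numeric(vapply(m, `[`, "", 2L)),
                    replicates = as.integer(vapply(m, `[`, "", 3L)))
}

#' Simulate a circadian timecourse count matrix
#'
#' Cycling genes follow `baseline * (1 + a * cos(2*pi*(t - phase)/period))`
#' with the cosine coefficient `a` set so that the noiseless maximum/minimum
#' fold over the sampled timepoints equals the drawn amplitude; non-cycling
#' genes are flat. Counts are drawn per sample with the chosen noise model
#' after scaling by a per-sample library-size factor.
#'
#' @param n_genes Number of genes.
#' @param frac_cycling Probability that a gene cycles.
#' @param timepoints ZT hours sampled (strictly increasing within one
#'   period).
#' @param n_replicates Replicates per timepoint.
#' @param period Period in hours.
#' @param amplitude_range Range of max/min fold ratios for cycling genes;
#'   lower bound must exceed 1.
#' @param baseline_mean,baseline_sdlog Log-normal distribution of per-gene
#'   baseline counts.
#' @param noise `"nb"` (negative binomial, variance `mu + dispersion*mu^2`),
#'   `"lognormal"`, or `"none"` (exact noiseless means, for construction
#'   checks).
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param sdlog Log-normal noise sd (natural log).
#' @param library_size_range Per-sample relative library-size factors are
#'   drawn uniformly from this range.
#' @param seed Integer seed.
#' @return List with `matrix` (a [timecourse_matrix()]) and `truth` (per-gene
#'   cycling flag, amplitude fold, phase, baseline).
#' @export
simulate_timecourse <- function(n_genes, frac_cycling = 0.2,
                                timepoints = c(3, 7, 11, 15, 19, 23),
                                n_replicates = 2, period = 24,
                                amplitude_range = c(2, 4),
                                baseline_mean = 500, baseline_sdlog = 1,
                                noise = c("nb", "lognormal", "none"),
                                dispersion = 0.1, sdlog = 0.25,
                                library_size_range = c(0.8, 1.2),
                                seed = 1L) {
  noise <- match.arg(noise)
  if (n_genes < 1) stopf("'n_genes' must be >= 1")
  if (frac_cycling < 0 || frac_cycling > 1) stopf("'frac_cycling' must be in [0, 1]")
  if (any(diff(timepoints) <= 0) || diff(range(timepoints)) >= period) {
    stopf("timepoints must be strictly increasing within one period")
  }
  if (amplitude_range[1] <= 1) stopf("amplitude_range lower bound must exceed 1")
  with_seed(seed, {
    tvec <- rep(timepoints, times = n_replicates)
    rvec <- rep(seq_len(n_replicates), each = length(timepoints))
    lib <- runif(length(tvec), library_size_range[1], library_size_range[2])
    cycling <- runif(n_genes) < frac_cycling
    fold <- ifelse(cycling,
                   runif(n_genes, amplitude_range[1], amplitude_range[2]), 1)
    phase <- ifelse(cycling, runif(n_genes, 0, period), NA_real_)
    baseline <- rlnorm(n_genes, log(baseline_mean), baseline_sdlog)
    mu <- matrix(baseline, n_genes, length(tvec))
    for (g in which(cycling)) {
      cvals <- cos(2 * pi * (tvec - phase[g]) / period)
      Mx <- max(cvals); Mn <- min(cvals)
      a <- (fold[g] - 1) / (Mx - fold[g] * Mn)
      if (!is.finite(a) || a <= 0) stopf("amplitude fold %.2f not attainable", fold[g])
      mu[g, ] <- baseline[g] * (1 + a * cvals)
    }
    mu <- sweep(mu, 2, lib, `*`)
    counts <- switch(noise,
      none = mu,
      nb = {
        x <- if (dispersion > 0) {
          rnbinom(length(mu), mu = as.numeric(mu), size = 1 / dispersion)
        } else rpois(length(mu), as.numeric(mu))
        matrix(x, n_genes, length(tvec))
      },
      lognormal = matrix(
        rlnorm(length(mu), log(as.numeric(mu)) - sdlog^2 / 2, sdlog),
        n_genes, length(tvec)))
    dimnames(counts) <- list(sprintf("gene_%04d", seq_len(n_genes)), NULL)
    tc <- timecourse_matrix(counts, tvec, rvec, library_sizes = lib)
    truth <- list(kind = "timecourse",
                  gene = rownames(counts),
                  cycling = cycling, amplitude = fold, phase = phase,
                  baseline = baseline, period = period,
                  seed = as.integer(seed))
    list(matrix = tc, truth = truth)
  })
}
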