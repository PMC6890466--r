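#' Simulate paired IP/input signals with planted enrichment
#'
#' Emulates an AGO1-immunoprecipitate vs input experiment on a common
#' normalized scale: per replicate, log2 input is drawn from a normal
#' distribution and log2 IP follows an affine function of log2 input plus a
#' per-gene enrichment offset (log2 of the planted fold for enriched genes,
#' 0 otherwise) and residual noise.
#'
#' @param n_genes Number of genes.
#' @param n_enriched Number of genes with planted enrichment
#'   (`<= n_genes`).
#' @param enrichment_fold_range Range of planted folds (> 1).
#' @param input_log2_mean,input_log2_sd Log2-scale input signal
#'   distribution.
#' @param alpha,beta Intercept and slope of the log2 IP ~ log2 input
#'   relation.
#' @param residual_noise_sd Residual noise sd in log2 units.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @return List with `table` (data frame `gene`, `replicate`, `input`, `ip`,
#'   linear scale) and `truth` (enriched gene set and folds).
#' @export
simulate_ip_input <- function(n_genes, n_enriched,
                              enrichment_fold_range = c(2, 8),
                              input_log2_mean = 8, input_log2_sd = 2,
                              alpha = 1, beta = 1,
                              residual_noise_sd = 0.3, n_replicates = 2L,
                              seed = 1L) {
  if (n_enriched > n_genes) stopf("'n_enriched' must not exceed 'n_genes'")
  if (n_replicates < 1L) stopf("need at least one replicate")
  if (n_enriched > 0 && enrichment_fold_range[1] <= 1) {
    stopf("enrichment folds must exceed 1")
  }
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    enriched <- sample(genes, n_enriched)
    delta <- setNames(numeric(n_genes), genes)
    folds <- stats::runif(n_enriched, enrichment_fold_range[1],
                          enrichment_fold_range[2])
    delta[enriched] <- log2(folds)
    tab <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      li <- rnorm(n_genes, input_log2_mean, input_log2_sd)
      lip <- alpha + beta * li + delta + rnorm(n_genes, 0, residual_noise_sd)
      data.frame(gene = genes, replicate = r, input = 2^li, ip = 2^lip,
                 stringsAsFactors = FALSE)
    }))
    truth <- list(kind = "ip_input", enriched = sort(enriched),
                  fold = as.list(setNames(folds, enriched)),
                  alpha = alpha, beta = beta,
                  residual_noise_sd = residual_noise_sd,
                  seed = as.integer(seed))
    list(table = tab, truth = truth)
  })
}

#' Per-gene residuals from the IP ~ input linear model
#'
#' Per replicate, ordinary least squares of log2(IP) on log2(input) across
#' genes; the residual (observed minus fitted log2 IP) measures how much
#' more of a transcript is immunoprecipitated than its abundance predicts.
#'
#' @param table Data frame with columns `gene`, `replicate`, `input`, `ip`
#'   (positive, common normalized scale).
#' @param pooled Fit one model across replicates instead of one per
#'   replicate.
#' @return Matrix of residuals (genes x replicates; one column if
#'   `pooled`).
#' @export
fit_residuals <- function(table, pooled = FALSE) {
  stopifnot(all(c("gene", "replicate", "input", "ip") %in% names(table)))
  if (any(table$input <= 0) || any(table$ip <= 0)) {
    stopf("signals must be positive (log-transformable)")
  }
  genes <- unique(table$gene)
  if (length(genes) < 3L) stopf("need at least 3 genes to fit the model")
  reps <- sort(unique(table$replicate))
  for (r in reps) {
    if (!setequal(table$gene[table$replicate == r], genes)) {
      stopf("replicate %s does not cover the same gene set", r)
    }
  }
  one_fit <- function(df) {
    x <- log2(df$input); y <- log2(df$ip)
    if (length(unique(x)) == 1L) stopf("degenerate input: constant signal")
    stats::residuals(lm(y ~ x))
  }
  if (pooled) {
    res <- one_fit(table)
    out <- matrix(NA_real_, length(genes), 1L,
                  dimnames = list(genes, "pooled"))
    # average duplicate gene entries (replicates) after the pooled fit
    agg <- tapply(res, table$gene, mean)
    out[names(agg), 1L] <- agg
    return(out)
  }
  out <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, paste0("rep_", reps)))
  for (k in seq_along(reps)) {
    df <- table[table$replicate == reps[k], ]
    out[df$gene, k] <- one_fit(df)
  }
  out
}

#' Rank genes by AGO1-IP enrichment
#'
#' Averages the per-replicate residuals of [fit_residuals()] per gene and
#' ranks them in decreasing order: rank 1 is the most enriched (a lower
#' ranking value corresponds to stronger RISC association). Ties are broken
#' deterministically by gene id order.
#'
#' @param residuals Residual matrix from [fit_residuals()].
#' @return Data frame sorted by rank: `gene`, `mean_residual`, `rank`.
#' @export
rank_enrichment <- function(residuals) {
  mr <- rowMeans(residuals)
  ord <- order(-mr, rownames(residuals))
  out <- data.frame(gene = rownames(residuals)[ord],
                    mean_residual = unname(mr[ord]),
                    rank = seq_along(mr), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simple IP/input ratio statistic
#'
#' Per-replicate IP/input ratio, combined across replicates by geometric
#' mean (ratios are multiplicative).
#'
#' @param table Data frame as in [fit_residuals()].
#' @return Data frame with `gene`, `ratio`, and `flag` (`"zero_input"` rows
#'   get `NA`).
#' @export
ip_input_ratio <- function(table) {
  stopifnot(all(c("gene", "replicate", "input", "ip") %in% names(table)))
  genes <- unique(table$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    df <- table[table$gene == g, ]
    if (any(df$input == 0)) {
      return(data.frame(gene = g, ratio = NA_real_, flag = "zero_input",
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, ratio = exp(mean(log(df$ip / df$input))),
               flag = "ok", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
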