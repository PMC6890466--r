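#' Simulate single-end reads from an isoform mixture
#'
#' Emulates a polyA+ RNA-seq library over one gene: each read picks an
#' isoform from the mixture, a start position uniform along that isoform's
#' mature (spliced / 3'-truncated, poly(A)-tailed) sequence, and independent
#' per-base substitution errors. No quality model beyond a constant Phred
#' score is used; junction counting needs only sequence identity.
#'
#' @param catalog A [junction_catalog()].
#' @param mixture Named numeric vector of isoform proportions; must sum to 1
#'   (within 1e-9) over isoforms present in the catalog.
#' @param n_reads Number of reads.
#' @param read_len Read length in bases; must not exceed the shortest mature
#'   isoform sequence.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   output.
#' @return List with `reads` (named character vector), `truth` (the truth
#'   bundle: mixture, per-isoform read counts, read origins, parameters).
#' @export
simulate_isoform_reads <- function(catalog, mixture, n_reads,
                                   read_len = 100L, error_rate = 0.001,
                                   seed = 1L) {
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    stopf("'mixture' must be a named vector of isoform proportions")
  }
  unknown <- setdiff(names(mixture), names(catalog$isoforms))
  if (length(unknown)) stopf("unknown isoform '%s' in mixture", unknown[1])
  if (abs(sum(mixture) - 1) > 1e-9) stopf("mixture proportions must sum to 1")
  if (any(mixture < 0)) stopf("mixture proportions must be non-negative")
  if (!is_count(n_reads) || n_reads < 1) stopf("'n_reads' must be a positive count")
  mat <- vapply(names(mixture), function(id) mature_sequence(catalog, id),
                character(1))
  lens <- nchar(mat)
  if (read_len > min(lens)) {
    stopf("read_len (%d) exceeds the shortest mature isoform ('%s', %d nt)",
          read_len, names(which.min(lens)), min(lens))
  }
  with_seed(seed, {
    origin <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
    starts <- vapply(origin, function(id)
      sample.int(lens[[id]] - read_len + 1L, 1L), integer(1))
    reads <- substr(mat[origin], starts, starts + read_len - 1L)
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_len, error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(read_len, n_err[i])
        ch <- strsplit(reads[i], "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    names(reads) <- sprintf("read_%06d %s:%d", seq_len(n_reads), origin, starts)
    truth <- list(
      kind = "isoform_reads",
      mixture = as.list(mixture),
      per_isoform_counts = as.list(table(factor(origin, levels = names(mixture)))),
      read_origin = unname(origin),
      read_start = unname(starts),
      n_reads = n_reads, read_len = read_len,
      error_rate = error_rate, seed = as.integer(seed))
    list(reads = reads, truth = truth)
  })
}

#' Write reads as FASTQ (constant Phred-33 quality)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(unname(reads))
  names(dna) <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(unname(reads))))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a truth bundle as JSON
#'
#' Every simulator returns a `truth` list recording the planted ground truth
#' (mixtures, cycling flags, onsets, enriched genes, ...); this serializes it
#' alongside the simulated data for downstream recovery tests.
#'
#' @param truth Truth list from a simulator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_bundle <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
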