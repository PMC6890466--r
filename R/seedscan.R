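#' Canonical miRNA seed-match sites in a UTR
#'
#' Scans a UTR (5'->3') for matches to the reverse complement of the miRNA
#' seed (positions 2-8 counted from the miRNA 5' end) and classifies each
#' site by the canonical hierarchy:
#'
#' * `8mer`: reverse complement of positions 2-8 followed by an `A` opposite
#'   miRNA position 1;
#' * `7mer-m8`: reverse complement of positions 2-8;
#' * `7mer-A1`: reverse complement of positions 2-7 followed by an `A`;
#' * `6mer`: reverse complement of positions 2-7 alone.
#'
#' Site types are mutually exclusive at a position (the longest match wins);
#' overlapping sites are resolved longest-first, then leftmost. T and U are
#' interchangeable in both inputs.
#'
#' @param utr UTR sequence (DNA or RNA alphabet).
#' @param mirna Mature miRNA sequence, 5'->3', at least 8 nt.
#' @param utr_id,mirna_id Identifiers used in the output.
#' @return Data frame with `utr_id`, `mirna_id`, `type`, `start` (0-based
#'   position of the site in the UTR), `match` (the matched substring, DNA
#'   alphabet); zero rows when there is no site.
#' @export
seed_sites <- function(utr, mirna, utr_id = "utr", mirna_id = "mirna") {
  utr <- normalize_dna(utr, "utr")
  mirna <- normalize_dna(mirna, "mirna")
  if (nchar(mirna) < 8L) stopf("miRNA must be at least 8 nt")
  core6 <- revcomp(substr(mirna, 2L, 7L))
  m8c <- revcomp(substr(mirna, 8L, 8L))
  empty <- data.frame(utr_id = character(0), mirna_id = character(0),
                      type = character(0), start = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  # all (overlapping) core matches
  starts <- integer(0); from <- 1L
  repeat {
    hit <- regexpr(core6, substr(utr, from, nchar(utr)), fixed = TRUE)
    if (hit < 0L) break
    starts <- c(starts, from + hit - 1L)       # 1-based core start
    from <- from + hit
  }
  if (!length(starts)) return(empty)
  hits <- do.call(rbind, lapply(starts, function(s) {
    has_m8 <- s > 1L && substr(utr, s - 1L, s - 1L) == m8c
    has_a1 <- substr(utr, s + 6L, s + 6L) == "A"   # "" when past the end
    if (has_m8 && has_a1) {
      data.frame(type = "8mer", start = s - 2L, len = 8L)
    } else if (has_m8) {
      data.frame(type = "7mer-m8", start = s - 2L, len = 7L)
    } else if (has_a1) {
      data.frame(type = "7mer-A1", start = s - 1L, len = 7L)
    } else {
      data.frame(type = "6mer", start = s - 1L, len = 6L)
    }
  }))
  # longest-first, then leftmost, greedy non-overlap
  hits <- hits[order(-hits$len, hits$start), , drop = FALSE]
  taken <- rep(FALSE, nchar(utr))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- (hits$start[i] + 1L):(hits$start[i] + hits$len[i])
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  data.frame(utr_id = utr_id, mirna_id = mirna_id, type = hits$type,
             start = hits$start,
             match = substring(utr, hits$start + 1L, hits$start + hits$len),
             stringsAsFactors = FALSE)
}

#' Seed-site count table over UTR and miRNA sets
#'
#' @param utrs Named character vector (or `DNAStringSet`) of UTR sequences.
#' @param mirnas Named character vector (or `RNAStringSet`) of mature miRNA
#'   sequences.
#' @return Data frame with one row per UTR x miRNA pair: per-type counts
#'   (`n_8mer`, `n_7mer_m8`, `n_7mer_A1`, `n_6mer`) and `total`.
#' @export
site_count_table <- function(utrs, mirnas) {
  if (methods::is(utrs, "XStringSet")) utrs <- as.character(utrs)
  if (methods::is(mirnas, "XStringSet")) mirnas <- as.character(mirnas)
  if (!length(utrs) || !length(mirnas)) stopf("need non-empty UTR and miRNA sets")
  if (is.null(names(utrs)) || is.null(names(mirnas))) {
    stopf("UTRs and miRNAs must be named")
  }
  if (anyDuplicated(names(utrs))) stopf("duplicate UTR ids")
  if (anyDuplicated(names(mirnas))) stopf("duplicate miRNA ids")
  types <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  grid <- expand.grid(utr_id = names(utrs), mirna_id = names(mirnas),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnt <- t(mapply(function(u, m) {
    hits <- seed_sites(utrs[[u]], mirnas[[m]], u, m)
    tabulate(factor(hits$type, levels = types), nbins = length(types))
  }, grid$utr_id, grid$mirna_id))
  colnames(cnt) <- c("n_8mer", "n_7mer_m8", "n_7mer_A1", "n_6mer")
  out <- cbind(grid, as.data.frame(cnt))
  out$total <- rowSums(cnt)
  rownames(out) <- NULL
  out
}
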