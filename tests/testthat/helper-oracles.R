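# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or closed form, never by calling the code paths
# they check.

# brute-force junction counting: try every alignment of every probe against
# every read, requiring >= min_overhang matched bases on each side of the
# probe's central boundary and an exact match over the full overlap
naive_count_oracle <- function(reads, probes, min_overhang = 8L) {
  flank <- attr(probes, "flank")
  counts <- integer(nrow(probes))
  for (j in seq_len(nrow(probes))) {
    pseq <- probes$sequence[j]
    plen <- nchar(pseq)
    for (rd in reads) {
      rlen <- nchar(rd)
      hit <- FALSE
      # r0: read position aligned with probe position 1 (may be <= 0)
      for (r0 in (2L - plen):rlen) {
        p_from <- max(1L, 2L - r0)
        p_to <- min(plen, rlen - r0 + 1L)
        if (p_to < p_from) next
        left <- flank - p_from + 1L     # matched bases left of the boundary
        right <- p_to - flank           # matched bases right of the boundary
        if (left < min_overhang || right < min_overhang) next
        if (substr(rd, r0 + p_from - 1L, r0 + p_to - 1L) ==
            substr(pseq, p_from, p_to)) { hit <- TRUE; break }
      }
      if (hit) counts[j] <- counts[j] + 1L
    }
  }
  counts
}

# exact JT null pmf by enumerating all permutations (small n only)
enum_jt_null <- function(ref_values) {
  n <- length(ref_values)
  stopifnot(n <= 8)
  perms <- gtools_permutations(n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- ref_values[pairs[, 2]] != ref_values[pairs[, 1]]
  ii <- pairs[keep, 1]; jj <- pairs[keep, 2]
  sgn <- sign(ref_values[jj] - ref_values[ii])
  maxj <- sum(keep)
  js <- apply(perms, 1L, function(y)
    (sum(sgn * sign(y[jj] - y[ii])) + maxj) / 2)
  tabulate(js + 1L, nbins = maxj + 1L) / nrow(perms)
}

# all permutations of 1..n (no package dependency)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# Mann-Whitney AUC of scores for recovering a positive set
auc_oracle <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exhaustive window-scan oracle for canonical seed sites: test every window
# of every site length at every UTR position, then resolve overlaps
# longest-first, leftmost
seed_scan_oracle <- function(utr, mirna) {
  utr <- chartr("Uu", "TT", toupper(utr))
  mirna <- chartr("Uu", "TT", toupper(mirna))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  pat <- list(`8mer` = paste0(rc(substr(mirna, 2, 8)), "A"),
              `7mer-m8` = rc(substr(mirna, 2, 8)),
              `7mer-A1` = paste0(rc(substr(mirna, 2, 7)), "A"),
              `6mer` = rc(substr(mirna, 2, 7)))
  cand <- do.call(rbind, lapply(names(pat), function(ty) {
    L <- nchar(pat[[ty]])
    starts <- integer(0)
    if (nchar(utr) >= L) {
      for (s in 1:(nchar(utr) - L + 1L)) {
        if (substr(utr, s, s + L - 1L) == pat[[ty]]) starts <- c(starts, s)
      }
    }
    if (!length(starts)) return(NULL)
    data.frame(type = ty, start = starts - 1L, len = L)
  }))
  if (is.null(cand)) {
    return(data.frame(type = character(0), start = integer(0),
                      len = integer(0)))
  }
  cand <- cand[order(-cand$len, cand$start), , drop = FALSE]
  taken <- rep(FALSE, nchar(utr))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):(cand$start[i] + cand$len[i])
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# deterministic random sequence helper for fixtures
random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# minimal two-isoform catalog: one intron, spliced vs retained
two_isoform_catalog <- function(seed = 42L, exon = 200L, intron = 120L) {
  ref <- random_dna(2L * exon + intron, seed)
  spliced <- isoform_model("iso-spliced",
                           list(c(0L, exon), c(exon + intron, 2L * exon + intron)))
  retained <- isoform_model("iso-retained", list(c(0L, 2L * exon + intron)))
  junction_catalog(ref, list(spliced, retained),
                   introns = list(I1 = c(exon, exon + intron)))
}

# two-isoform catalog with six introns: isoform A splices all of them,
# isoform B retains all of them -> exactly 12 diagnostic probes
twelve_probe_catalog <- function(seed = 77L, exon = 150L, intron = 100L) {
  n_ex <- 7L
  ref <- random_dna(n_ex * exon + (n_ex - 1L) * intron, seed)
  pos <- 0L
  blocks_a <- list(); introns <- list()
  for (i in seq_len(n_ex)) {
    blocks_a[[i]] <- c(pos, pos + exon)
    pos <- pos + exon
    if (i < n_ex) {
      introns[[paste0("I", i)]] <- c(pos, pos + intron)
      pos <- pos + intron
    }
  }
  a <- isoform_model("iso-A", blocks_a)
  b <- isoform_model("iso-B", list(c(0L, pos)))
  junction_catalog(ref, list(a, b), introns)
}
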