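# coerce reads input (character vector, DNAStringSet, or FASTA/FASTQ path)
# to a plain character vector
as_read_vector <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  if (!is.character(reads)) stopf("'reads' must be sequences or a FASTA/FASTQ path")
  reads
}

#' Count junction-supporting reads
#'
#' A read supports a probe when it spans the probe's diagnostic boundary with
#' at least `min_overhang` matching bases on each side: the probe's central
#' `2 * min_overhang` core must occur in the read, and the read must agree
#' with the probe over their whole overlap (up to `max_mismatch` mismatches
#' in the flanks outside the core). Each read is counted at most once per
#' probe.
#'
#' @param reads Character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA/FASTQ file path.
#' @param probes A [build_junction_probes()] table.
#' @param min_overhang Minimum bases on each side of the boundary
#'   (`<= flank`). Default 8.
#' @param revcomp_scan Also scan the reverse complement of each probe
#'   (antisense reads). Default `FALSE`: reads are assumed sense.
#' @param max_mismatch Hamming tolerance (0 or 1) applied to the overlap
#'   outside the exact-matched core.
#' @return Data frame of class `junction_counts` with columns `probe_id`,
#'   `kind`, `intron`, `count`; total read number kept as attribute
#'   `total_reads`.
#' @export
count_junction_reads <- function(reads, probes, min_overhang = 8L,
                                 revcomp_scan = FALSE, max_mismatch = 0L) {
  if (!nrow(probes)) stopf("empty probe list")
  flank <- attr(probes, "flank")
  min_overhang <- as.integer(min_overhang)
  if (min_overhang < 1L || min_overhang > flank) {
    stopf("'min_overhang' must be in 1..flank (%d)", flank)
  }
  if (!max_mismatch %in% c(0L, 1L)) stopf("'max_mismatch' must be 0 or 1")
  reads <- as_read_vector(reads)

  counts <- integer(nrow(probes))
  for (j in seq_len(nrow(probes))) {
    pseq <- probes$sequence[j]
    supported <- probe_support(reads, pseq, flank, min_overhang, max_mismatch)
    if (revcomp_scan) {
      supported <- supported |
        probe_support(reads, revcomp(pseq), flank, min_overhang, max_mismatch)
    }
    counts[j] <- sum(supported)
  }
  out <- data.frame(probe_id = probes$probe_id, kind = probes$kind,
                    intron = probes$intron, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- length(reads)
  class(out) <- c("junction_counts", class(out))
  out
}

# logical vector: does each read support this probe sequence?
probe_support <- function(reads, pseq, flank, min_overhang, max_mismatch) {
  plen <- nchar(pseq)
  core_start <- flank - min_overhang + 1L
  core <- substr(pseq, core_start, flank + min_overhang)
  hits <- gregexpr(core, reads, fixed = TRUE)
  out <- logical(length(reads))
  cand <- which(vapply(hits, function(h) h[1] > 0L, logical(1)))
  for (i in cand) {
    rlen <- nchar(reads[i])
    for (s in as.integer(hits[[i]])) {
      # probe position core_start aligns with read position s
      off <- s - core_start               # read pos = probe pos + off
      p_from <- max(1L, 1L - off)
      p_to <- min(plen, rlen - off)
      rseg <- substr(reads[i], p_from + off, p_to + off)
      pseg <- substr(pseq, p_from, p_to)
      ok <- if (max_mismatch == 0L) {
        rseg == pseg
      } else {
        sum(strsplit(rseg, "")[[1]] != strsplit(pseg, "")[[1]]) <= max_mismatch
      }
      if (ok) { out[i] <- TRUE; break }
    }
  }
  out
}

#' Relative isoform proportions from junction counts
#'
#' Implements the "relative number of isoform-specific junction reads"
#' statistic. Two estimation schemes are available:
#'
#' * `"unique"`: each isoform's support is the mean count over its uniquely
#'   diagnostic probes, comparable across isoforms with unequal numbers of
#'   diagnostic junctions; proportions are supports normalized to sum 1.
#' * `"resolve"`: when some isoform (like the full-length one, whose every
#'   junction is shared) has no uniquely diagnostic probe, the small
#'   non-negative linear system mapping isoform abundances to probe-set
#'   counts is solved by non-negative least squares over all probes.
#'
#' When `catalog` and `read_len` are supplied, supports are corrected for
#' mature-transcript length: with reads sampled uniformly along an isoform of
#' mature length `L`, the chance that a read spans a given boundary with
#' `min_overhang` bases on each side is `(read_len - 2*min_overhang + 1) /
#' (L - read_len + 1)`, so junction counts under-represent long isoforms.
#'
#' @param counts A [count_junction_reads()] table.
#' @param probes The matching [build_junction_probes()] table.
#' @param method `"auto"` (unique if every isoform has a unique probe, else
#'   resolve), `"unique"`, or `"resolve"`.
#' @param catalog,read_len Optional [junction_catalog()] and read length for
#'   the length correction.
#' @param min_overhang Overhang used when counting (for the length
#'   correction).
#' @return Data frame with columns `isoform`, `support`, `proportion` and
#'   attributes `method` and `defined` (`FALSE` when all probe counts are 0,
#'   in which case proportions are `NA`).
#' @export
isoform_proportions <- function(counts, probes,
                                method = c("auto", "unique", "resolve"),
                                catalog = NULL, read_len = NULL,
                                min_overhang = 8L) {
  method <- match.arg(method)
  stopifnot(nrow(counts) == nrow(probes),
            all(counts$probe_id == probes$probe_id))
  iso <- sort(unique(unlist(probes$diagnostic_for)))
  weights <- setNames(rep(1, length(iso)), iso)
  if (!is.null(catalog) && !is.null(read_len)) {
    lens <- vapply(iso, function(id) nchar(mature_sequence(catalog, id)),
                   numeric(1))
    weights <- (read_len - 2 * min_overhang + 1) / (lens - read_len + 1)
    if (any(weights <= 0)) stopf("read_len too long for the length correction")
  }
  uniq_idx <- lapply(iso, function(id) {
    which(vapply(probes$diagnostic_for, function(s)
      length(s) == 1L && s == id, logical(1)))
  })
  names(uniq_idx) <- iso
  have_unique <- all(lengths(uniq_idx) > 0L)
  if (method == "unique" && !have_unique) {
    stopf("isoform '%s' has no uniquely diagnostic probe; use method = \"resolve\"",
          iso[which(lengths(uniq_idx) == 0L)[1]])
  }
  use_unique <- method == "unique" || (method == "auto" && have_unique)

  if (use_unique) {
    support <- vapply(iso, function(id)
      mean(counts$count[uniq_idx[[id]]]), numeric(1))
    est <- support / weights
    method_used <- "unique"
  } else {
    A <- vapply(iso, function(id)
      vapply(probes$diagnostic_for, function(s) (id %in% s) * weights[id],
             numeric(1)),
      numeric(nrow(probes)))
    fit <- pracma::lsqnonneg(A, as.numeric(counts$count))
    est <- setNames(fit$x, iso)
    support <- est * weights     # expected per-boundary read support
    method_used <- "resolve"
  }
  defined <- sum(counts$count) > 0
  prop <- if (defined) est / sum(est) else rep(NA_real_, length(iso))
  out <- data.frame(isoform = iso, support = unname(support),
                    proportion = unname(prop), stringsAsFactors = FALSE)
  attr(out, "method") <- method_used
  attr(out, "defined") <- defined
  out
}

#' Unspliced/spliced ratio for one intron
#'
#' Ratio of the retained-boundary probe count to the spliced-junction probe
#' count of an intron, the minigene splicing-efficiency statistic.
#'
#' @param counts A [count_junction_reads()] table (its `intron` and `kind`
#'   columns identify the probe pair).
#' @param intron_id Intron identifier.
#' @return One-row data frame with `intron`, `unspliced`, `spliced`, `ratio`,
#'   and `flag` (`"ok"`, `"infinite"` when spliced = 0 < unspliced,
#'   `"undefined"` when both are 0).
#' @export
spliced_unspliced_ratio <- function(counts, intron_id) {
  sel <- !is.na(counts$intron) & counts$intron == intron_id
  sp <- counts$count[sel & counts$kind == "spliced"]
  un <- counts$count[sel & counts$kind == "retained"]
  if (length(sp) != 1L || length(un) != 1L) {
    stopf("no spliced/retained probe pair for intron '%s'", intron_id)
  }
  flag <- if (sp == 0 && un == 0) "undefined" else if (sp == 0) "infinite" else "ok"
  ratio <- switch(flag, undefined = NaN, infinite = Inf, ok = un / sp)
  data.frame(intron = intron_id, unspliced = un, spliced = sp,
             ratio = ratio, flag = flag, stringsAsFactors = FALSE)
}
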