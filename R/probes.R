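# count (possibly overlapping) occurrences of needle in haystack
count_occurrences <- function(needle, haystack) {
  n <- 0L; from <- 1L
  repeat {
    hit <- regexpr(needle, substr(haystack, from, nchar(haystack)), fixed = TRUE)
    if (hit < 0L) return(n)
    n <- n + 1L
    from <- from + hit  # advance one base past the match start: overlap-safe
  }
}

#' Build isoform-diagnostic junction probes
#'
#' For every intron in the catalog, emits the spliced exon-exon junction
#' probe (the sequence formed when the intron is removed) and the retained
#' exon-intron boundary probe (the contiguous genomic sequence across the
#' donor site); for every isoform with an intra-intronic cleavage site, emits
#' a terminal probe made of the last genomic bases followed by poly(A)
#' context. Each probe's `diagnostic_for` set is determined empirically: the
#' isoforms whose mature sequence contains the probe exactly once. A probe
#' occurring more than once in any mature sequence is ambiguous and aborts
#' the build. Probes present in every isoform (constitutive junctions) are
#' retained as controls with the full diagnostic set.
#'
#' @param catalog A [junction_catalog()].
#' @param flank Bases on each side of the diagnostic boundary (probe length
#'   is `2 * flank`). Default 20: long enough to be unique in a gene-scale
#'   reference, short enough to sit inside a read.
#' @return A data frame of class `junction_probes` with columns `probe_id`,
#'   `kind` (`spliced`/`retained`/`terminal`), `intron`, `sequence`,
#'   `constitutive`, and list-column `diagnostic_for`; the flank is stored as
#'   an attribute.
#' @export
build_junction_probes <- function(catalog, flank = 20L) {
  flank <- as.integer(flank)
  if (flank < 8L) stopf("'flank' must be at least 8")
  ref <- catalog$reference
  iso_ids <- names(catalog$isoforms)
  mat <- vapply(iso_ids, function(id) mature_sequence(catalog, id), character(1))

  # exon segment bordering each intron (gene coordinates)
  ibounds <- do.call(rbind, catalog$introns)
  rows <- list()
  add <- function(probe_id, kind, intron, sequence) {
    rows[[length(rows) + 1L]] <<- data.frame(
      probe_id = probe_id, kind = kind, intron = intron,
      sequence = sequence, stringsAsFactors = FALSE)
  }
  for (iid in names(catalog$introns)) {
    iv <- catalog$introns[[iid]]
    d <- iv[1]; a <- iv[2]
    up <- d - max(c(0L, ibounds[ibounds[, 2] <= d, 2]))
    dn <- min(c(nchar(ref), ibounds[ibounds[, 1] >= a, 1])) - a
    if (flank > up || flank > dn) {
      stopf("flank %d exceeds an exon segment adjacent to intron '%s'", flank, iid)
    }
    if (flank > (a - d)) {
      stopf("flank %d exceeds the length of intron '%s'", flank, iid)
    }
    add(paste0(iid, "_spliced"), "spliced", iid,
        paste0(substr(ref, d - flank + 1L, d), substr(ref, a + 1L, a + flank)))
    add(paste0(iid, "_retained"), "retained", iid,
        substr(ref, d - flank + 1L, d + flank))
  }
  for (m in catalog$isoforms) {
    if (is.null(m$terminal_position)) next
    tp <- m$terminal_position
    if (catalog$polya_tail < flank) {
      stopf("poly(A) tail (%d) shorter than flank (%d): cannot build terminal probe",
            catalog$polya_tail, flank)
    }
    host <- names(catalog$introns)[vapply(catalog$introns, function(iv)
      tp > iv[1] && tp < iv[2], logical(1))]
    add(paste0("term_", m$id), "terminal",
        if (length(host)) host[1] else NA_character_,
        paste0(substr(ref, tp - flank + 1L, tp), strrep("A", flank)))
  }
  probes <- do.call(rbind, rows)

  occ <- vapply(probes$sequence, function(s)
    vapply(mat, function(ms) count_occurrences(s, ms), integer(1)),
    integer(length(iso_ids)))
  if (length(iso_ids) == 1L) occ <- matrix(occ, nrow = 1L,
                                           dimnames = list(iso_ids, NULL))
  multi <- which(occ > 1L, arr.ind = TRUE)
  if (nrow(multi)) {
    stopf("ambiguous probe '%s': sequence occurs %d times in isoform '%s'",
          probes$probe_id[multi[1, 2]], occ[multi[1, 1], multi[1, 2]],
          iso_ids[multi[1, 1]])
  }
  diag_sets <- lapply(seq_len(nrow(probes)), function(j) iso_ids[occ[, j] == 1L])
  keep <- lengths(diag_sets) > 0L
  probes <- probes[keep, , drop = FALSE]
  probes$constitutive <- vapply(diag_sets[keep], function(s)
    length(s) == length(iso_ids), logical(1))
  probes$diagnostic_for <- I(diag_sets[keep])
  rownames(probes) <- NULL
  attr(probes, "flank") <- flank
  class(probes) <- c("junction_probes", class(probes))
  probes
}
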