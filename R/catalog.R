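#' Define a transcript isoform model
#'
#' An isoform is described by its ordered exon blocks on a shared reference
#' sequence, using 0-based half-open coordinates. Intron-retention isoforms
#' simply carry a block that spans the retained intron; isoforms produced by
#' intra-intronic cleavage and polyadenylation additionally carry a
#' `terminal_position`, the coordinate of their 3' end inside the last block,
#' after which the mature transcript continues as a poly(A) tail.
#'
#' @param id Isoform identifier.
#' @param blocks Two-column matrix (or list of length-2 vectors) of 0-based
#'   half-open `[start, end)` intervals on the reference, in transcript order.
#' @param terminal_position Optional 0-based coordinate of the 3' cleavage
#'   site; must lie strictly inside the final block.
#' @return An object of class `isoform_model`.
#' @export
isoform_model <- function(id, blocks, terminal_position = NULL) {
  if (is.list(blocks)) blocks <- do.call(rbind, blocks)
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (any(blocks[, 2] <= blocks[, 1])) stopf("isoform '%s': empty or reversed block", id)
  if (nrow(blocks) > 1L) {
    if (any(blocks[-1L, 1] < blocks[-nrow(blocks), 2])) {
      stopf("isoform '%s': blocks must be ordered and non-overlapping", id)
    }
  }
  if (!is.null(terminal_position)) {
    terminal_position <- as.integer(terminal_position)
    last <- blocks[nrow(blocks), ]
    if (terminal_position <= last[1] || terminal_position >= last[2]) {
      stopf("isoform '%s': terminal_position must lie inside the last block", id)
    }
  }
  structure(list(id = as.character(id), blocks = blocks,
                 terminal_position = terminal_position),
            class = "isoform_model")
}

#' Build a junction catalog
#'
#' Bundles a reference sequence, a set of [isoform_model()]s, and the intron
#' coordinates whose splicing status distinguishes the isoforms. The catalog
#' is the unit consumed by [build_junction_probes()] and
#' [simulate_isoform_reads()].
#'
#' @param reference Reference (pre-mRNA) sequence, A/C/G/T.
#' @param isoforms List of [isoform_model()] objects.
#' @param introns Named list of 0-based half-open `c(start, end)` intron
#'   intervals on the reference; the start is the donor site and the end the
#'   acceptor site.
#' @param polya_tail Length of the poly(A) tail appended to the mature
#'   sequence of terminal (intra-intronic cleavage) isoforms. Keep it at
#'   least `read_len - flank` for the reads you plan to simulate, so that
#'   reads can span the cleavage boundary from every offset and terminal
#'   probes are not depleted by the transcript edge.
#' @return An object of class `junction_catalog`.
#' @export
junction_catalog <- function(reference, isoforms, introns, polya_tail = 100L) {
  reference <- normalize_dna(reference, "reference")
  if (!length(isoforms)) stopf("catalog needs at least one isoform")
  ids <- vapply(isoforms, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate isoform ids in catalog")
  names(isoforms) <- ids
  for (m in isoforms) {
    if (max(m$blocks[, 2]) > nchar(reference)) {
      stopf("isoform '%s' extends beyond the reference", m$id)
    }
  }
  if (!length(introns) || is.null(names(introns)) || any(!nzchar(names(introns)))) {
    stopf("'introns' must be a non-empty named list of c(start, end)")
  }
  introns <- lapply(introns, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[2] <= iv[1]) stopf("malformed intron interval")
    iv
  })
  structure(list(reference = reference, isoforms = isoforms,
                 introns = introns, polya_tail = as.integer(polya_tail)),
            class = "junction_catalog")
}

#' @export
print.junction_catalog <- function(x, ...) {
  cat(sprintf("junction_catalog: %d isoforms, %d introns, reference %d nt\n",
              length(x$isoforms), length(x$introns), nchar(x$reference)))
  for (m in x$isoforms) {
    cat(sprintf("  %-8s %d block(s), mature %d nt%s\n", m$id, nrow(m$blocks),
                nchar(mature_sequence(x, m$id)),
                if (is.null(m$terminal_position)) "" else
                  sprintf(", cleaved at %d + poly(A)", m$terminal_position)))
  }
  invisible(x)
}

#' Mature transcript sequence of a catalog isoform
#'
#' Concatenates the isoform's exon blocks; for terminal isoforms the sequence
#' is cut at `terminal_position` and extended by the catalog's poly(A) tail.
#'
#' @param catalog A [junction_catalog()].
#' @param isoform_id Isoform identifier.
#' @return Character string, the mature (spliced / 3'-truncated) sequence.
#' @export
mature_sequence <- function(catalog, isoform_id) {
  m <- catalog$isoforms[[isoform_id]]
  if (is.null(m)) stopf("unknown isoform '%s'", isoform_id)
  blocks <- m$blocks
  if (!is.null(m$terminal_position)) {
    blocks[nrow(blocks), 2] <- m$terminal_position
  }
  seqs <- substring(catalog$reference, blocks[, 1] + 1L, blocks[, 2])
  s <- paste(seqs, collapse = "")
  if (!is.null(m$terminal_position)) {
    s <- paste0(s, strrep("A", catalog$polya_tail))
  }
  s
}

#' Synthetic four-isoform catalog mimicking the tim locus architecture
#'
#' Builds a deterministic synthetic gene (random reference sequence from a
#' fixed internal seed) with five exons and four introns, carrying the same
#' isoform architecture as the temperature-regulated *timeless* transcripts:
#' a full-length isoform (`tim-L`), two intron-retention isoforms
#' (`tim-cold`, retaining the last intron; `tim-M`, retaining the
#' second-to-last), and a short isoform (`tim-sc`) terminated at an
#' intra-intronic cleavage/polyadenylation site. `tim-L` shares every
#' junction with some other isoform and is therefore only diagnosable through
#' the set-resolution scheme of [isoform_proportions()].
#'
#' This catalog is synthetic: coordinates and sequence are invented; only the
#' splicing architecture mirrors the real locus.
#'
#' @return A [junction_catalog()] with isoforms `tim-L`, `tim-cold`, `tim-M`,
#'   `tim-sc` and introns `I1`-`I4` (`I2` hosting the cleavage site).
#' @export
tim_example_catalog <- function() {
  exon_len <- c(300L, 250L, 280L, 260L, 310L)
  intron_len <- c(120L, 150L, 140L, 130L)
  ref <- with_seed(104729L, {
    n <- sum(exon_len) + sum(intron_len)
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  })
  # exon/intron layout
  starts <- integer(5); ends <- integer(5)
  istarts <- integer(4); iends <- integer(4)
  pos <- 0L
  for (i in 1:5) {
    starts[i] <- pos; pos <- pos + exon_len[i]; ends[i] <- pos
    if (i < 5) { istarts[i] <- pos; pos <- pos + intron_len[i]; iends[i] <- pos }
  }
  introns <- Map(function(s, e) c(s, e), istarts, iends)
  names(introns) <- paste0("I", 1:4)
  ex <- function(i) c(starts[i], ends[i])

  tim_L <- isoform_model("tim-L", lapply(1:5, ex))
  tim_cold <- isoform_model("tim-cold",
    list(ex(1), ex(2), ex(3), c(starts[4], ends[5])))      # retains I4
  tim_M <- isoform_model("tim-M",
    list(ex(1), ex(2), c(starts[3], ends[4]), ex(5)))      # retains I3
  tim_sc <- isoform_model("tim-sc",
    list(ex(1), c(starts[2], iends[2])),                   # runs into I2
    terminal_position = istarts[2] + 80L)

  junction_catalog(ref, list(tim_L, tim_cold, tim_M, tim_sc), introns)
}

#' Write / read a junction catalog as JSON
#'
#' @param catalog A [junction_catalog()].
#' @param path File path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the reconstructed [junction_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  obj <- list(
    reference = catalog$reference,
    polya_tail = catalog$polya_tail,
    introns = catalog$introns,
    isoforms = lapply(unname(catalog$isoforms), function(m) {
      list(id = m$id,
           blocks = lapply(seq_len(nrow(m$blocks)),
                           function(i) unname(m$blocks[i, ])),
           terminal_position = m$terminal_position)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path)
  isoforms <- lapply(obj$isoforms, function(m) {
    isoform_model(m$id, lapply(m$blocks, unlist),
                  terminal_position = m$terminal_position)
  })
  junction_catalog(obj$reference, isoforms,
                   lapply(obj$introns, unlist),
                   polya_tail = obj$polya_tail %||% 30L)
}
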