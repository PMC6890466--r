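# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a DNA/RNA character string; returns DNA alphabet
revcomp <- function(x) {
  x <- normalize_dna(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# uppercase, U -> T, validate alphabet
normalize_dna <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGT]", "", x)
  if (nzchar(bad)) {
    stop(sprintf("invalid character(s) '%s' in %s (A/C/G/T/U expected)",
                 substr(bad, 1, 5), what), call. = FALSE)
  }
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic, seed-scoped evaluation (no global RNG state leaks)
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("'seed' must be a single integer")
  }
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
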