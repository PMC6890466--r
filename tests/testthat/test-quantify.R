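make_probe_table <- function(ids, seqs, diag, flank,
                             kind = rep("spliced", length(ids)),
                             intron = rep(NA_character_, length(ids))) {
  df <- data.frame(probe_id = ids, kind = kind, intron = intron,
                   sequence = seqs, constitutive = FALSE,
                   stringsAsFactors = FALSE)
  df$diagnostic_for <- I(diag)
  attr(df, "flank") <- flank
  class(df) <- c("junction_probes", class(df))
  df
}

test_that("reads equal to, containing, or missing a probe count correctly", {
  cat <- two_isoform_catalog()
  probes <- build_junction_probes(cat)
  psp <- probes$sequence[probes$kind == "spliced"]
  reads <- c(psp,                                    # read == probe
             paste0("ACGT", psp, "TTTT"),            # probe inside read
             strrep("A", 60))                        # no probe
  cnt <- count_junction_reads(reads, probes)
  expect_identical(cnt$count[cnt$kind == "spliced"], 2L)
  expect_identical(cnt$count[cnt$kind == "retained"], 0L)
  expect_identical(attr(cnt, "total_reads"), 3L)
  expect_error(count_junction_reads(reads, probes[0, ]), "empty probe")
})

test_that("overhang, mismatch tolerance, and strand flags behave as documented", {
  cat <- two_isoform_catalog()
  probes <- build_junction_probes(cat)
  p <- probes[probes$kind == "spliced", ]
  flank <- attr(probes, "flank")
  core_only <- substr(p$sequence, flank - 7, flank + 8)    # exactly 8+8
  short_side <- substr(p$sequence, flank - 6, flank + 8)   # 7 left bases
  expect_identical(count_junction_reads(core_only, probes)$count[
    probes$probe_id == p$probe_id], 1L)
  expect_identical(count_junction_reads(short_side, probes)$count[
    probes$probe_id == p$probe_id], 0L)

  mut <- p$sequence
  substr(mut, 2, 2) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 2, 2))[1]       # flank mismatch
  expect_identical(count_junction_reads(mut, probes)$count[
    probes$probe_id == p$probe_id], 0L)
  expect_identical(
    count_junction_reads(mut, probes, max_mismatch = 1)$count[
      probes$probe_id == p$probe_id], 1L)

  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", p$sequence), "")[[1]]),
              collapse = "")
  expect_identical(count_junction_reads(rc, probes)$count[
    probes$probe_id == p$probe_id], 0L)
  expect_identical(
    count_junction_reads(rc, probes, revcomp_scan = TRUE)$count[
      probes$probe_id == p$probe_id], 1L)
})

test_that("counting matches the naive alignment-scan oracle exactly", {
  cat <- tim_example_catalog()
  probes <- build_junction_probes(cat)
  mix <- setNames(c(0.4, 0.3, 0.2, 0.1),
                  c("tim-L", "tim-cold", "tim-M", "tim-sc"))
  sim <- simulate_isoform_reads(cat, mix, 300, read_len = 80,
                                error_rate = 0.002, seed = 3)
  cnt <- count_junction_reads(sim$reads, probes)
  expect_identical(cnt$count, naive_count_oracle(sim$reads, probes))
})

test_that("probe diagnostic sets are consistent with single-isoform reads", {
  cat <- tim_example_catalog()
  probes <- build_junction_probes(cat)
  for (id in names(cat$isoforms)) {
    sim <- simulate_isoform_reads(cat, setNames(1, id), 400,
                                  error_rate = 0, seed = 2)
    cnt <- count_junction_reads(sim$reads, probes)
    off_target <- !vapply(probes$diagnostic_for, function(s) id %in% s,
                          logical(1))
    expect_true(all(cnt$count[off_target] == 0L),
                info = paste("off-target counts for", id))
  }
})

test_that("proportions from unique probes follow the mean-support arithmetic", {
  probes <- make_probe_table(paste0("p", 1:4), strrep(c("A", "C", "G", "T"), 16),
                             as.list(paste0("iso", 1:4)), flank = 8)
  cnt <- data.frame(probe_id = probes$probe_id, kind = probes$kind,
                    intron = probes$intron, count = c(100L, 100L, 100L, 100L))
  pr <- isoform_proportions(cnt, probes)
  expect_equal(pr$proportion, rep(0.25, 4))
  cnt$count <- c(300L, 100L, 0L, 0L)
  pr <- isoform_proportions(cnt, probes)
  expect_equal(pr$proportion, c(0.75, 0.25, 0, 0))
  cnt$count <- c(0L, 0L, 0L, 0L)
  pr <- isoform_proportions(cnt, probes)
  expect_true(all(is.na(pr$proportion)))
  expect_false(attr(pr, "defined"))
})

test_that("isoforms without unique probes require and get the set-resolution scheme", {
  cat <- tim_example_catalog()
  probes <- build_junction_probes(cat)
  cnt <- data.frame(probe_id = probes$probe_id, kind = probes$kind,
                    intron = probes$intron, count = 10L)
  expect_error(isoform_proportions(cnt, probes, method = "unique"),
               "tim-L.*resolve")
  pr <- isoform_proportions(cnt, probes)   # auto falls back
  expect_identical(attr(pr, "method"), "resolve")
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)
})

test_that("a known mixture is recovered within 0.02 from 50k reads", {
  cat <- tim_example_catalog()
  probes <- build_junction_probes(cat)
  mix <- setNames(c(0.4, 0.3, 0.2, 0.1),
                  c("tim-L", "tim-cold", "tim-M", "tim-sc"))
  sim <- simulate_isoform_reads(cat, mix, 50000, seed = 1)
  cnt <- count_junction_reads(sim$reads, probes)
  pr <- isoform_proportions(cnt, probes, catalog = cat, read_len = 100)
  got <- setNames(pr$proportion, pr$isoform)
  expect_true(all(abs(got[names(mix)] - mix) <= 0.02))
})

test_that("recovery error shrinks with read depth", {
  cat <- tim_example_catalog()
  probes <- build_junction_probes(cat)
  mix <- setNames(c(0.4, 0.3, 0.2, 0.1),
                  c("tim-L", "tim-cold", "tim-M", "tim-sc"))
  err_at <- function(n, seed) {
    sim <- simulate_isoform_reads(cat, mix, n, seed = seed)
    cnt <- count_junction_reads(sim$reads, probes)
    pr <- isoform_proportions(cnt, probes, catalog = cat, read_len = 100)
    max(abs(setNames(pr$proportion, pr$isoform)[names(mix)] - mix))
  }
  e5k <- mean(vapply(1:4, function(s) err_at(5000, s), numeric(1)))
  e50k <- mean(vapply(1:4, function(s) err_at(50000, s), numeric(1)))
  expect_lt(e50k, e5k)
})

test_that("unspliced/spliced ratios handle the documented cases", {
  fake <- function(un, sp) {
    data.frame(probe_id = c("I1_spliced", "I1_retained"),
               kind = c("spliced", "retained"), intron = "I1",
               count = c(sp, un), stringsAsFactors = FALSE)
  }
  expect_equal(spliced_unspliced_ratio(fake(50, 100), "I1")$ratio, 0.5)
  expect_equal(spliced_unspliced_ratio(fake(0, 100), "I1")$ratio, 0)
  r <- spliced_unspliced_ratio(fake(10, 0), "I1")
  expect_identical(r$flag, "infinite"); expect_identical(r$ratio, Inf)
  r <- spliced_unspliced_ratio(fake(0, 0), "I1")
  expect_identical(r$flag, "undefined"); expect_true(is.nan(r$ratio))
  expect_error(spliced_unspliced_ratio(fake(1, 1), "I9"), "I9")
})

test_that("a 70/30 retained:spliced junction-read mixture gives ratio near 7/3", {
  cat <- two_isoform_catalog()
  probes <- build_junction_probes(cat)
  flank <- attr(probes, "flank")
  seq_sp <- mature_sequence(cat, "iso-spliced")
  seq_re <- mature_sequence(cat, "iso-retained")
  boundary_sp <- 200L  # exon1 length: junction position in both matures
  n <- 6000L
  reads <- withr::with_seed(99L, {
    retained <- runif(n) < 0.7
    vapply(seq_len(n), function(i) {
      src <- if (retained[i]) seq_re else seq_sp
      start <- boundary_sp - sample(8:52, 1)  # read (60 nt) spans boundary
      substr(src, start + 1L, start + 60L)
    }, character(1))
  })
  cnt <- count_junction_reads(reads, probes)
  r <- spliced_unspliced_ratio(cnt, "I1")$ratio
  # binomial sampling error on u/s at n = 6000
  expect_lt(abs(r - 7 / 3), 0.25)
})
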