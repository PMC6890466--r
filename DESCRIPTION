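Package: timsplice
Title: Temperature-Dependent timeless Splice-Isoform Quantification and
    Circadian Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Junction-based quantification of alternatively spliced and
    alternatively polyadenylated transcript isoforms from short reads,
    nonparametric (JTK-style) detection of circadian cycling in count
    time courses, Drosophila activity-monitor behavioral statistics
    (day/night activity ratio, morning/evening onset detection, and
    free-running period and rhythmicity index from autocorrelation),
    AGO1 immunoprecipitation enrichment ranking from paired IP/input
    signals, and canonical miRNA seed-site scanning of 3' UTRs. Each
    analysis stage is paired with a seeded simulator that generates its
    input together with a machine-readable ground-truth record, so the
    whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
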