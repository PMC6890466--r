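# timsplice

Quantitative tools for studying how temperature remodels the splice-isoform
repertoire of the *Drosophila* clock gene *timeless* and what that does to
circadian behavior. The package implements five analysis stages as tested,
reusable components, each paired with a seeded simulator that generates its
input together with a machine-readable ground-truth record:

1. **Junction-based isoform quantification** — relative abundance of
   isoforms (full-length, intron-retaining, and intra-intronically
   cleaved/polyadenylated) from reads spanning isoform-diagnostic
   boundaries, plus per-intron unspliced/spliced ratios.
2. **Circadian cycling detection** — library-size and per-replicate-max
   normalization, max/min amplitude folds, and a JTK-style rank-concordance
   test with an exact generating-function null; a gene is called cycling
   when p < 0.05 and amplitude > 1.5.
3. **Locomotor behavior** — Trikinetics activity-monitor parsing, day/night
   activity ratios, morning/evening activity-onset detection by the
   three-criteria rule (increasing trend, ≤ 1/3 outlier bins, <10% dips
   tolerated), and free-running period plus rhythmicity index (RI) from the
   autocorrelation of the constant-darkness trace.
4. **AGO1-IP enrichment ranking** — residuals from a per-replicate linear
   model of log2(IP) on log2(input), averaged and ranked (rank 1 = most
   RISC-associated), plus the simple IP/input ratio.
5. **miRNA seed-site scanning** — canonical 8mer / 7mer-m8 / 7mer-A1 / 6mer
   seed-match counting in 3' UTRs.

## The statistics at the core

For a series $y$ sampled at ZT times $t$ with replicates, the cycling test
compares $y$ against cosine references $\cos(2\pi(t-\varphi)/\tau)$ on a
phase grid. Concordance is the Jonckheere–Terpstra statistic $J$ over pairs
with distinct reference values (replicates create reference-side ties); its
exact null pmf is the convolution of Mann–Whitney U distributions over the
tie groups, so for 6 distinct timepoints a noiseless cosine attains the
minimal one-sided p of 1/720. The reported p is the minimum over phases,
Bonferroni-corrected by the number of distinct reference patterns.

Isoform support counts follow
$\mathbb{E}[\text{count}_p] \propto \sum_{i \in \text{diag}(p)} n_i \cdot
\frac{R - 2m + 1}{L_i - R + 1}$
for read length $R$, overhang $m$, and mature lengths $L_i$; proportions
are obtained from uniquely diagnostic probes or, when an isoform has no
unique probe (the full-length isoform shares every junction), by
non-negative least squares over all probe-set counts.

## Worked example

```r
library(timsplice)

catalog <- tim_example_catalog()          # synthetic 4-isoform tim-like gene
probes  <- build_junction_probes(catalog, flank = 20)

# a cold-like, fairly even isoform pool
mix <- c("tim-L" = 0.25, "tim-cold" = 0.25, "tim-M" = 0.25, "tim-sc" = 0.25)
sim    <- simulate_isoform_reads(catalog, mix, n_reads = 50000, seed = 1)
counts <- count_junction_reads(sim$reads, probes, min_overhang = 8)
isoform_proportions(counts, probes, catalog = catalog, read_len = 100)
#>    isoform   support proportion
#> 1 tim-cold  735.0938  0.2585340
#> 2    tim-L  741.5000  0.2370957
#> 3    tim-M  719.5938  0.2548512
#> 4   tim-sc 1608.9375  0.2495191
```

The planted even mixture is recovered within ~0.015 of truth (supports are
mean junction-read counts per isoform before length correction; `tim-sc` is
much shorter, so its junction coverage per molecule is higher). The
unspliced/spliced ratio of the cold-sensitive intron in the same library:

```r
spliced_unspliced_ratio(counts, "I4")
#>   intron unspliced spliced     ratio flag
#> 1     I4       724    1450 0.4993103   ok
```

Cycling detection on a simulated 6-timepoint, 2-replicate matrix in which
20% of 200 genes cycle:

```r
tc  <- simulate_timecourse(n_genes = 200, frac_cycling = 0.2, seed = 1)
res <- cycle_detect(tc$matrix)            # p < 0.05 & amplitude > 1.5
head(res[order(res$p), c("gene", "p", "phase", "amp_combined", "cycling")], 3)
#>          gene            p phase amp_combined cycling
#> 35  gene_0035 6.814173e-05     8     3.424667    TRUE
#> 43  gene_0043 1.915985e-04     0     5.235546    TRUE
#> 193 gene_0193 1.060606e-03     0     4.457912    TRUE
sum(res$cycling)                          # 26 called; 30 truly cycle
```

Behavior metrics on a simulated monitor (4 LD + 5 DD days, evening
component programmed at ZT9):

```r
dam <- simulate_dam(n_channels = 8, seed = 1)
detect_onset(activity_profile(dam$record, channel = 1), "evening")
#>   channel component detected onset_min run_length outliers
#> 1       1   evening     TRUE       540          4        0
estimate_period(dam$record, channel = 1)
#>   channel period_h        ri rhythmic
#> 1       1       24 0.5812764     TRUE
```

The onset is recovered at exactly ZT9 (minute 540), the free-running
period at 24.0 h with RI 0.58 — a strongly rhythmic channel.

A thin command-line wrapper over the same functions is installed at
`inst/cli/timsplice.R` with stages `simulate`, `quantify`, `cycle`,
`behavior`, `enrich`, and `scan`; every stage is byte-deterministic given
its inputs and `--seed`.

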