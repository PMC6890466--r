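---
title: "Methods: junction-based isoform quantification and circadian analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based isoform quantification and circadian analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timsplice)
```

# Scope and scientific setting

The *timeless* (*tim*) gene of *Drosophila* produces several transcript
isoforms whose balance shifts with ambient temperature: besides the
canonical full-length mRNA (*tim-L*), cold favours an isoform retaining the
last thermosensitive intron (*tim-cold*) and a short isoform terminated at
a cleavage/polyadenylation site inside an upstream intron (*tim-sc*), while
warmth favours retention of another intron (*tim-M*). Because TIM is a core
clock protein, this splicing program couples temperature to circadian
behavior: the day/night distribution of locomotor activity, the timing of
the morning and evening activity bouts, and free-running rhythms in
constant darkness. Post-transcriptional control by miRNAs, assayed by AGO1
immunoprecipitation and seed-site prediction, acts on the isoform-specific
3' UTRs.

`timsplice` implements the quantitative procedures used in such a study as
reusable, tested components, together with simulators that generate every
input with known ground truth. The package does not attempt to reproduce
any wet-lab result; it reproduces the *computations*, and its tests verify
them against independent oracles (closed forms, brute-force enumeration,
and resimulation).

# Junction-based isoform quantification

## Model

Isoforms are described on a shared reference by ordered exon blocks
(0-based, half-open intervals); intron retention appears as a block spanning
the intron, and intra-intronic cleavage/polyadenylation as a
`terminal_position` with a poly(A) tail appended to the mature sequence.
Each structural difference creates a diagnostic boundary:

* a **spliced** exon–exon junction (sequence formed when an intron is
  removed),
* a **retained** exon–intron boundary (contiguous genomic sequence across
  the donor site),
* a **terminal** cleavage boundary (last genomic bases followed by poly(A)
  context).

`build_junction_probes()` emits one probe of `2 * flank` bases per
boundary. The probe's `diagnostic_for` set is determined *empirically*: the
isoforms whose mature sequence contains the probe exactly once. A probe
occurring multiple times in any isoform is ambiguous and aborts the build,
so uniqueness is guaranteed by construction rather than assumed.
Constitutive junctions (present in every isoform) are retained as controls.

A read supports a probe when it spans the boundary with at least
`min_overhang` matching bases on each side; the probe's central
`2 * min_overhang` core must match exactly and the rest of the overlap must
agree (optionally within a Hamming distance of 1). Defaults are
`flank = 20` and `min_overhang = 8`: 40-mers are effectively unique in a
gene-scale reference, while an 8-base overhang tolerates read-end placement
without spurious matches.

## From counts to proportions

Per-isoform support is the mean count over the isoform's uniquely
diagnostic probes (mean, not sum, so isoforms with different numbers of
diagnostic junctions are comparable). When an isoform has no unique probe —
the full-length isoform shares every junction with some other isoform —
`isoform_proportions()` solves the small non-negative least-squares system
mapping isoform abundances to probe-set counts over *all* probes
(`pracma::lsqnonneg`), which resolves it through junction co-occurrence.

Junction support also scales inversely with mature transcript length: with
reads sampled uniformly along an isoform of mature length $L$, the chance
that a read of length $R$ spans a given boundary with overhang $m$ is
$(R - 2m + 1)/(L - R + 1)$. When the catalog and read length are supplied,
supports are divided by this factor, which matters whenever isoforms differ
substantially in length (the short cleaved isoform is less than half the
length of the others in the bundled example catalog). Whether the original
junction tallies were corrected for junction multiplicity or length is not
derivable from published methods text; both the mean-over-probes rule and
the optional length correction are therefore explicit, recorded choices of
this package.

The per-intron `spliced_unspliced_ratio()` (retained-boundary count over
spliced-junction count) is the minigene splicing-efficiency statistic; it
is reported raw, with infinite/undefined flags for zero denominators.

## Read simulator

`simulate_isoform_reads()` draws an isoform per read from the mixture, a
start uniform along the mature sequence, and independent substitution
errors (default $10^{-3}$ per base); quality is a constant Phred score
because junction counting uses only sequence identity. The bundled
`tim_example_catalog()` is a *synthetic* four-isoform gene mirroring only
the architecture of the real locus (one constitutive junction, two
retention isoforms, one intra-intronic cleavage isoform whose every
junction is shared). The default poly(A) tail is 100 nt so that reads can
span the cleavage boundary from every offset; with a tail shorter than
`read_len - flank`, terminal-probe support is depleted by the transcript
edge. The simulator does not model 3'-end bias, PCR duplicates,
multi-mapping, alignment, or a realistic transcriptome, so recovery tests
demonstrate correctness of the counting scheme, not robustness to those
artifacts.

# Cycling detection

## Preprocessing and amplitude

Counts are divided by per-sample library sizes, then each gene is divided
by its maximum within each replicate series, making series scale-free so
that the amplitude statistic (per-replicate maximum/minimum fold) is
comparable across genes. Genes with more than two zero counts are
discarded. The zero rule is read as *total across all of a gene's samples*
(the stricter, simpler reading); a per-timepoint variant is available via
`zero_rule = "per_timepoint"` and the choice is recorded in the output.
The combined amplitude is the arithmetic mean of per-replicate folds; the
combination rule is not derivable from the published text and is this
package's documented choice.

## The JTK test

For each candidate phase $\varphi$ on a grid (default: the sampling
resolution, so six phases for 4-h sampling and a 24-h period),
`jtk_test()` measures Kendall concordance between the series and the
cosine reference $\cos(2\pi(t-\varphi)/\tau)$. Replicates enter as
repeated observations at their timepoint, which creates ties on the
reference side; the concordance statistic over reference-distinct pairs is
the Jonckheere–Terpstra statistic $J$, whose exact null distribution
factorizes into a convolution of independent Mann–Whitney U distributions
over the tie groups (the generating-function identity for the Gaussian
multinomial). The package computes this null exactly (via `stats::dwilcox`
convolution) for up to 20 observations and falls back to a
continuity-corrected normal approximation above that. For six distinct
timepoints the minimal attainable one-sided p is $1/6! = 1/720$, which the
test attains on a noiseless grid-phase cosine; the test suite checks the
entire null pmf against brute-force permutation enumeration.

The reported p-value is the minimum over phases multiplied by the number
of distinct reference rank patterns (Bonferroni, capped at 1); the
unadjusted minimum is reported alongside as `p_raw`. A constant series
carries no concordance information and is assigned p = 1.

## The call rule, calibration, and power

A gene is called cycling when p < 0.05 and combined amplitude > 1.5 (the
published thresholds; both configurable). `call_cycling()` applies the
rule to the phase-adjusted p by default because that is the calibrated
per-gene test: on simulated null genes its rejection rate stays at or
below the nominal level. The unadjusted minimum-phase p is available via
`use_raw_p = TRUE`, but selecting the best of six one-sided tests without
correction inflates the null rejection rate several-fold.

This choice has a power consequence that users of sparse designs should
understand. With six timepoints, two replicates, a max/min fold of 3, and
negative-binomial dispersion 0.1 (biological-replicate-level noise), the
adjusted rule detects roughly seven in ten cycling genes, while the
unadjusted rule detects nearly all of them — at the cost of its inflated
false-positive rate. Both rates are recomputed from scratch by
`scripts/acceptance.R`; a rank test on 12 observations with a six-pattern
correction simply cannot be both calibrated and near-perfectly powerful at
this noise level. Phase estimates are restricted to the phase grid, so
recovered phases land on the nearest or, occasionally under noise, the
adjacent grid point; a small fraction of detected genes therefore shows
phase errors between one and one-and-a-half sampling intervals.

## Timecourse simulator

Cycling genes follow $b\,(1 + a\cos(2\pi(t-\varphi)/\tau))$ with $a$ set
so the noiseless max/min fold *over the sampled timepoints* equals the
drawn amplitude; phases are uniform, baselines log-normal, and counts
negative binomial (dispersion 0.1 by default; log-normal and noiseless
variants available). The noise family of real count data is not something
the package asserts; negative binomial is the conventional default for
read counts. Default sampling follows the study design the package
emulates: six timepoints (ZT3–ZT23), two replicates.

# Locomotor behavior

## Monitor files and profiles

`read_dam()` parses Trikinetics-style monitor text (one line per minute:
index, date, time, status, five unused fields, light flag, 32 channel
counts), requires strictly advancing timestamps, and treats missing
minutes as gaps: flagged by default (downstream operations refuse the
record), zero-filled on request, or rejected outright. Daily activity
profiles are per-bin sums (30-min bins by default) averaged over a stated
set of days; day selection is always an explicit argument because
"average over the last three LD days" and "over all days" are different
published displays.

`day_night_ratio()` is mean counts/min during lights-on divided by mean
counts/min during lights-off over the selected LD days — invariant to
uniform count rescaling, infinite-flagged when the night mean is zero.

## Onset detection

The published criteria for the beginning of an activity component are:
(1) a trend of increasing activity, (2) at most one third of the bins may
be outliers, (3) a bin is an outlier only if it falls below its
predecessor by at least 10% (smaller dips are tolerated). The criteria
validate a candidate run but do not by themselves locate its start: on a
noisy profile, *any* early bin in a flat stretch before the component
starts a run whose outlier budget (which grows with run length) absorbs
the flat prefix, so taking the earliest bin whose run satisfies (1)–(3)
is systematically biased early. The detector therefore anchors the
candidate the way the component itself is defined: the onset is the first
bin in the search window that exceeds the window baseline (lower
quartile) by a configurable fraction (`onset_frac`, default 0.1) of the
component height *and* rises above its preceding bin; the run from that
bin to the window maximum is then validated by criteria (1)–(3), and a
failed validation means no clearly distinguishable component (the
not-detected flag, mirroring the published inclusion rule). Minimum run
length (default 3 bins) and the search windows (evening ZT4–12, morning
ZT18–36 across midnight) are explicit parameters.

## Period and rhythmicity in DD

`estimate_period()` computes the autocorrelation of the 30-min-binned
constant-darkness trace (at least 3 DD days). The period is the lag of
the highest autocorrelation peak between 14 and 34 h; peak *locations*
are found on the unbiased autocorrelation estimate because the standard
$1/n$ normalization tapers with lag and drags peaks toward shorter
periods by up to one bin. The rhythmicity index (RI) follows the
signal-processing-toolbox convention: the height of the third
autocorrelation peak (the peak nearest twice the estimated period,
counting lag 0 as the first), read from the conventionally normalized
autocorrelation. A channel is rhythmic when a period peak exists and RI
reaches the threshold (default 0.25 — the published analyses report RI
without stating a cutoff, so the threshold is explicit and configurable).
RI thresholds trade sensitivity against specificity: at 0.25, white-noise
channels essentially never pass, while clean sinusoidal rhythms over five
DD days score RI well above 0.4.

## Behavior simulator

`simulate_dam()` writes per-minute Poisson counts: during LD, a baseline
(default 0.1 counts/min, the low tonic beam-crossing rate of a single fly
between bouts) plus truncated-Gaussian morning and evening components
(peak 4 counts/min, span 240 min — a several-hour activity buildup rising
across multiple 30-min bins, anchored so the rate first exceeds baseline
exactly at the programmed onset); during DD, a sinusoid with the
channel's free-running period, or a mean-matched constant rate for
designated arrhythmic channels. Defaults follow the emulated protocol:
4 LD days, 5 DD days, 12:12 light schedule, morning onset ZT22, evening
onset ZT9. The truncated-Gaussian shape is chosen precisely because it
gives an unambiguous programmed onset for recovery tests; real fly
activity has bout structure, startle responses at light transitions, and
inter-individual variability that this generator does not model.

# AGO1-IP enrichment

Per replicate, `fit_residuals()` fits ordinary least squares of log2(IP)
on log2(input) across genes; the residual is the log2 excess of
immunoprecipitated signal over what transcript abundance predicts.
Residuals are averaged across replicates and ranked in decreasing order
(`rank_enrichment()`; rank 1 = most enriched, ties broken by gene id).
The log2 scale is the conventional one for microarray-type signals; the
published methods do not state the scale, and no covariates beyond input
signal are included. The model is fit per replicate and residuals
averaged (a pooled fit is available behind a flag). Upstream array
normalization is out of scope: the module requires pre-normalized
signals. The simple `ip_input_ratio()` (geometric mean of per-replicate
IP/input) is provided as the companion statistic; when the IP–input
relation has slope 1 the two rankings coincide.

`simulate_ip_input()` plants enrichment as per-gene log2-fold offsets
(default folds 2–8) on top of an affine log-linear IP/input relation with
residual noise (default sd 0.3 log2 units, two replicates).

# miRNA seed sites

`seed_sites()` scans a UTR for matches to the *reverse complement* of the
miRNA seed (positions 2–8 from the miRNA 5' end) and classifies canonical
site types by the standard hierarchy — 8mer (seed match plus the A
opposite position 1), 7mer-m8, 7mer-A1, 6mer — with the longest match
winning at a position and overlaps resolved longest-first, then leftmost.
The target-site A1 is required to be an adenosine in the UTR regardless of
miRNA position 1, per the canonical definition. T and U are
interchangeable in both inputs. Context scores, conservation filtering,
3'-supplementary pairing, and site accessibility are deliberately out of
scope: the module reproduces seed-match counting only, so its counts are
an upper bound on, not a reimplementation of, full target-prediction
pipelines.

# Numerical and testing choices

* All simulators take explicit integer seeds and are byte-deterministic;
  no global RNG state is touched (`withr::with_seed`).
* Exact JTK nulls are cached per tie-group signature; exact computation
  is used up to 20 observations, the normal approximation beyond.
* Degenerate inputs have defined behavior: constant series give p = 1;
  all-zero probe counts flag proportions undefined; zero spliced counts
  flag ratios infinite/undefined; zero night activity flags the
  day/night ratio infinite; constant input signal is a fit error.
* Problem sizes in the test suite (50,000 reads for mixture recovery,
  1,000/500 genes for calibration/power, 100 channels for onset and
  rhythmicity recovery) were chosen so the full suite completes in well
  under a minute while keeping Monte-Carlo margins comfortable; the same
  sizes are used by `scripts/acceptance.R`.

# Known limitations

* Proportions assume reads sample isoforms uniformly along their length;
  3'-biased protocols would need a different support model.
* The set-resolution scheme assumes probe counts are (up to noise) linear
  in isoform abundance — true for the simulator, approximate for real
  libraries.
* JTK power at sparse designs is modest under the calibrated rule (see
  above); more timepoints help far more than more replicates because the
  reference side gains distinct values.
* Onset detection presumes a single dominant component per search window;
  bimodal components within one window will be anchored at the first
  threshold crossing.
* The RI threshold and the onset `onset_frac` are conventions, not
  estimates; both are surfaced as parameters and recorded in outputs.
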