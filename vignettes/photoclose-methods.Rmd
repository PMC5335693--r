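---
title: "Models and design choices in photoclose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in photoclose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`photoclose` implements a comparative open-chromatin analysis for purified
photoreceptor populations: rods, green cones, and the blue-cone-like
photoreceptors of *Nrl*-deficient retina. The scientific question it serves
is how rod chromatin differs globally and locally from cone chromatin —
genome-wide closure, peak-level differential accessibility, the sequence
grammar (transcription-factor motifs and homeodomain dimer k-mers) of
rod- versus cone-specific elements, and how accessibility changes couple to
gene expression. Peaks, fragment tables, count matrices, annotation and
motif files are the inputs; read alignment and peak calling are upstream
and out of scope, as are GO enrichment, conservation scoring, and *de novo*
motif discovery.

A first-class simulator (`simulateDataset()`) generates every input with
planted ground truth, so the full pipeline can be exercised and validated
offline.

# Conventions

All interval arithmetic is 0-based half-open on disk (BED/narrowPeak) and
1-based closed in memory (Bioconductor `GRanges`); readers and writers
convert at the boundary and round-trip byte-identically. Peaks are
standardized to 200 bp elements centered on summits (`recenterOnSummit()`),
with boundary windows shifted inward rather than truncated so all elements
stay equal width. Fragment filtering keeps nucleosome-free inserts
(`insert_size <= 100` bp). Fragments are assigned to bins and windows by
their midpoint: the midpoint is strand-symmetric, keeps window counts
conserved (they sum to the number of fragments), and makes brute-force
oracles trivial; a cut-site mode (`mode = "cut"`) and a bp-overlap window
mode are available where a different convention is wanted.

# Peak atlas and specificity classes

`mergePeakSets()` coalesces per-sample peak calls (>= 1 bp overlap) into a
reference atlas recording contributing sources. `nearestTSS()` measures the
signed summit-to-TSS distance on the gene's strand (negative = upstream);
the summit is the anchor because all peak-level analyses here are
summit-centered — the midpoint is the fallback when no summit exists. Ties
break to the smaller absolute distance, then the lexicographically smaller
gene id, and the implementation is tested against an exhaustive all-pairs
oracle.

Promoters are elements with signed distance strictly between -1000 and
+100 bp; everything else is an enhancer. Both bounds are open, following
the "less than" phrasing conventional for this partition; boundary cases
are covered by tests.

Specificity classification combines the rod-vs-cone differential test with
external peak sets: significantly more open in rods = rod-specific, in
cones = cone-specific, not significant = shared; any element overlapping a
non-photoreceptor peak set is reassigned to the shared-with-other-tissues
class regardless of the test. The enhancer-focused "filtered" view removes
promoters, then non-photoreceptor elements, then elements with more than
70% repeat overlap (strictly greater; exactly 70% survives), and reports
per-stage survivor counts.

# Differential testing

Normalization is median-of-ratios: a sample's size factor is the median,
over features with all-positive counts, of its count over the feature's
geometric mean. The differential engine is a deliberately simple
thresholded negative-binomial test rather than a reimplementation of a
full GLM framework: the comparative analysis needs a calibrated three-way
call (rod-up / cone-up / not significant) at |log2 FC| > 1, not shrunken
effect estimates. Per feature:

* group means on the normalized scale, with a pseudocount of 0.5 before
  the log ratio (configurable);
* method-of-moments NB dispersion pooled across groups, floored at 1e-8
  and shrunk halfway toward a fitted `a0 + a1/mu` mean-dispersion trend;
* a delta-method standard error for the log2 ratio,
  `Var(mean) = (1/n^2) * sum_j (mu/s_j + alpha mu^2)`;
* a two-sided normal p-value for the composite hypothesis
  `|LFC| > threshold`, statistic `max(0, |LFC| - threshold) / SE` — the
  composite (rather than one-sided-per-direction) reading matches the
  three-way classification downstream;
* Benjamini-Hochberg control (`bhAdjust()`, a validated front end over
  `stats::p.adjust`).

Accessibility runs at FDR 0.1 and expression at FDR 0.05 by default, both
with an LFC threshold of 1. The test is validated against DESeq2 on
planted data (LFC correlation > 0.95, matching calls), calibrated under
the null (empirical call rate <= 0.15 at nominal 0.1 over 20 simulations)
and powered (>= 0.9 at planted LFC 3, mean 100, dispersion 0.05, two
replicates per group). Known behavior shared with all median-of-ratios
pipelines: a large fraction of strongly differential features biases the
size factors; the simulator therefore keeps differential features a
minority, as in real data.

# Global closure statistic

`windowCoverage()` tiles each chromosome with fixed windows (50 kb
default) from position 0, truncating the last window, counts fragment
midpoints, and normalizes by the total assigned fragments. Optionally,
blacklisted windows are dropped before the ECDF. `coverageEcdf()` is the
proportion of windows at or below each observed coverage value; a
left-shifted curve means a more closed landscape.

`closureShift()` reduces a pair of ECDFs to scalars. A caveat discovered
during development and worth stating precisely: for per-sample normalized
coverage, every sample's window distribution has the same mean (1 divided
by the number of windows), and the signed area between two ECDFs equals
the difference of their means — so the linear-scale area is ~0 for *any*
pair of normalized samples and cannot order them. The statistic reported
for that purpose is `area_log`, the same signed area computed on log10
coverage (with a small epsilon for empty windows): it equals the log ratio
of geometric means and is positive exactly when the sample's distribution
is more left-skewed — more low-coverage windows — which is what "more
closed" means here. The linear `area` (useful for unnormalized inputs) and
a tie-counting dominance fraction are reported alongside. On simulated
data the rod samples' `area_log` exceeds that of every non-rod sample
against every reference, reproducing the uniquely-closed ordering as a
property.

# Motif engine

PWMs are probability matrices with natural-log odds scoring
(`sum(log(p/q))`), the unit convention under which a "relaxed threshold of
5" is a meaningful hit cutoff for typical 8-14 bp motifs. Probabilities
are epsilon-smoothed (0.001) only when a motif file contains zeros, so
re-reading a written library is stable. `N` bases contribute zero to the
score. Both strands are scanned; reverse-strand hits are reported at the
forward coordinate of the match start, and scanning is tested against
per-position rescoring and for strand symmetry.

Background construction draws fixed-length windows uniformly from the
genome, rejects windows with more than 70% masked bases, scores the rest
by a target-versus-pool composition log-likelihood, and selects the rank
window whose aggregate mono- and di-nucleotide composition minimizes the
L1 distance to the target set (tolerance 0.05 per frequency vector, with a
warning when unreachable). The selection is deterministic given the
candidate draws, which makes pipeline reruns byte-identical.

Redundancy collapse scores similarity as the maximum Pearson correlation
of aligned flattened probability columns over all ungapped offsets and
both orientations (>= 4 overlapping columns), then clusters greedily from
the highest-scoring motif, absorbing any unassigned motif above the 0.6
threshold. The enrichment score used for ranking is the -log10
hypergeometric p from target-versus-background sequence counts (the
ranking statistic was an open choice; the hypergeometric is the natural
companion of the enrichment workflow). Total information content is the
fallback for unscored motifs.

Co-occurrence counts peaks containing at least one hit of each motif;
co-presence suffices by default (the weakest reading of "at least one
pair"), with a minimum-separation option for the stricter reading.
Expected co-occurrence under independence is `n_i * n_j / N` and
enrichment is `log2(O/E)` with a `-Inf` sentinel at `O = 0`. Calibration:
under independent planting at N = 10,000 the absolute enrichment stays
below 0.2; planted joint placement above independence is recovered within
0.1.

Spacing profiles re-anchor each sequence on its best primary hit (highest
score, ties leftmost), orient by its strand, and tally secondary hits by
signed start-to-start offset and relative strand at 1 bp resolution. Only
the anchor hit itself is masked; overlapping non-identical hits are kept,
because tightly spaced dimer configurations are the object of interest.

# Homeodomain dimer k-mers and reporter stratification

The k-mer scheme encodes the K50 homeodomain monomer cores TAAT and TAAG
(with reverse complements ATTA / CTTA) and the inverted dimer
configurations with a fixed 3-nt spacer: homotypic `TAAT[N]3ATTA`,
homotypic-3'G `TAAG[N]3CTTA`, and heterotypic `TAAT[N]3CTTA` (whose
reverse complement `TAAG[N]3ATTA` is included in the same class). Every
class is closed under reverse complement, which is asserted
property-style; matching is exact (IUPAC `N` only in the spacer), on the
forward strand in both literal and reverse-complement forms — equivalent
to two-strand scanning and simpler to check against the regex oracle used
in tests. The spacer is exactly 3 nt by default with a range option, since
an ellipsis in a k-mer list could also be read as "any spacer".

`mutateCrxSites()` applies the canonical single-base CRX knockout
(CTAATCC to CTACTCC, and GGATTAG to GGAGTAG on the other strand),
left-to-right and non-overlapping; it is idempotent.

Reporter stratification splits constructs of one variant class (native /
CRX-mutant / scrambled) by presence of a k-mer class and compares
expression with a two-sided Wilcoxon rank-sum test (normal approximation
with tie correction). A rank test was chosen over a t-test because
reporter expression distributions are heavy-tailed and the conventional
analysis in this setting is permutation-capable; an exact/permutation mode
is provided for small strata.

# The simulator

`simulateDataset()` emulates the study's structure at desk scale. The
default configuration — the package's fixed reference conditions — is:

* a 12 Mb genome over 3 chromosomes, order-1 Markov background (~42% GC,
  CpG-depleted), scaled down from a mammalian genome so the full pipeline
  runs in seconds while keeping thousands of windows and a thousand peaks;
* four rod-closed domains (two of 1 Mb, two of 0.5 Mb; the half-megabyte-
  to-megabyte scale of the large selectively closed regions), hosting 80%
  of cone-specific peaks;
* 600 shared, 60 rod-specific, 300 cone-specific and 150
  non-photoreceptor peaks — preserving the two key ratios: shared peaks
  dominate, and cone-specific peaks outnumber rod-specific ~10-fold;
* NB counts with mean 100 for open peaks, 10 inside closed domains for
  rods, dispersion alpha 0.05, planted |log2 FC| 2, two replicates per
  group, and per-sample depth factors in [0.8, 1.25];
* fragments emitted two ways that reconcile exactly: each peak receives
  its NB draw as short (40-100 bp) inserts with midpoints inside the peak,
  plus ~30% nucleosomal (~200 bp) inserts that the NFR filter removes, plus
  genome-wide background thinned to 10% inside closed domains for rod
  samples — this is what makes the closure ECDF shift emerge from the
  fragment level rather than being painted onto window counts;
* motifs planted per class (shared: CRX + CTCF; rod-specific: MAF + NR;
  cone-specific: Q50 homeodomain + bHLH), written into the genome sequence
  so exact-match scans recover every planted instance;
* gene TSSs sponsored by class-specific peaks — every rod-specific peak
  sponsors a gene 2-10 kb away, every third cone-specific peak sponsors
  one 25-80 kb away, filler genes avoid closed domains — which reproduces
  the cone-specific-elements-are-gene-poor geometry (cone peaks sit
  several-fold farther from the nearest TSS than rod-specific or shared
  peaks) while keeping the nearest-gene map granular enough for coupling
  recovery;
* gene directions drawn per gene from the majority class of its assigned
  differential peaks, concordant with probability `expr_coupling` (0.8),
  discordant otherwise, and 30% of genes at most differential so
  median-of-ratios stays unbiased;
* a reporter library of 500 native 84 bp constructs (every one carrying a
  CRX site; dimer configurations planted in subsets), a mutated arm
  produced by `mutateCrxSites()`, and scrambled controls; native
  constructs containing the homotypic TAAT dimer have expression shifted
  down by 1 sd — the mutant arm carries no shift, so the repression
  vanishes when CRX sites are gone.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: mappability and GC biases, fragment-length
chromatin structure beyond a two-component insert mixture, realistic motif
co-occurrence grammar within elements, overdispersion trends across the
dynamic range, batch effects, and genome-scale repeat structure. The
simulator validates the machinery and its calibration, not biological
discovery.

Determinism: a `SimConfig` plus its seed fixes every byte of output;
reruns of `simulateDataset()` and `runPipeline()` compare identical file
by file, which the test suite asserts.

# Problem sizes

The test suite and the acceptance script run the default 12 Mb / 1,110
peak configuration for structure-recovery checks, a 3 Mb configuration for
module-level tests, and a 24 Mb / 2,400 peak configuration for coupling
recovery, where the +/- 0.05 tolerance needs at least ~500
doubly-significant peak-gene links. Calibration loops use 10-20
simulations of a few hundred features each. These sizes were chosen so
each property is measured with adequate precision while the whole suite
runs in minutes.

# Known limitations

* The NB test's normal approximation is anticonservative below ~5 counts;
  the simulator keeps open-peak means well above that, and real use should
  too (or pre-filter low-count features).
* Greedy redundancy collapse depends on the score order among motifs in
  the same similarity cluster; a different ranking statistic can change
  which member represents a cluster (never the cluster membership
  threshold).
* `sampleMatchedBackground()` cannot reach compositions absent from the
  genome (e.g. strongly GC-rich targets against an AT-rich genome); it
  warns and returns the best achievable match.
* Expression coupling recovery degrades when many differential peaks share
  one nearest gene; the tolerance quoted above presumes the link scale
  stated there.
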