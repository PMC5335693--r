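# photoclose

Comparative open-chromatin analysis of rod and cone photoreceptors.

Rod photoreceptors of nocturnal mammals carry an inverted nuclear
architecture and a globally *more closed* chromatin landscape than cones
and other cell types: megabase-scale runs of regulatory elements that are
open in cones (and in *Nrl*-deficient "blue-cone-like" photoreceptors) are
selectively closed in rods. `photoclose` provides the statistical pipeline
for characterizing that difference from ATAC-seq peaks, fragment tables
and count matrices:

* **Peak atlas** — merge per-sample peak calls into a reference set of
  200 bp summit-centered elements, assign nearest TSSs, partition
  promoters (−1 kb < d < +100 bp of the TSS) from enhancers, and classify
  elements as shared / rod-specific / cone-specific / shared-with-other-
  tissues, with the enhancer filter cascade (promoter, non-photoreceptor,
  >70%-repeat removal).
* **Global closure** — fixed 50 kb window coverage, per-sample
  normalization, empirical cumulative distributions
  F(x) = #{windows with coverage ≤ x}/N, and scalar closure-shift
  summaries between samples (signed ECDF area, log-scale area = log ratio
  of geometric mean coverage, dominance fraction).
* **Differential accessibility / expression** — median-of-ratios size
  factors s_j = median_i (K_ij / (∏_j K_ij)^{1/n}) and a simplified
  negative-binomial test of |log2 FC| > 1 (delta-method SE, method-of-
  moments dispersion shrunk to a trend, BH control; FDR 0.1 for ATAC, 0.05
  for RNA), cross-checked against DESeq2 in the test suite.
* **Motif grammar** — natural-log-odds PWM scanning on both strands,
  composition-matched genomic background sampling, known-motif enrichment
  (hypergeometric), motif-library redundancy collapse (max PCC over
  ungapped alignments and orientations, greedy by score, threshold 0.6),
  pairwise co-occurrence enrichment log2(O/E) with E = n1·n2/N, and
  strand-resolved spacing profiles around a primary motif.
* **Homeodomain dimer k-mers** — exact-match classification of K50
  monomer (TAAT/TAAG) and inverted dimer configurations with a 3-nt spacer
  (TAAT[N]3ATTA, TAAG[N]3CTTA, TAAT[N]3CTTA), CRX-site knockout mutation
  (CTAATCC→CTACTCC), and Wilcoxon stratification of reporter (CRE-seq)
  expression by k-mer class.
* **Integration** — quadrant classification of doubly-significant
  peak–gene links (concordant-rod / concordant-cone / discordant),
  sign-agreement summaries, and Spearman relatedness with UPGMA clustering
  on 1−ρ.
* **Simulator** — `simulateDataset()` generates a complete synthetic
  study (genome with rod-closed domains, peak calls, fragments, NB counts,
  planted motifs, coupled expression, reporter library) with ground truth,
  so everything above is testable offline and deterministically.

## Worked example

Simulate the default synthetic study and run the full pipeline:

```r
library(photoclose)

cfg <- SimConfig(seed = 7)
cfg
#> SimConfig
#>   genome: 1.2e+07 bp over 3 chromosome(s), seed 7
#>   peaks: shared_PR=600, rod_specific=60, cone_specific=300, non_PR=150
#>   groups: rod / green_cone / blue_cone x 2 replicates
#>   NB: mean open 100, closed 10, dispersion 0.05, planted LFC 2.0

b   <- simulateDataset(cfg)
res <- runPipeline(b, out_dir = "run7")

res$filter_cascade
#>                all       non_promoter photoreceptor_only    repeat_filtered
#>               1110               1033                894                850
```

The cascade mirrors the enhancer-focused filtering: 1,110 atlas elements,
1,033 after promoter removal, 894 after dropping elements shared with
non-photoreceptor samples, 850 after the 70% repeat filter.

```r
head(res$enrichment$rod_specific, 3)
#>   motif target_frac background_frac  ratio neg_log10_p
#> 1   MAF      0.7292          0.0050 145.83      38.106
#> 2    NR      0.6667          0.1275   5.23      14.485
#> 3  bHLH      0.0625          0.0425   1.47       0.439
```

The motifs planted into rod-specific elements (MAF, NR) rank on top of the
enrichment table computed against a mono/di-nucleotide-matched genomic
background; cone-specific elements return Q50 and bHLH instead.

```r
subset(res$closure, sample == "rod_rep1")[1:3, ]
#>     sample       reference      area area_log dominance
#> 1 rod_rep1        rod_rep2 -5.78e-20  0.00263     0.617
#> 2 rod_rep1 green_cone_rep1  1.24e-20  0.13015     0.381
#> 3 rod_rep1 green_cone_rep2 -2.44e-20  0.13196     0.398
```

`area_log` — the log-scale area between window-coverage ECDFs, i.e. the
log ratio of geometric mean coverage — is ≈ 0 against the other rod
replicate and strongly positive against every cone sample: the rod
landscape is uniquely shifted toward low-coverage windows. (The
linear-scale `area` is ~0 for any pair of normalized samples; see the
methods vignette.)

```r
res$directional[c("n_significant", "sign_agreement")]
#> $n_significant
#> [1] 227
#> $sign_agreement
#> [1] 0.793
```

Among peaks that are both differentially accessible and near a
differentially expressed gene, 79% change in the same direction —
recovering the simulator's configured coupling of 0.8.

The methods, parameter choices and simulator design are documented in
`vignettes/photoclose-methods.Rmd`.

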