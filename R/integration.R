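#' @importFrom stats cor hclust as.dist binom.test
NULL

#' Link peak accessibility to nearest-gene expression
#'
#' Joins a peak-level differential-accessibility table with a gene-level
#' differential-expression table through each peak's nearest gene, and
#' classifies doubly-significant links by the sign pair of the two log2
#' fold changes (group A = rods as numerator in both): `concordant_rod`
#' (more open and higher expressed in rods), `concordant_cone` (both
#' cone-directed), `discordant` (opposite signs), `ns` otherwise. Quadrant
#' classification conventionally runs both FDRs at 0.1.
#'
#' @param atlas `GRanges` with `name` and `nearest_gene` columns.
#' @param atac_diff data.frame from [nbDiffTest()] over peaks.
#' @param rna_diff data.frame from [nbDiffTest()] over genes.
#' @param fdr_atac,fdr_rna q-value cutoffs for the two tables.
#' @return data.frame: `peak`, `gene`, `tss_distance`, `atac_lfc`, `atac_q`,
#'   `rna_lfc`, `rna_q`, `class` (factor with the four levels above).
#' @export
linkPeaksToExpression <- function(atlas, atac_diff, rna_diff,
                                  fdr_atac = 0.1, fdr_rna = 0.1) {
  nm <- mcols(atlas)$name
  gene <- mcols(atlas)$nearest_gene
  if (is.null(nm) || is.null(gene)) {
    stop("atlas needs 'name' and 'nearest_gene' columns")
  }
  ai <- match(nm, atac_diff$feature)
  if (anyNA(ai)) stop("peaks missing from the accessibility table")
  ri <- match(gene, rna_diff$feature)
  n_unmatched <- sum(is.na(ri) & !is.na(gene))
  if (n_unmatched) {
    message(n_unmatched,
            " peak(s) with nearest gene absent from expression table; ",
            "classed ns")
  }
  alfc <- atac_diff$log2_fold_change[ai]; aq <- atac_diff$q_value[ai]
  rlfc <- rna_diff$log2_fold_change[ri]; rq <- rna_diff$q_value[ri]
  sig <- !is.na(rq) & aq < fdr_atac & rq < fdr_rna
  cls <- rep("ns", length(nm))
  cls[sig & alfc > 0 & rlfc > 0] <- "concordant_rod"
  cls[sig & alfc < 0 & rlfc < 0] <- "concordant_cone"
  cls[sig & (alfc * rlfc < 0)] <- "discordant"
  td <- mcols(atlas)$tss_distance
  data.frame(peak = nm, gene = gene,
             tss_distance = if (is.null(td)) NA_real_ else td,
             atac_lfc = alfc, atac_q = aq, rna_lfc = rlfc, rna_q = rq,
             class = factor(cls, levels = c("concordant_rod",
                                            "concordant_cone", "discordant",
                                            "ns")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Directional correlation between accessibility and expression
#'
#' Summarizes a link table: per-class counts and the sign-agreement
#' fraction, `concordant / (concordant + discordant)`, over
#' doubly-significant links, with an exact binomial confidence interval.
#'
#' @param links data.frame from [linkPeaksToExpression()].
#' @param conf_level confidence level for the binomial interval.
#' @return list: `counts` (per class), `n_significant`, `sign_agreement`
#'   (NA with a message when no doubly-significant links exist),
#'   `conf_int`.
#' @export
directionalCorrelation <- function(links, conf_level = 0.95) {
  counts <- table(links$class)
  conc <- sum(counts[c("concordant_rod", "concordant_cone")])
  disc <- counts[["discordant"]]
  n_sig <- conc + disc
  if (n_sig == 0L) {
    message("no doubly-significant links; sign agreement undefined")
    return(list(counts = counts, n_significant = 0L,
                sign_agreement = NA_real_, conf_int = c(NA_real_, NA_real_)))
  }
  bt <- binom.test(conc, n_sig, conf.level = conf_level)
  list(counts = counts, n_significant = as.integer(n_sig),
       sign_agreement = conc / n_sig,
       conf_int = as.numeric(bt$conf.int))
}

#' Sample relatedness by Spearman correlation
#'
#' Pairwise Spearman rank correlation of per-feature counts across samples,
#' with average-linkage (UPGMA) hierarchical clustering on the `1 - rho`
#' distance — the standard replicate/relatedness QC for count matrices.
#'
#' @param counts features x samples matrix or `SummarizedExperiment`.
#' @return list: `rho` (symmetric correlation matrix, unit diagonal) and
#'   `tree` (an `hclust` object).
#' @export
sampleRelatedness <- function(counts) {
  counts <- .as_count_matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  sds <- apply(counts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample(s), Spearman undefined: ",
         paste(colnames(counts)[sds == 0], collapse = ", "))
  }
  rho <- cor(counts, method = "spearman")
  tree <- hclust(as.dist(1 - rho), method = "average")
  list(rho = rho, tree = tree)
}
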