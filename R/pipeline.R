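#' Run the full comparative accessibility pipeline
#'
#' Executes the analysis stages in dependency order on a simulated (or
#' equivalently structured) input bundle: atlas construction (merge of
#' per-group peak calls, summit recentering, nearest-TSS annotation,
#' promoter/enhancer partition), differential accessibility (rods vs cones,
#' cone subtypes collapsed) and differential expression, specificity
#' classification with the enhancer filter cascade, global closure ECDFs
#' and per-sample shift summaries (when fragments are present), motif
#' enrichment per specificity class against a composition-matched genomic
#' background, and accessibility-expression integration. Outputs are
#' written under `out_dir` with a manifest recording the configuration
#' hash, and per-stage element counts are logged.
#'
#' @param bundle a bundle from [simulateDataset()] (or a list with the same
#'   members).
#' @param out_dir output directory; created if needed. `NULL` skips file
#'   output.
#' @param fdr_atac,fdr_rna,lfc_threshold differential test settings
#'   (accessibility / expression FDR defaults 0.1 / 0.05).
#' @param fdr_link FDR applied to both tables for the quadrant
#'   classification (default 0.1).
#' @param window_size closure window in bp.
#' @param n_background background sequences per enrichment run.
#' @param stages which optional stages to run: `"auto"` (default) runs
#'   `closure` when fragments are present and `motifs` when a genome and
#'   motif library are present; naming a stage explicitly makes its missing
#'   inputs a fail-fast error.
#' @param verbose print per-stage progress.
#' @return list with `atlas`, `atac_diff`, `rna_diff`, `classified`,
#'   `filter_cascade`, `closure` (per-sample shift table or `NULL`),
#'   `enrichment` (per specificity class), `links`, `directional`,
#'   `relatedness`, `manifest`.
#' @export
runPipeline <- function(bundle, out_dir = NULL, fdr_atac = 0.1,
                        fdr_rna = 0.05, lfc_threshold = 1, fdr_link = 0.1,
                        window_size = 50000L, n_background = 500L,
                        stages = "auto", verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  auto <- identical(stages, "auto")
  want <- function(stage) auto || stage %in% stages
  need <- function(what, stage = NULL) {
    if (is.null(bundle[[what]])) {
      stop("pipeline stage ", if (!is.null(stage)) paste0("'", stage, "' "),
           "requires missing input: '", what, "'")
    }
    bundle[[what]]
  }
  set.seed(bundle$config@seed + 7L)
  log <- list()

  ## stage: atlas
  calls <- need("peak_calls")
  tss <- need("tss")
  atlas <- mergePeakSets(calls)
  say("atlas: ", length(atlas), " merged elements")
  # carry summits over from the constituent calls (max-score source wins)
  pooled <- suppressWarnings(do.call(c, unname(calls)))
  hits <- findOverlaps(atlas, pooled, ignore.strand = TRUE)
  summit <- rep(NA_integer_, length(atlas))
  sc <- mcols(pooled)$score
  if (is.null(sc)) sc <- rep(1, length(pooled))
  qh <- queryHits(hits); sh <- subjectHits(hits)
  ord <- order(sc[sh], decreasing = TRUE)
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  summit[qh[first]] <- mcols(pooled)$summit[sh[first]]
  mcols(atlas)$summit <- summit
  atlas <- nearestTSS(atlas, tss)
  atlas <- partitionPromoterEnhancer(atlas)
  log$atlas_elements <- length(atlas)

  ## stage: differential
  atac_se <- need("atac_counts")
  grp <- as.character(colData(atac_se)$collapsed_group)
  if (!length(grp) || all(is.na(grp))) grp <-
      as.character(colData(atac_se)$group)
  atac_diff <- nbDiffTest(assay(atac_se), "rod", "cone", groups = grp,
                          lfc_threshold = lfc_threshold, fdr = fdr_atac)
  rna_se <- need("rna_counts")
  rna_diff <- nbDiffTest(assay(rna_se), "rod", "cone",
                         groups = as.character(colData(rna_se)$group),
                         lfc_threshold = lfc_threshold, fdr = fdr_rna)
  log$atac_significant <- sum(atac_diff$call != "ns")
  log$rna_significant <- sum(rna_diff$call != "ns")
  say("differential: ", log$atac_significant, " peaks, ",
      log$rna_significant, " genes significant")

  ## stage: specificity classification (on the simulator's peak universe)
  peaks <- need("peaks")
  peaks <- partitionPromoterEnhancer(peaks)
  classified <- classifySpecificity(peaks, atac_diff,
                                    non_pr_peaks = bundle$non_pr_peaks)
  filtered <- classifySpecificity(peaks, atac_diff,
                                  non_pr_peaks = bundle$non_pr_peaks,
                                  filtered = TRUE,
                                  repeats = need("repeats"))
  cascade <- attr(filtered, "filter_cascade")
  log$filter_cascade <- cascade
  say("filter cascade: ", paste(names(cascade), cascade, sep = "=",
                                collapse = ", "))

  ## stage: global closure (requires fragments)
  closure <- NULL
  if (!auto && "closure" %in% stages && is.null(bundle$fragments)) {
    stop("pipeline stage 'closure' requires missing input: 'fragments'")
  }
  if (want("closure") && !is.null(bundle$fragments)) {
    chrom_sizes <- need("chrom_sizes", "closure")
    nfr <- lapply(bundle$fragments, filterNFR)
    wc <- lapply(nfr, windowCoverage, chrom_sizes = chrom_sizes,
                 window_size = window_size)
    ecdfs <- lapply(wc, function(w) coverageEcdf(w$normalized))
    shift_rows <- lapply(names(ecdfs), function(s) {
      refs <- ecdfs[setdiff(names(ecdfs), s)]
      cbind(sample = s, closureShift(ecdfs[[s]], refs))
    })
    closure <- do.call(rbind, shift_rows)
    log$closure_samples <- length(ecdfs)
  }

  ## stage: motif enrichment per specificity class
  enrichment <- NULL
  if (!auto && "motifs" %in% stages &&
      (is.null(bundle$genome) || is.null(bundle$motif_library))) {
    stop("pipeline stage 'motifs' requires missing input: '",
         if (is.null(bundle$genome)) "genome" else "motif_library", "'")
  }
  if (want("motifs") && !is.null(bundle$genome) &&
      !is.null(bundle$motif_library)) {
    genome <- bundle$genome
    lib <- bundle$motif_library
    seq_of <- function(gr) extractSequences(genome, gr)
    spec <- mcols(classified)$specificity
    enh <- mcols(classified)$region_class == "enhancer"
    class_sets <- list(
      rod_specific = classified[spec == "rod_specific" & enh],
      cone_specific = classified[spec == "cone_specific" & enh])
    enrichment <- lapply(class_sets, function(set) {
      if (!length(set)) return(NULL)
      targets <- seq_of(set)
      bg <- sampleMatchedBackground(genome, n = n_background,
                                    length = 200L, targets = targets)
      motifEnrichment(targets, bg, lib)
    })
    say("motif enrichment: ",
        paste(vapply(enrichment, function(e) {
          if (is.null(e)) "-" else e$motif[1L]
        }, character(1L)), collapse = " / "))
  }

  ## stage: integration
  links <- linkPeaksToExpression(peaks, atac_diff, rna_diff,
                                 fdr_atac = fdr_link, fdr_rna = fdr_link)
  directional <- directionalCorrelation(links)
  relatedness <- sampleRelatedness(assay(atac_se))
  log$doubly_significant_links <- directional$n_significant

  manifest <- list(
    package_version = as.character(utils::packageVersion("photoclose")),
    config_hash = .config_hash(bundle$config),
    seed = bundle$config@seed,
    stages = c("atlas", "differential", "classification",
               if (!is.null(closure)) "closure",
               if (!is.null(enrichment)) "motifs", "integration"),
    log = log)

  res <- list(atlas = atlas, atac_diff = atac_diff, rna_diff = rna_diff,
              classified = classified, filtered = filtered,
              filter_cascade = cascade, closure = closure,
              enrichment = enrichment, links = links,
              directional = directional, relatedness = relatedness,
              manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.config_hash <- function(config) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  txt <- paste(deparse(vals), collapse = "")
  # small stable polynomial hash; avoids extra digest dependencies
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  atlas_df <- data.frame(
    chrom = as.character(seqnames(res$atlas)),
    start = start(res$atlas) - 1L, end = end(res$atlas),
    as.data.frame(mcols(res$atlas)))
  atlas_df$sources <- vapply(atlas_df$sources, paste, character(1L),
                             collapse = ",")
  write.table(atlas_df, fp("atlas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeBed(granges(res$atlas), fp("atlas.bed"))
  write.table(res$atac_diff, fp("differential_accessibility.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$rna_diff, fp("differential_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$closure)) {
    write.table(res$closure, fp("closure_shift.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$enrichment)) {
    for (cl in names(res$enrichment)) {
      if (is.null(res$enrichment[[cl]])) next
      write.table(res$enrichment[[cl]],
                  fp(sprintf("motif_enrichment_%s.tsv", cl)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  write.table(res$links, fp("peak_gene_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
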