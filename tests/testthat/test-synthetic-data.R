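test_that("plantMotif writes exactly the requested positions", {
  expect_equal(plantMotif("CCCCCC", "TAAT", 0, "-"), "ATTACC")
  expect_equal(plantMotif("CCCCCC", "TAAT", 2, "+"), "CCTAAT")
  # only [offset, offset + width) changes
  s <- strrep("G", 30)
  out <- plantMotif(s, "TAAT", 10)
  expect_equal(substr(out, 11, 14), "TAAT")
  expect_equal(substr(out, 1, 10), strrep("G", 10))
  expect_equal(substr(out, 15, 30), strrep("G", 16))
  expect_error(plantMotif("CCCC", "TAAT", 1), "exceeds")
  # planting then scanning with the dimer scheme finds the class
  planted <- plantMotif(strrep("C", 30), "TAATGGGATTA", 5)
  expect_equal(scanKmers(planted)$offsets$homotypic_TAAT, 5L)
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(SimConfig(nb_dispersion = 0), "nb_dispersion")
  expect_error(SimConfig(expr_coupling = 1.5), "expr_coupling")
  expect_error(SimConfig(peak_counts = c(shared_PR = -1, rod_specific = 1,
                                         cone_specific = 1, non_PR = 1)),
               ">= 0")
  # domains that cannot fit the genome name the binding constraint
  expect_error(simulateDataset(small_sim_config(
    closed_domain_lengths = 4e6, closed_domain_counts = 1L)),
    "domain")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_sim_config(seed = 77L,
                          peak_counts = c(shared_PR = 60L,
                                          rod_specific = 15L,
                                          cone_specific = 30L,
                                          non_PR = 15L),
                          genome_length = 1e6, n_chromosomes = 1L,
                          closed_domain_lengths = 2e5,
                          closed_domain_counts = 1L,
                          n_genes = 80L, cre_n_constructs = 50L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateDataset(cfg), d1)
  writeSimulation(simulateDataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) > 8)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("an empty cone class propagates as zero cone-specific calls", {
  cfg <- small_sim_config(seed = 9L,
                          peak_counts = c(shared_PR = 150L,
                                          rod_specific = 30L,
                                          cone_specific = 0L,
                                          non_PR = 30L))
  b <- simulateDataset(cfg, fragments = FALSE)
  expect_false("cone_specific" %in% b$truth$peak_classes)
  atac <- SummarizedExperiment::assay(b$atac_counts)
  grp <- as.character(
    SummarizedExperiment::colData(b$atac_counts)$collapsed_group)
  diff <- nbDiffTest(atac, "rod", "cone", groups = grp)
  expect_equal(sum(diff$call == "B_up"), 0L)
})

test_that("class-conditional coverage matches the planted design", {
  b <- cached_small_sim()
  atac <- SummarizedExperiment::assay(b$atac_counts)
  grp <- as.character(
    SummarizedExperiment::colData(b$atac_counts)$collapsed_group)
  cls <- b$truth$peak_classes[rownames(atac)]
  cone_pk <- cls == "cone_specific"
  rod_mean <- mean(atac[cone_pk, grp == "rod"])
  cone_mean <- mean(atac[cone_pk, grp == "cone"])
  expect_lt(rod_mean, cone_mean)
  # rod-specific peaks show the mirrored pattern
  rod_pk <- cls == "rod_specific"
  expect_gt(mean(atac[rod_pk, grp == "rod"]),
            mean(atac[rod_pk, grp == "cone"]))
})

test_that("every planted motif is recoverable from the emitted FASTA", {
  b <- cached_small_sim()
  pm <- b$truth$planted_motifs
  expect_gt(nrow(pm), 100)
  seqs <- extractSequences(b$genome, b$peaks)
  lib <- b$motif_library
  iupac <- c(W = "[AT]", N = ".")
  ok <- vapply(seq_len(nrow(pm)), function(i) {
    m <- lib[[pm$motif[i]]]
    word <- motifConsensus(m)
    if (pm$strand[i] == "-") {
      word <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(word)))
    }
    pat <- word
    for (code in names(iupac)) pat <- gsub(code, iupac[[code]], pat)
    found <- substr(seqs[[pm$peak[i]]], pm$offset[i] + 1,
                    pm$offset[i] + motifWidth(m))
    grepl(paste0("^", pat, "$"), found)
  }, logical(1))
  expect_true(all(ok))
})

test_that("fragment counts reconcile with the NB count matrix", {
  b <- cached_small_sim()
  atac <- SummarizedExperiment::assay(b$atac_counts)
  s <- "rod_rep1"
  nfr <- filterNFR(b$fragments[[s]])
  # midpoint counts over peaks equal the drawn NB counts plus genome-wide
  # background that happens to fall inside peaks
  mid <- GRanges(seqnames(nfr),
                 IRanges((start(nfr) + end(nfr)) %/% 2L, width = 1L))
  ov <- countOverlaps(b$peaks, mid)
  expect_gte(cor(ov, atac[, s]), 0.98)
  expect_true(all(ov >= atac[, s])) # background only adds
  # nucleosomal fragments exist and are removed by the NFR filter
  expect_gt(length(b$fragments[[s]]), length(nfr))
  expect_true(all(mcols(nfr)$insert_size <= 100))
})

test_that("rod background fragments are depleted inside closed domains", {
  b <- cached_small_sim()
  dom <- b$truth$domains
  dens <- function(s) {
    fr <- filterNFR(b$fragments[[s]])
    inside <- sum(countOverlaps(fr, dom) > 0)
    inside / sum(width(dom))
  }
  expect_lt(dens("rod_rep1"), dens("green_cone_rep1") / 2)
})

test_that("native homotypic-dimer constructs carry the repression shift", {
  b <- cached_small_sim()
  cre <- b$cre_table
  labels <- b$truth$cre_kmer_labels
  has <- vapply(labels[cre$construct_id], function(k) {
    "homotypic_TAAT" %in% k
  }, logical(1))
  native <- cre$variant_class == "native"
  shift <- mean(cre$expression[native & has]) -
    mean(cre$expression[native & !has])
  expect_lt(shift, -0.7) # planted effect of 1 unit
  mutant <- cre$variant_class == "crx_mutant"
  shift_mut <- mean(cre$expression[mutant & has]) -
    mean(cre$expression[mutant & !has])
  expect_lt(abs(shift_mut), 0.3)
})
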