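test_that("narrowPeak reader maps column 10 to absolute summits", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\t300\tpeakA\t500\t+\t8.5\t-1\t-1\t50",
    "chr1\t1000\t1400\tpeakB\t200\t.\t3.1\t-1\t-1\t-1"), f)
  gr <- readNarrowPeak(f)
  expect_length(gr, 2L)
  # 0-based summit = start + offset = 150
  expect_equal(mcols(gr)$summit[1L] - 1L, 150L)
  expect_true(is.na(mcols(gr)$summit[2L]))
  expect_equal(start(gr), c(101L, 1001L)) # 1-based in memory
  expect_equal(end(gr), c(300L, 1400L))
})

test_that("narrowPeak parse errors name the line and field", {
  f <- withr::local_tempfile()
  writeLines("chr1\t300\t100\tp\t0\t.\t0\t-1\t-1\t5", f)
  expect_error(readNarrowPeak(f), "line 1.*end.*start")
  writeLines("chr1\t100\t300\tp\t0\t.\t0\t-1\t-1\t250", f)
  expect_error(readNarrowPeak(f), "summit offset.*outside")
  writeLines("chr1\t100\t300", f)
  expect_error(readNarrowPeak(f), "line 1.*3 field")
})

test_that("narrowPeak, BED and fragment round trips are byte-identical", {
  lines <- c("chr1\t100\t300\tpk1\t500\t+\t8.5\t-1\t-1\t50",
             "chr2\t0\t200\tpk2\t10\t-\t1\t-1\t-1\t-1")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(lines, f1)
  writeNarrowPeak(readNarrowPeak(f1), f2)
  expect_identical(readLines(f2), lines)

  bed <- c("chr1\t10\t20\tr1\t0\t+", "chr1\t30\t40\tr2\t5\t-")
  writeLines(bed, f1)
  writeBed(readBed(f1), f2)
  expect_identical(readLines(f2), bed)

  frg <- c("chr1\t0\t80", "chr1\t500\t720")
  writeLines(frg, f1)
  writeFragments(readFragments(f1), f2)
  expect_identical(readLines(f2), frg)
})

test_that("FASTA and motif-file round trips are lossless", {
  seqs <- DNAStringSet(c(chrA = "ACGTACGTAC", chrB = "TTTTGGGGCC"))
  f <- withr::local_tempfile()
  writeXStringSet(seqs, f)
  expect_identical(as.character(readDNAStringSet(f)),
                   as.character(seqs))

  lib <- MotifLibrary(consensus_pwm("m1", "TAAT"),
                      consensus_pwm("m2", "CTAATCC"))
  fm <- withr::local_tempfile()
  writeHomerMotifs(lib, fm)
  lib2 <- readHomerMotifs(fm)
  expect_identical(names(lib2), c("m1", "m2"))
  expect_equal(motifMatrix(lib2[["m1"]]), motifMatrix(lib[["m1"]]),
               tolerance = 1e-5)
  # a second round trip reproduces the file byte-for-byte
  fm2 <- withr::local_tempfile()
  writeHomerMotifs(lib2, fm2)
  expect_identical(readLines(fm2), readLines(fm))
})

test_that("recenterOnSummit produces fixed-width summit-centered windows", {
  pk <- GRanges("chr1", IRanges(800, 1200))
  mcols(pk)$summit <- 1001L # 0-based position 1000
  out <- recenterOnSummit(pk, width = 200L)
  expect_equal(start(out) - 1L, 900L) # 0-based [900, 1100)
  expect_equal(end(out), 1100L)

  # near-boundary windows shift inward instead of truncating
  pk2 <- GRanges("chr1", IRanges(10, 120))
  mcols(pk2)$summit <- 51L
  out2 <- recenterOnSummit(pk2, width = 200L, chrom_sizes = c(chr1 = 5000L))
  expect_equal(start(out2) - 1L, 0L)
  expect_equal(end(out2), 200L)

  expect_error(recenterOnSummit(pk, width = 0L), "width")
  mcols(pk)$summit <- NA_integer_
  mcols(pk)$name <- "pkX"
  expect_error(recenterOnSummit(pk), "pkX")
})

test_that("mergePeakSets coalesces overlaps and is idempotent/commutative", {
  a <- GRanges("chr1", IRanges(101, 300)) # 0-based [100, 300)
  b <- GRanges("chr1", IRanges(251, 400)) # 0-based [250, 400)
  atlas <- mergePeakSets(list(s1 = a, s2 = b))
  expect_length(atlas, 1L)
  expect_equal(c(start(atlas) - 1L, end(atlas)), c(100L, 400L))
  expect_equal(mcols(atlas)$n_sources, 2L)

  disjoint <- mergePeakSets(list(GRanges("chr1", IRanges(1, 100)),
                                 GRanges("chr1", IRanges(201, 300))))
  expect_length(disjoint, 2L)

  # idempotence: a set merged with itself is itself
  self <- mergePeakSets(list(a = a, b = a))
  expect_equal(granges(self), granges(mergePeakSets(list(a))))

  # commutativity + covered-bp bound on random sets
  set.seed(42)
  for (i in 1:5) {
    s1 <- reduce(random_peaks(30)); s2 <- reduce(random_peaks(30))
    m12 <- mergePeakSets(list(x = s1, y = s2))
    m21 <- mergePeakSets(list(y = s2, x = s1))
    expect_equal(granges(m12), granges(m21))
    expect_lte(sum(width(m12)), sum(width(s1)) + sum(width(s2)))
  }
})

test_that("filterNFR keeps inserts at or below the cutoff, preserving order", {
  fr <- GRanges("chr1", IRanges(c(1, 10, 20), width = c(50, 100, 101)))
  mcols(fr)$insert_size <- c(50L, 100L, 101L)
  out <- filterNFR(fr)
  expect_equal(mcols(out)$insert_size, c(50L, 100L)) # 101 removed, 100 kept
  expect_length(filterNFR(fr[0]), 0L)
  expect_length(filterNFR(fr, max_insert = Inf), 3L)
})

test_that("nearestTSS matches forced geometry and the brute-force oracle", {
  pk <- GRanges("chr1", IRanges(4901, 5100))
  mcols(pk)$summit <- 5000L
  tss <- GRanges("chr1", IRanges(c(4000, 7000), width = 1),
                 strand = c("+", "+"))
  mcols(tss)$name <- c("geneA", "geneB")
  out <- nearestTSS(pk, tss)
  expect_equal(mcols(out)$nearest_gene, "geneA")
  expect_equal(mcols(out)$tss_distance, 1000) # downstream of geneA TSS

  # summit exactly at a TSS
  mcols(pk)$summit <- 4000L
  expect_equal(mcols(nearestTSS(pk, tss))$tss_distance, 0)

  # random instances vs exhaustive all-pairs scan
  set.seed(7)
  for (rep in 1:4) {
    pks <- random_peaks(100)
    tsss <- random_tss(20)
    got <- nearestTSS(pks, tsss)
    anchor <- mcols(pks)$summit
    pchr <- as.character(seqnames(pks))
    tchr <- as.character(seqnames(tsss))
    tstr <- as.character(strand(tsss))
    for (i in seq_along(pks)) {
      j <- which(tchr == pchr[i])
      d <- abs(anchor[i] - start(tsss)[j])
      cand <- j[d == min(d)]
      best <- cand[order(mcols(tsss)$name[cand])][1L]
      expect_identical(mcols(got)$nearest_gene[i],
                       mcols(tsss)$name[best])
      delta <- anchor[i] - start(tsss)[best]
      expect_equal(mcols(got)$tss_distance[i],
                   if (tstr[best] == "-") -delta else delta)
    }
  }
})

test_that("peaks on TSS-free chromosomes get NA with a warning", {
  pk <- random_peaks(3, chroms = "chrZ")
  tss <- random_tss(5, chroms = "chr1")
  expect_warning(out <- nearestTSS(pk, tss), "without any TSS")
  expect_true(all(is.na(mcols(out)$nearest_gene)))
  expect_true(all(is.infinite(mcols(out)$tss_distance)))
})

test_that("extractSequences pulls the forward-strand sequence", {
  genome <- DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  gr <- GRanges("chr1", IRanges(4, 9))
  mcols(gr)$name <- "x"
  expect_identical(extractSequences(genome, gr), c(x = "CCCGGG"))
  expect_error(extractSequences(genome, GRanges("chr9", IRanges(1, 2))),
               "chr9")
})
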