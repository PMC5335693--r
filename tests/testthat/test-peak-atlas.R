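test_that("quantifySignal places forced fragments in the expected bin", {
  el <- GRanges("chr1", IRanges(4901, 5100))
  mcols(el)$summit <- 5000L
  mcols(el)$name <- "e1"
  # one fragment whose midpoint sits exactly at the summit
  fr <- GRanges("chr1", IRanges(4971, 5030))
  m <- quantifySignal(el, fr, window = 3000L, bin_width = 5L)
  expect_equal(sum(m), 1)
  # midpoint at summit falls in the center-right bin (bin 301 of 600,
  # i.e. 0-based bin 300)
  expect_equal(unname(which(m[1, ] == 1) - 1L), 300L)

  empty <- quantifySignal(el, fr[0], window = 3000L, bin_width = 5L)
  expect_true(all(empty == 0))
  expect_error(quantifySignal(el, fr, window = 3000L, bin_width = 7L),
               "divisible")
  el2 <- el; mcols(el2)$summit <- NA_integer_
  expect_error(quantifySignal(el2, fr), "summit")
})

test_that("quantifySignal matches a naive per-bin rescan", {
  set.seed(11)
  els <- random_peaks(12)
  frs <- GRanges(sample(c("chr1", "chr2"), 400, replace = TRUE),
                 IRanges(sample.int(999000, 400), width = 80L))
  window <- 1000L; bw <- 10L
  m <- quantifySignal(els, frs, window = window, bin_width = bw)
  mid <- (start(frs) + end(frs)) %/% 2L
  fchr <- as.character(seqnames(frs))
  for (i in seq_along(els)) {
    lo <- mcols(els)$summit[i] - window / 2
    for (j in seq_len(window / bw)) {
      b0 <- lo + (j - 1) * bw
      expected <- sum(fchr == as.character(seqnames(els))[i] &
                        mid >= b0 & mid < b0 + bw)
      expect_equal(unname(m[i, j]), expected)
    }
  }
})

test_that("promoter/enhancer partition follows the strict distance bounds", {
  el <- GRanges("chr1", IRanges(rep(1, 6), width = 200))
  mcols(el)$tss_distance <- c(-500, 2000, 0, -1000, 99, 100)
  out <- partitionPromoterEnhancer(el)
  expect_equal(as.character(mcols(out)$region_class),
               c("promoter", "enhancer", "promoter",
                 "enhancer",          # exactly -1000 is outside (strict <)
                 "promoter", "enhancer")) # +100 is outside (strict <)
  # partition is exhaustive and exclusive
  expect_false(anyNA(mcols(out)$region_class))
})

test_that("repeat filter drops elements above 70% overlap, keeps 70% exactly", {
  els <- GRanges("chr1", IRanges(c(1, 1001, 2001), width = 200))
  mcols(els)$name <- c("over", "at", "free")
  reps <- GRanges("chr1", IRanges(c(1, 1001), width = c(150, 140)))
  out <- repeatFilter(els, reps)
  expect_identical(mcols(out)$name, c("at", "free"))
  expect_equal(mcols(repeatFraction(els, reps))$repeat_fraction,
               c(0.75, 0.70, 0))
  # no repeats: identity
  expect_length(repeatFilter(els, GRanges()), 3L)
})

test_that("overlapFraction is asymmetric and matches brute force", {
  a <- GRanges("chr1", IRanges(c(1, 101, 301), width = 50))
  expect_equal(overlapFraction(a, a), 1)
  b <- c(a, GRanges("chr1", IRanges(c(1001, 2001, 3001), width = 50)))
  expect_equal(overlapFraction(a, b), 1)
  expect_equal(overlapFraction(b, a), 0.5)
  expect_error(overlapFraction(GRanges(), a), "empty")

  set.seed(3)
  x <- random_peaks(40); y <- random_peaks(25)
  brute <- mean(vapply(seq_along(x), function(i) {
    any(as.character(seqnames(y)) == as.character(seqnames(x))[i] &
          start(y) <= end(x)[i] & end(y) >= start(x)[i])
  }, logical(1L)))
  expect_equal(overlapFraction(x, y), brute)
})

test_that("specificity classification maps calls and non-PR overlap", {
  els <- GRanges("chr1", IRanges(c(1, 1001, 2001), width = 200))
  mcols(els)$name <- c("p1", "p2", "p3")
  diff <- data.frame(feature = c("p1", "p2", "p3"),
                     log2_fold_change = c(2, -2, 0),
                     q_value = c(0.01, 0.01, 0.9),
                     call = factor(c("A_up", "B_up", "ns"),
                                   levels = c("A_up", "B_up", "ns")))
  out <- classifySpecificity(els, diff)
  expect_equal(as.character(mcols(out)$specificity),
               c("rod_specific", "cone_specific", "shared_PR"))
  # overlap with a non-photoreceptor peak set overrides the call
  liver <- GRanges("chr1", IRanges(2050, 2100))
  out2 <- classifySpecificity(els, diff, non_pr_peaks = list(liver = liver))
  expect_equal(as.character(mcols(out2)$specificity)[3], "non_PR")
  # element missing from the differential table is an error
  expect_error(classifySpecificity(els, diff[-2, ]), "p2")
})

test_that("filter cascade counts are monotone non-increasing", {
  b <- cached_small_sim()
  atac <- SummarizedExperiment::assay(b$atac_counts)
  grp <- as.character(SummarizedExperiment::colData(b$atac_counts)$collapsed_group)
  diff <- suppressWarnings(nbDiffTest(atac, "rod", "cone", groups = grp))
  pk <- partitionPromoterEnhancer(b$peaks)
  filtered <- classifySpecificity(pk, diff, non_pr_peaks = b$non_pr_peaks,
                                  filtered = TRUE, repeats = b$repeats)
  cascade <- attr(filtered, "filter_cascade")
  expect_named(cascade, c("all", "non_promoter", "photoreceptor_only",
                          "repeat_filtered"))
  expect_true(all(diff(cascade) <= 0))
  expect_equal(unname(cascade["repeat_filtered"]), length(filtered))
})
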