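test_that("scan behaves on uniform and consensus-only PWMs", {
  unif <- PWMotif("unif", matrix(0.25, 4, 4))
  seqs <- c(s1 = "ACGTACGTAC")
  hits <- scanMotif(seqs, unif, threshold = 0)
  # every position on both strands scores exactly 0
  expect_equal(nrow(hits), 2 * (10 - 4 + 1))
  expect_true(all(hits$score == 0))

  cons <- consensus_pwm("cons", "TAAT")
  s <- c(x = "CCTAATCCATTACC") # TAAT at 2 (0-based), ATTA (rc) at 8
  h <- scanMotif(s, cons, threshold = 4)
  h <- h[order(h$offset), ]
  expect_equal(h$offset, c(2L, 8L))
  expect_equal(h$strand, c("+", "-"))
})

test_that("scan matches brute-force per-position rescoring", {
  set.seed(6)
  for (rep in 1:3) {
    w <- sample(4:7, 1)
    mat <- matrix(rexp(4 * w), 4, w)
    pwm <- PWMotif(sprintf("r%d", rep), sweep(mat, 2, colSums(mat), "/"))
    seqs <- random_dna(4, 60)
    names(seqs) <- paste0("s", 1:4)
    got <- scanMotif(seqs, pwm, threshold = -2)
    got <- got[order(got$seq_id, got$strand, got$offset), ]
    S <- log(motifMatrix(pwm) / 0.25)
    Src <- S[4:1, w:1]
    brute <- list()
    for (nm in names(seqs)) {
      v <- strsplit(seqs[[nm]], "")[[1]]
      idx <- match(v, c("A", "C", "G", "T"))
      for (p in seq_len(length(v) - w + 1)) {
        sc_f <- sum(S[cbind(idx[p:(p + w - 1)], 1:w)])
        sc_r <- sum(Src[cbind(idx[p:(p + w - 1)], 1:w)])
        if (sc_f >= -2) brute[[length(brute) + 1]] <-
            data.frame(seq_id = nm, offset = p - 1L, strand = "+",
                       score = sc_f)
        if (sc_r >= -2) brute[[length(brute) + 1]] <-
            data.frame(seq_id = nm, offset = p - 1L, strand = "-",
                       score = sc_r)
      }
    }
    brute <- do.call(rbind, brute)
    brute <- brute[order(brute$seq_id, brute$strand, brute$offset), ]
    expect_equal(got$offset, brute$offset)
    expect_equal(got$strand, brute$strand)
    expect_equal(got$score, brute$score, tolerance = 1e-10)
  }
})

test_that("scanning is strand-symmetric", {
  set.seed(14)
  pwm <- consensus_pwm("crx", "CTAATCC", p = 0.9)
  seqs <- random_dna(20, 120)
  names(seqs) <- paste0("s", 1:20)
  rc <- vapply(seqs, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1))
  h1 <- scanMotif(seqs, pwm, threshold = 3)
  h2 <- scanMotif(rc, pwm, threshold = 3)
  expect_equal(nrow(h1), nrow(h2))
  # mirrored coordinates: offset' = L - w - offset, strand flipped
  m1 <- sort(paste(h1$seq_id, 120 - 7 - h1$offset,
                   ifelse(h1$strand == "+", "-", "+")))
  m2 <- sort(paste(h2$seq_id, h2$offset, h2$strand))
  expect_equal(m1, m2)
})

test_that("N bases score as background and do not create hits", {
  cons <- consensus_pwm("m", "TAAT")
  h <- scanMotif(c(x = "NNNNNNNN"), cons, threshold = 1)
  expect_equal(nrow(h), 0L)
})

test_that("low-information flanks are trimmed with a strict cutoff", {
  core <- consensus_pwm("core", "TAAT", p = 0.997)
  flank <- matrix(0.25, 4, 2)
  padded <- PWMotif("padded", cbind(flank, motifMatrix(core), flank))
  trimmed <- trimLowInfo(padded)
  expect_equal(motifWidth(trimmed), 4L)
  expect_equal(motifConsensus(trimmed), "TAAT")

  expect_equal(motifMatrix(trimLowInfo(core)), motifMatrix(core))
  expect_error(trimLowInfo(PWMotif("u", matrix(0.25, 4, 3))), "information")

  # strictness: a column at exactly the threshold is kept
  half <- PWMotif("h", matrix(c(.5, .5, 0, 0), 4, 1), epsilon = 0.001)
  ic <- 2 + sum(motifMatrix(half) * log2(motifMatrix(half)))
  expect_equal(motifWidth(trimLowInfo(half, min_bits = ic)), 1L)
  expect_error(trimLowInfo(half, min_bits = ic + 1e-9), "information")
})

test_that("redundancy collapse absorbs duplicates and reverse complements", {
  a <- consensus_pwm("a", "CTAATCC", score = 10)
  dup <- consensus_pwm("a_dup", "CTAATCC", score = 5)
  rc <- PWMotif("a_rc", motifMatrix(reverseComplement(a)), score = 1)
  other <- consensus_pwm("sp1", "GGGGCGGGG", score = 8)
  res <- collapseRedundant(MotifLibrary(a, dup, rc, other))
  expect_setequal(names(res$seeds), c("a", "sp1"))
  expect_equal(res$mapping$seed[res$mapping$member == "a_dup"], "a")
  expect_equal(res$mapping$seed[res$mapping$member == "a_rc"], "a")
  # every member maps to exactly one seed
  expect_true(all(res$mapping$seed %in% names(res$seeds)))
  expect_lte(length(res$seeds), 4L)
})

test_that("redundancy collapse matches an exhaustive oracle", {
  set.seed(31)
  mots <- lapply(1:12, function(i) {
    m <- matrix(rexp(4 * 6), 4, 6)
    PWMotif(sprintf("m%02d", i), sweep(m, 2, colSums(m), "/"),
            score = runif(1))
  })
  lib <- MotifLibrary(mots)
  res <- collapseRedundant(lib, pcc_threshold = 0.6)

  # oracle: independent similarity computation + greedy absorption
  osim <- function(m1, m2) {
    best <- -1
    rc <- function(m) m[4:1, rev(seq_len(ncol(m)))]
    for (mm in list(m2, rc(m2))) {
      for (off in -(ncol(mm) - 1):(ncol(m1) - 1)) {
        i1 <- max(1, 1 + off):min(ncol(m1), ncol(mm) + off)
        if (length(i1) < 4) next
        v1 <- as.vector(m1[, i1]); v2 <- as.vector(mm[, i1 - off])
        if (sd(v1) > 0 && sd(v2) > 0) best <- max(best, cor(v1, v2))
      }
    }
    best
  }
  nms <- names(lib)
  scores <- vapply(as.list(lib), motifScore, numeric(1))
  assigned <- setNames(rep(NA_character_, 12), nms)
  for (i in order(-scores, nms)) {
    if (!is.na(assigned[i])) next
    assigned[i] <- nms[i]
    for (j in which(is.na(assigned))) {
      if (osim(motifMatrix(lib[[i]]), motifMatrix(lib[[j]])) > 0.6) {
        assigned[j] <- nms[i]
      }
    }
  }
  expect_setequal(names(res$seeds), unique(assigned))
  expect_equal(res$mapping$seed, unname(assigned[res$mapping$member]))
})

test_that("co-occurrence enrichment matches hand-computed instances", {
  universe <- sprintf("p%03d", 1:100)
  hits <- rbind(
    data.frame(seq_id = universe[1:50], motif = "m1", offset = 0L),
    data.frame(seq_id = universe[41:60], motif = "m2", offset = 10L))
  cc <- motifCooccurrence(hits, universe)
  expect_equal(unname(cc$n), c(50, 20))
  expect_equal(cc$expected["m1", "m2"], 10) # 50*20/100
  expect_equal(cc$observed["m1", "m2"], 10)
  expect_equal(cc$enrichment["m1", "m2"], 0) # independence

  hits2 <- rbind(
    data.frame(seq_id = universe[1:50], motif = "m1", offset = 0L),
    data.frame(seq_id = universe[31:50], motif = "m2", offset = 10L))
  cc2 <- motifCooccurrence(hits2, universe)
  expect_equal(cc2$observed["m1", "m2"], 20)
  expect_equal(cc2$enrichment["m1", "m2"], 1) # log2(20/10)

  # absent pair is a -Inf sentinel; matrix is symmetric
  hits3 <- rbind(data.frame(seq_id = universe[1:10], motif = "m1",
                            offset = 0L),
                 data.frame(seq_id = universe[11:20], motif = "m2",
                            offset = 0L))
  cc3 <- motifCooccurrence(hits3, universe)
  expect_equal(cc3$enrichment["m1", "m2"], -Inf)
  expect_equal(cc3$enrichment, t(cc3$enrichment))
  expect_error(motifCooccurrence(hits, character(0)), "empty")
})

test_that("central density profiles localize planted motifs", {
  set.seed(12)
  crx <- consensus_pwm("crx", "CTAATCC")
  seqs <- random_dna(40, 200)
  # plant at the exact center of every sequence
  seqs <- vapply(seqs, function(s) plantMotif(s, crx, 97L), character(1))
  names(seqs) <- paste0("s", 1:40)
  prof <- centralDensityProfile(seqs, crx, bin_width = 5)
  peak_bin <- which.max(prof$density)
  expect_lt(abs(prof$position[peak_bin]), 5.1)
  expect_gte(max(prof$density), 0.9)

  none <- centralDensityProfile(c(a = strrep("C", 200)), crx)
  expect_true(all(none$density == 0))
  expect_error(centralDensityProfile(c(a = "ACGT", b = "ACGTAC"), crx),
               "equal width")
})

test_that("spacing profiles recover forced secondary placement", {
  set.seed(18)
  crx <- consensus_pwm("crx", "CTAATCC")
  nr <- consensus_pwm("nr", "AGGTCA")
  seqs <- random_dna(30, 120)
  # secondary always starts 10 bp downstream of the primary, same strand
  seqs <- vapply(seqs, function(s) {
    s <- plantMotif(s, crx, 40L)
    plantMotif(s, nr, 50L)
  }, character(1))
  names(seqs) <- paste0("s", 1:30)
  prof <- spacingProfile(seqs, crx, nr, threshold = 5)
  same <- prof[prof$relative_strand == "same", ]
  expect_equal(same$offset[which.max(same$count)], 10L)
  expect_gte(max(same$count), 30 * 0.9)

  # a motif against itself: the anchor hit is masked, no spike at 0
  self <- spacingProfile(seqs, crx, crx, threshold = 5)
  if (nrow(self)) expect_false(any(self$offset == 0 & self$count > 5))

  expect_warning(
    empty <- spacingProfile(c(a = strrep("C", 50)), crx, nr),
    "no primary")
  expect_equal(nrow(empty), 0L)
})

test_that("matched background shifts composition toward the targets", {
  set.seed(27)
  # AT-rich genome, moderately GC-richer targets
  genome <- DNAStringSet(c(chr1 = paste(random_dna(1, 200000, gc = 0.40),
                                        collapse = "")))
  targets <- random_dna(150, 200, gc = 0.46)
  bg <- suppressWarnings(
    sampleMatchedBackground(genome, n = 200, length = 200,
                            targets = targets, tol = 0.05,
                            oversample = 20L))
  gc_of <- function(x) {
    f <- Biostrings::oligonucleotideFrequency(DNAStringSet(x), 1)
    sum(f[, c("C", "G")]) / sum(f)
  }
  gc_t <- gc_of(targets)
  gc_bg <- gc_of(as.character(bg))
  gc_genome <- 0.40
  # background moved from genome composition toward the target
  expect_lt(abs(gc_bg - gc_t), abs(gc_genome - gc_t) / 2)
  expect_error(sampleMatchedBackground(genome, n = 10000, length = 200,
                                       targets = targets),
               "too short")
})

test_that("motif enrichment ranks a planted motif above decoys", {
  set.seed(33)
  crx <- consensus_pwm("crx", "CTAATCC")
  lib <- MotifLibrary(crx, consensus_pwm("gata", "GATAAG"),
                      consensus_pwm("ebox", "CATATG"))
  bg <- random_dna(150, 200); names(bg) <- paste0("b", seq_along(bg))
  tg <- random_dna(150, 200)
  tg <- vapply(tg, function(s) plantMotif(s, crx, sample(0:190, 1)),
               character(1))
  names(tg) <- paste0("t", seq_along(tg))
  enr <- motifEnrichment(tg, bg, lib)
  expect_equal(enr$motif[1], "crx")
  expect_gt(enr$ratio[1], 2)
  expect_lt(enr$p_value[1], 1e-10)
})
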