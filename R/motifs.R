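#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   subseq oligonucleotideFrequency
#' @importFrom stats cor phyper rbinom runif stepfun
NULL

.seq_codes <- function(s) {
  # A,C,G,T -> 1..4, anything else (N) -> 5
  code <- rep(5L, 256L)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  code[utf8ToInt(s)]
}

.as_char_seqs <- function(sequences) {
  nm <- names(sequences)
  s <- as.character(sequences)
  names(s) <- nm # as.character() drops names on plain vectors
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  s
}

.scan_one_strand <- function(codes, S5) {
  w <- ncol(S5)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_pos <- L - w + 1L
  sc <- numeric(n_pos)
  for (k in seq_len(w)) {
    sc <- sc + S5[codes[k:(k + n_pos - 1L)], k]
  }
  sc
}

#' Scan sequences with a PWM
#'
#' Scores every position of every sequence on both strands with natural-log
#' odds `sum(log(p_base / q_base))` and reports positions at or above the
#' threshold. `N` positions contribute 0 to the score. Reverse-strand hits
#' are reported at the forward-strand coordinate of the match start.
#'
#' @param sequences `DNAStringSet` or character vector (named).
#' @param pwm a [PWMotif].
#' @param threshold log-odds threshold; defaults to the motif's own.
#' @return data.frame of hits: `seq_id`, `offset` (0-based match start on
#'   the forward strand), `strand` (`+`/`-`), `score`, `motif`.
#' @export
scanMotif <- function(sequences, pwm, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm@threshold
  s <- .as_char_seqs(sequences)
  S <- log(motifMatrix(pwm) / pwm@background)
  S5 <- rbind(S, 0)                      # row 5: N scores 0
  rcS <- log(motifMatrix(reverseComplement(pwm)) / pwm@background)
  rcS5 <- rbind(rcS, 0)
  out <- vector("list", length(s))
  for (i in seq_along(s)) {
    codes <- .seq_codes(s[[i]])
    fw <- .scan_one_strand(codes, S5)
    rv <- .scan_one_strand(codes, rcS5)
    hit_f <- which(fw >= threshold)
    hit_r <- which(rv >= threshold)
    if (length(hit_f) + length(hit_r)) {
      out[[i]] <- data.frame(
        seq_id = names(s)[i],
        offset = c(hit_f, hit_r) - 1L,
        strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
        score = c(fw[hit_f], rv[hit_r]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  res$motif <- rep(motifName(pwm), nrow(res))
  res
}

.comp_features <- function(seqs) {
  # per-sequence mono (4) and di (16) nucleotide counts
  x <- DNAStringSet(seqs)
  cbind(oligonucleotideFrequency(x, 1L), oligonucleotideFrequency(x, 2L))
}

.comp_l1 <- function(counts_a, counts_b) {
  fa1 <- colSums(counts_a[, 1:4, drop = FALSE])
  fb1 <- colSums(counts_b[, 1:4, drop = FALSE])
  fa2 <- colSums(counts_a[, 5:20, drop = FALSE])
  fb2 <- colSums(counts_b[, 5:20, drop = FALSE])
  max(sum(abs(fa1 / sum(fa1) - fb1 / sum(fb1))),
      sum(abs(fa2 / sum(fa2) - fb2 / sum(fb2))))
}

#' Sample composition-matched background sequences
#'
#' Draws fixed-length intervals uniformly from the genome, rejects draws
#' with more than `max_masked` masked (`N`) bases, and importance-resamples
#' the pool so that the aggregate mono- and di-nucleotide composition
#' matches the target set within an L1 tolerance. Used as the null set for
#' motif enrichment, mirroring the standard practice of ~50,000 random
#' 200 bp genomic intervals normalized for nucleotide content.
#'
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param n number of background sequences to return.
#' @param length interval length in bp (default 200).
#' @param targets target sequences (`DNAStringSet` or character) whose
#'   composition is to be matched.
#' @param tol L1 tolerance on each of the mono- and di-nucleotide frequency
#'   vectors (default 0.05).
#' @param max_masked reject draws with a masked-base fraction above this.
#' @param oversample candidate pool size as a multiple of `n`.
#' @return `DNAStringSet` of `n` background sequences; attribute
#'   `achieved_l1` records the final mismatch.
#' @export
sampleMatchedBackground <- function(genome, n = 1000L, length = 200L,
                                    targets, tol = 0.05, max_masked = 0.70,
                                    oversample = 8L) {
  genome <- .as_char_seqs(genome)
  lens <- nchar(genome)
  if (sum(lens) < n * length) {
    stop("genome too short to host ", n, " background intervals of ",
         length, " bp")
  }
  m <- n * oversample
  chr_p <- pmax(lens - length + 1L, 0L)
  chr_idx <- sample(seq_along(genome), m, replace = TRUE,
                    prob = chr_p / sum(chr_p))
  starts <- floor(runif(m) * chr_p[chr_idx]) + 1L
  cand <- substring(genome[chr_idx], starts, starts + length - 1L)
  n_frac <- 1 - (.comp_features(cand)[, 1:4, drop = FALSE] |> rowSums()) /
    length
  keep <- n_frac <= max_masked
  cand <- cand[keep]
  if (length(cand) < n) stop("too few unmasked candidate intervals")
  names(cand) <- sprintf("bg_%06d", seq_along(cand))
  feats <- .comp_features(cand)
  tfeats <- .comp_features(.as_char_seqs(targets))
  # rank candidates by target-vs-pool composition log-likelihood and slide
  # a rank window of size n from "strongest shift" toward "no shift",
  # keeping the offset whose aggregate composition best matches the target
  pseudo <- 0.5
  tfreq <- colSums(tfeats) + pseudo
  pfreq <- colSums(feats) + pseudo
  tfreq[1:4] <- tfreq[1:4] / sum(tfreq[1:4])
  tfreq[5:20] <- tfreq[5:20] / sum(tfreq[5:20])
  pfreq[1:4] <- pfreq[1:4] / sum(pfreq[1:4])
  pfreq[5:20] <- pfreq[5:20] / sum(pfreq[5:20])
  score <- as.vector(feats %*% log(tfreq / pfreq))
  ord <- order(score, decreasing = TRUE)
  l1_at <- function(o) {
    sel <- ord[(o + 1L):(o + n)]
    .comp_l1(feats[sel, , drop = FALSE], tfeats)
  }
  lo <- 0L; hi <- length(cand) - n
  # coarse grid then local refinement (L1 is near-unimodal in the offset)
  grid <- unique(round(seq(lo, hi, length.out = 25L)))
  vals <- vapply(grid, l1_at, numeric(1L))
  o0 <- grid[which.min(vals)]
  for (step in c(64L, 16L, 4L, 1L)) {
    repeat {
      cands <- unique(pmin(pmax(c(o0 - step, o0, o0 + step), lo), hi))
      vs <- vapply(cands, l1_at, numeric(1L))
      onew <- cands[which.min(vs)]
      if (onew == o0) break
      o0 <- onew
    }
  }
  best <- sort(ord[(o0 + 1L):(o0 + n)])
  best_l1 <- l1_at(o0)
  if (best_l1 > tol) {
    warning(sprintf("composition matching reached L1 = %.3f (> tol %.3f)",
                    best_l1, tol))
  }
  out <- DNAStringSet(cand[best])
  attr(out, "achieved_l1") <- best_l1
  out
}

#' Positional motif density around peak centers
#'
#' For equal-width, center-anchored sequences (e.g. summit +/- 500 bp),
#' tallies motif-hit midpoints per position bin and divides by the number of
#' sequences, giving motifs per peak per bin. When background sequences are
#' supplied, the per-bin enrichment ratio against the same profile on the
#' background is attached.
#'
#' @param sequences equal-width center-anchored sequences.
#' @param pwm a [PWMotif].
#' @param bin_width bin size in bp (default 5).
#' @param threshold log-odds threshold (motif default when `NULL`).
#' @param background optional background sequences of the same width.
#' @return data.frame with `position` (bin center, bp relative to sequence
#'   center), `density`, and `enrichment` when background is given.
#' @export
centralDensityProfile <- function(sequences, pwm, bin_width = 5L,
                                  threshold = NULL, background = NULL) {
  s <- .as_char_seqs(sequences)
  wd <- unique(nchar(s))
  if (length(wd) != 1L) stop("sequences must be equal width")
  profile_of <- function(ss) {
    hits <- scanMotif(ss, pwm, threshold)
    n_bins <- ceiling(wd / bin_width)
    dens <- rep(0, n_bins)
    if (nrow(hits)) {
      mid <- hits$offset + motifWidth(pwm) / 2    # 0-based bp from seq start
      bin <- pmin(floor(mid / bin_width) + 1L, n_bins)
      tab <- tabulate(bin, nbins = n_bins)
      dens <- tab / length(ss)
    }
    dens
  }
  dens <- profile_of(s)
  n_bins <- length(dens)
  pos <- (seq_len(n_bins) - 0.5) * bin_width - wd / 2
  out <- data.frame(position = pos, density = dens)
  if (!is.null(background)) {
    bdens <- profile_of(.as_char_seqs(background))
    out$background_density <- bdens
    out$enrichment <- ifelse(bdens > 0, dens / bdens, NA_real_)
  }
  out
}

.pwm_similarity <- function(m1, m2) {
  # max Pearson correlation over ungapped offsets and both orientations,
  # flattened aligned probability columns, overlap >= 4 columns
  best <- -1
  for (mat2 in list(m2, m2[c("T", "G", "C", "A"), rev(seq_len(ncol(m2))),
                           drop = FALSE])) {
    w1 <- ncol(m1); w2 <- ncol(mat2)
    for (off in seq(-(w2 - 1L), w1 - 1L)) {
      i1 <- max(1L, 1L + off):min(w1, w2 + off)
      i2 <- i1 - off
      if (length(i1) < 4L) next
      v1 <- as.vector(m1[, i1]); v2 <- as.vector(mat2[, i2])
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
      best <- max(best, cor(v1, v2))
    }
  }
  best
}

#' Collapse a motif library to a non-redundant set
#'
#' Pairwise similarity is the maximum Pearson correlation of aligned,
#' flattened probability columns over all ungapped offsets and both
#' orientations (minimum 4 overlapping columns). Motifs are sorted by their
#' enrichment score (descending; ties by name) and greedily clustered: each
#' unassigned motif with similarity above `pcc_threshold` to the current
#' seed is absorbed. This reduces a redundant curated library to a
#' non-redundant set, keeping the highest-scoring representative of each
#' similarity cluster.
#'
#' @param library a [MotifLibrary]; motif `score` slots supply the ranking
#'   (unscored motifs rank by total information content).
#' @param pcc_threshold similarity threshold (default 0.6, strict `>`).
#' @return list with `seeds` (a `MotifLibrary`), `mapping` (data.frame
#'   `member` -> `seed`), and the `similarity` matrix.
#' @export
collapseRedundant <- function(library, pcc_threshold = 0.6) {
  mots <- as.list(library)
  if (!length(mots)) stop("empty motif library")
  nms <- names(mots)
  scores <- vapply(mots, motifScore, numeric(1L))
  ic <- vapply(mots, function(m) {
    sum(apply(motifMatrix(m), 2L, function(p) 2 + sum(p * log2(p))))
  }, numeric(1L))
  scores[is.na(scores)] <- ic[is.na(scores)]
  k <- length(mots)
  sim <- matrix(1, k, k, dimnames = list(nms, nms))
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      sim[i, j] <- sim[j, i] <- .pwm_similarity(motifMatrix(mots[[i]]),
                                                motifMatrix(mots[[j]]))
    }
  }
  ord <- order(-scores, nms)
  assigned <- rep(NA_character_, k)
  for (i in ord) {
    if (!is.na(assigned[i])) next
    assigned[i] <- nms[i]
    free <- which(is.na(assigned))
    absorb <- free[sim[i, free] > pcc_threshold]
    assigned[absorb] <- nms[i]
  }
  seeds <- unique(assigned[order(match(assigned, nms))])
  list(seeds = MotifLibrary(mots[seeds]),
       mapping = data.frame(member = nms, seed = assigned,
                            stringsAsFactors = FALSE),
       similarity = sim)
}

#' Motif co-occurrence enrichment over a peak universe
#'
#' From a motif-hit table over a fixed universe of N peaks: `n_i` counts
#' peaks with at least one hit of motif i; `O_ij` counts peaks with at least
#' one hit of both i and j; the expectation under independence is
#' `E_ij = n_i * n_j / N`; enrichment is `log2(O_ij / E_ij)` (`-Inf` when
#' `O_ij = 0`). Co-presence in the peak is sufficient by default; a minimum
#' separation between the two motifs' hits can be required.
#'
#' @param hits data.frame with `seq_id`, `motif`, `offset` columns (as from
#'   [scanMotif()], rbind-ed over motifs).
#' @param universe character vector of all peak ids (defines N).
#' @param motifs motif names to include (default: all in `hits`).
#' @param min_separation if positive, a pair only counts in `O_ij` when some
#'   hit pair of the two motifs is at least this many bp apart.
#' @return list with `N`, `n` (per-motif peak counts), `observed`,
#'   `expected`, `enrichment` (symmetric matrices, `NA` diagonal).
#' @export
motifCooccurrence <- function(hits, universe, motifs = NULL,
                              min_separation = 0L) {
  N <- length(universe)
  if (N == 0L) stop("empty peak universe")
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  k <- length(motifs)
  pres <- matrix(FALSE, N, k, dimnames = list(universe, motifs))
  hi <- hits[hits$motif %in% motifs & hits$seq_id %in% universe, ,
             drop = FALSE]
  pres[cbind(match(hi$seq_id, universe), match(hi$motif, motifs))] <- TRUE
  n_i <- colSums(pres)
  O <- crossprod(pres)
  if (min_separation > 0L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      both <- universe[pres[, a] & pres[, b]]
      ok <- vapply(both, function(p) {
        oa <- hi$offset[hi$seq_id == p & hi$motif == motifs[a]]
        ob <- hi$offset[hi$seq_id == p & hi$motif == motifs[b]]
        any(abs(outer(oa, ob, "-")) >= min_separation)
      }, logical(1L))
      O[a, b] <- O[b, a] <- sum(ok)
    }
  }
  E <- outer(n_i, n_i) / N
  enr <- suppressWarnings(log2(O / E))
  enr[O == 0] <- -Inf
  diag(O) <- diag(E) <- diag(enr) <- NA
  list(N = N, n = n_i, observed = O, expected = E, enrichment = enr)
}

#' Secondary-motif spacing profile around a primary motif
#'
#' Re-anchors each sequence on its best primary-motif hit (highest score,
#' ties to the leftmost), orients by the primary hit's strand, and tallies
#' secondary-motif hits by signed start-to-start offset and relative strand
#' at 1 bp resolution. The anchor hit itself (same offset and strand) is
#' masked, so a motif scanned against itself does not produce a trivial
#' spike at zero; overlapping but non-identical hits are kept, since
#' closely spaced dimer configurations are exactly what the profile is
#' meant to reveal.
#'
#' @param sequences peak sequences.
#' @param primary,secondary [PWMotif] objects.
#' @param threshold relaxed log-odds threshold for both motifs (default 5).
#' @param max_offset only offsets within `[-max_offset, max_offset]` are
#'   reported.
#' @return data.frame `offset`, `relative_strand` (`same`/`opposite`),
#'   `count`; attribute `n_anchored` = number of sequences with a primary
#'   hit. Empty (with a warning) when no primary hits exist.
#' @export
spacingProfile <- function(sequences, primary, secondary, threshold = 5,
                           max_offset = 200L) {
  s <- .as_char_seqs(sequences)
  ph <- scanMotif(s, primary, threshold)
  empty <- data.frame(offset = integer(), relative_strand = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (!nrow(ph)) {
    warning("no primary-motif hits; empty spacing profile")
    attr(empty, "n_anchored") <- 0L
    return(empty)
  }
  sh <- scanMotif(s, secondary, threshold)
  best <- ph[order(ph$seq_id, -ph$score, ph$offset), ]
  best <- best[!duplicated(best$seq_id), ]
  recs <- list()
  for (r in seq_len(nrow(best))) {
    anc <- best[r, ]
    hits <- sh[sh$seq_id == anc$seq_id, , drop = FALSE]
    self <- hits$offset == anc$offset & hits$strand == anc$strand
    hits <- hits[!self, , drop = FALSE]
    if (!nrow(hits)) next
    delta <- hits$offset - anc$offset
    same <- hits$strand == anc$strand
    if (anc$strand == "-") delta <- -delta
    recs[[length(recs) + 1L]] <- data.frame(offset = delta, same = same)
  }
  if (!length(recs)) {
    attr(empty, "n_anchored") <- nrow(best)
    return(empty)
  }
  all <- do.call(rbind, recs)
  all <- all[abs(all$offset) <= max_offset, , drop = FALSE]
  tab <- as.data.frame(table(offset = all$offset,
                             relative_strand = ifelse(all$same, "same",
                                                      "opposite")),
                       stringsAsFactors = FALSE)
  tab$offset <- as.integer(tab$offset)
  names(tab)[3L] <- "count"
  out <- tab[order(tab$relative_strand, tab$offset), ]
  rownames(out) <- NULL
  attr(out, "n_anchored") <- nrow(best)
  out
}

#' Known-motif enrichment in target vs background sequences
#'
#' For each motif, counts target and background sequences carrying at least
#' one hit and computes the target/background occurrence-rate ratio and a
#' one-sided cumulative hypergeometric p-value (over-representation in
#' targets). The `-log10(p)` column doubles as the enrichment score used to
#' rank motifs during redundancy collapse.
#'
#' @param targets,background sequence sets.
#' @param library a [MotifLibrary].
#' @param threshold log-odds threshold (per-motif default when `NULL`).
#' @return data.frame per motif: `motif`, `n_target`, `n_background`,
#'   `target_frac`, `background_frac`, `ratio`, `p_value`, `neg_log10_p`,
#'   sorted by decreasing `neg_log10_p`.
#' @export
motifEnrichment <- function(targets, background, library, threshold = NULL) {
  ts <- .as_char_seqs(targets); bs <- .as_char_seqs(background)
  nt <- length(ts); nb <- length(bs)
  rows <- lapply(as.list(library), function(m) {
    a <- length(unique(scanMotif(ts, m, threshold)$seq_id))
    b <- length(unique(scanMotif(bs, m, threshold)$seq_id))
    p <- phyper(a - 1, a + b, nt + nb - a - b, nt, lower.tail = FALSE)
    data.frame(motif = motifName(m), n_target = a, n_background = b,
               target_frac = a / nt, background_frac = b / nb,
               ratio = (a / nt) / max(b / nb, 1e-12),
               p_value = p, neg_log10_p = -log10(max(p, 1e-300)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$neg_log10_p, out$motif), ]
  rownames(out) <- NULL
  out
}
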