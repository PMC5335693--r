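# shared fixture builders; everything is generated in code at test time

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

# near-deterministic PWM from a consensus string (W = A/T allowed)
consensus_pwm <- function(name, consensus, p = 0.97, threshold = 5,
                          score = NA_real_) {
  w <- nchar(consensus)
  m <- matrix((1 - p) / 3, nrow = 4, ncol = w,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) {
    b <- switch(substr(consensus, j, j),
                W = c("A", "T"), N = c("A", "C", "G", "T"),
                substr(consensus, j, j))
    m[, j] <- if (length(b) == 4L) 0.25 else (1 - p) / (4 - length(b))
    if (length(b) < 4L) m[b, j] <- p / length(b)
  }
  PWMotif(name, m, threshold = threshold, score = score)
}

random_dna <- function(n, len, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1L))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), chrom_len = 1e6) {
  chr <- sample(chroms, n, replace = TRUE)
  summit <- sample.int(chrom_len - 400L, n) + 200L
  gr <- GRanges(chr, IRanges(summit - 100L, width = 200L))
  mcols(gr)$name <- sprintf("pk%04d", seq_len(n))
  mcols(gr)$summit <- summit
  gr
}

random_tss <- function(n, chroms = c("chr1", "chr2"), chrom_len = 1e6) {
  gr <- GRanges(sample(chroms, n, replace = TRUE),
                IRanges(sample.int(chrom_len, n), width = 1L),
                strand = sample(c("+", "-"), n, replace = TRUE))
  mcols(gr)$name <- sprintf("g%03d", seq_len(n))
  gr
}

# small simulation shared across tests (cached per session)
small_sim_config <- function(seed = 101L, ...) {
  args <- list(seed = seed, genome_length = 3e6, n_chromosomes = 2L,
               closed_domain_lengths = 5e5, closed_domain_counts = 2L,
               peak_counts = c(shared_PR = 200L, rod_specific = 40L,
                               cone_specific = 120L, non_PR = 60L),
               n_genes = 400L, cre_n_constructs = 200L)
  args[names(list(...))] <- list(...)
  do.call(SimConfig, args)
}

.sim_cache <- new.env(parent = emptyenv())
cached_small_sim <- function() {
  if (is.null(.sim_cache$bundle)) {
    .sim_cache$bundle <- simulateDataset(small_sim_config())
  }
  .sim_cache$bundle
}
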