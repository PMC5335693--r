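#' @importFrom stats rnbinom rnorm rpois
#' @importFrom Biostrings DNAStringSet
#' @importFrom IRanges "end<-"
NULL

.DEFAULT_DINUC <- local({
  # slightly AT-rich order-1 background (~42% GC), mild CpG depletion
  m <- matrix(c(0.33, 0.19, 0.22, 0.26,
                0.33, 0.25, 0.06, 0.36,
                0.29, 0.21, 0.25, 0.25,
                0.22, 0.22, 0.25, 0.31),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  sweep(m, 1L, rowSums(m), "/")
})

#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig]. The defaults encode the study structure
#' the pipeline targets: a 12 Mb genome over 3 chromosomes; four rod-closed
#' domains (two of 1 Mb, two of 0.5 Mb); a peak universe of 600 shared
#' photoreceptor peaks, 60 rod-specific, 300 cone-specific (~10x the
#' rod-specific count, placed preferentially inside closed domains and away
#' from genes) and 150 peaks shared with non-photoreceptor cell types;
#' NB counts with mean 100 (open) / 10 (closed-domain baseline), dispersion
#' 0.05 and a planted |log2 FC| of 2; two replicates per photoreceptor
#' group; expression coupled to differential peaks at 0.8; and a 500 + 500
#' construct reporter library with a 1-unit repression for the homotypic
#' TAAT dimer.
#'
#' @param genome_length,n_chromosomes genome size and chromosome count.
#' @param seed RNG seed.
#' @param n_replicates_per_group replicates per photoreceptor group.
#' @param peak_counts named counts over `shared_PR`, `rod_specific`,
#'   `cone_specific`, `non_PR`.
#' @param closed_domain_lengths,closed_domain_counts rod-closed domain
#'   spans (bp) and multiplicities.
#' @param nb_mean_open,nb_mean_closed,nb_dispersion NB count model; the
#'   dispersion is alpha in `var = mu + alpha * mu^2`.
#' @param lfc_planted planted log2 fold change for specific peaks.
#' @param n_genes number of genes.
#' @param expr_coupling P(nearest gene of a differential peak is
#'   concordantly differential); discordant otherwise.
#' @param motif_plant_rates per-class named planting probabilities.
#' @param cre_n_constructs native reporter constructs (mutant arm mirrors).
#' @param cre_repression_effect expression shift for homotypic-TAAT native
#'   constructs, in reporter sd units.
#' @return a `SimConfig`.
#' @export
SimConfig <- function(genome_length = 12e6, n_chromosomes = 3L, seed = 1L,
                      n_replicates_per_group = 2L,
                      peak_counts = c(shared_PR = 600L, rod_specific = 60L,
                                      cone_specific = 300L, non_PR = 150L),
                      closed_domain_lengths = c(1e6, 5e5),
                      closed_domain_counts = c(2L, 2L),
                      nb_mean_open = 100, nb_mean_closed = 10,
                      nb_dispersion = 0.05, lfc_planted = 2,
                      n_genes = 1200L, expr_coupling = 0.8,
                      motif_plant_rates = list(
                        shared_PR = c(CRX = 0.6, CTCF = 0.4),
                        rod_specific = c(MAF = 0.8, NR = 0.6),
                        cone_specific = c(Q50 = 0.8, bHLH = 0.6),
                        non_PR = c(CTCF = 0.5)),
                      cre_n_constructs = 500L,
                      cre_repression_effect = 1) {
  new("SimConfig", genome_length = genome_length,
      n_chromosomes = as.integer(n_chromosomes), seed = as.integer(seed),
      n_replicates_per_group = as.integer(n_replicates_per_group),
      peak_counts = setNames(as.integer(peak_counts[.PEAK_CLASSES]),
                             .PEAK_CLASSES),
      closed_domain_lengths = closed_domain_lengths,
      closed_domain_counts = as.integer(closed_domain_counts),
      nb_mean_open = nb_mean_open, nb_mean_closed = nb_mean_closed,
      nb_dispersion = nb_dispersion, lfc_planted = lfc_planted,
      n_genes = as.integer(n_genes), expr_coupling = expr_coupling,
      motif_plant_rates = motif_plant_rates,
      cre_n_constructs = as.integer(cre_n_constructs),
      cre_repression_effect = cre_repression_effect)
}

# order-1 Markov sequence; candidate-matrix trick keeps the sequential
# dependency to a cheap index fold
.markov_seq <- function(len, trans = .DEFAULT_DINUC, chunk = 1e6L) {
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(len)
  state <- sample.int(4L, 1L)
  done <- 0L
  while (done < len) {
    k <- min(chunk, len - done)
    u <- runif(k)
    # nxt[i, s]: sampled next state at step i given previous state s
    nxt <- matrix(0L, k, 4L)
    for (s in 1:4) {
      nxt[, s] <- findInterval(u, cum[s, ]) + 1L
      nxt[nxt[, s] > 4L, s] <- 4L
    }
    seg <- integer(k)
    for (i in seq_len(k)) {
      state <- nxt[i, state]
      seg[i] <- state
    }
    out[(done + 1L):(done + k)] <- seg
    done <- done + k
  }
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Overwrites `[offset, offset + width)` of the sequence with the motif's
#' consensus (for a [PWMotif]) or the literal k-mer; strand `-` writes the
#' reverse complement. No other position changes.
#'
#' @param sequence DNA string.
#' @param motif a `PWMotif` or a literal DNA string (IUPAC `N` positions are
#'   filled with random bases).
#' @param offset 0-based start of the planted instance.
#' @param strand `"+"` or `"-"`.
#' @return the modified sequence (character).
#' @export
plantMotif <- function(sequence, motif, offset, strand = "+") {
  s <- as.character(sequence)
  word <- if (is(motif, "PWMotif")) motifConsensus(motif) else
    toupper(as.character(motif))
  if (grepl("N", word, fixed = TRUE)) {
    ns <- gregexpr("N", word, fixed = TRUE)[[1L]]
    for (i in ns) substr(word, i, i) <- sample(c("A", "C", "G", "T"), 1L)
  }
  w <- nchar(word)
  if (offset < 0L || offset + w > nchar(s)) {
    stop(sprintf("offset %d with width %d exceeds sequence length %d",
                 offset, w, nchar(s)))
  }
  if (strand == "-") {
    word <- as.character(reverseComplement(DNAString(word)))
  }
  substr(s, offset + 1L, offset + w) <- word
  s
}

# built-in motif library for planting: photoreceptor-relevant consensi
.sim_motif_library <- function() {
  mk <- function(name, consensus, p = 0.97) {
    w <- nchar(consensus)
    m <- matrix((1 - p) / 3, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    iub <- list(A = "A", C = "C", G = "G", T = "T",
                W = c("A", "T"), S = c("C", "G"), N = c("A", "C", "G", "T"))
    for (j in seq_len(w)) {
      b <- iub[[substr(consensus, j, j)]]
      m[, j] <- (1 - p) / (4 - length(b) + 1e-9)
      m[b, j] <- p / length(b)
      m[, j] <- m[, j] / sum(m[, j])
    }
    PWMotif(name, m, threshold = 5)
  }
  MotifLibrary(
    mk("CRX", "CTAATCC"),
    mk("K50_dimer", "TAATNNNATTA"),
    mk("Q50", "TAATTA"),
    mk("MAF", "TGCTGACTCAGCA"),
    mk("NR", "AGGTCA"),
    mk("bHLH", "CATATG"),
    mk("MADS", "CCWWWWWWWWGG"),
    mk("CTCF", "CCACCAGGTGGCAG")
  )
}

#' Simulate a complete synthetic photoreceptor dataset
#'
#' Generates, from one seed, every input the pipeline consumes: a genome
#' (order-1 Markov background) with rod-closed domains; TSS and repeat
#' annotation; summit-bearing peak calls per photoreceptor group; paired
#' NB count matrices and fragment sets (short nucleosome-free inserts whose
#' peak-level midpoint counts equal the NB draws, plus nucleosomal inserts
#' that the NFR filter removes, plus genome-wide background depleted inside
#' closed domains for rod samples); planted motif instances written into
#' the genome sequence; RNA counts with expression directionally coupled to
#' differential peaks; a reporter (CRE-seq) library with a repressive
#' homotypic TAAT dimer effect in the native arm; and a ground-truth record
#' for every emitted object.
#'
#' @param config a [SimConfig].
#' @param fragments generate fragment sets (slower); count matrices are
#'   always generated.
#' @return a list bundle: `genome` (`DNAStringSet`), `chrom_sizes`, `tss`,
#'   `repeats`, `domains`, `peak_calls` (list of `GRanges` per group),
#'   `non_pr_peaks`, `atac_counts` (`SummarizedExperiment`), `rna_counts`
#'   (`SummarizedExperiment`), `fragments` (named list of `GRanges`, when
#'   requested), `motif_library`, `cre_table`, `truth`, `config`.
#' @export
simulateDataset <- function(config = SimConfig(), fragments = TRUE) {
  stopifnot(validObject(config))
  set.seed(config@seed)
  chrom_len <- as.integer(floor(config@genome_length / config@n_chromosomes))
  chroms <- paste0("chr", seq_len(config@n_chromosomes))
  chrom_sizes <- setNames(rep(chrom_len, config@n_chromosomes), chroms)

  ## --- rod-closed domains --------------------------------------------------
  dom_len <- rep(config@closed_domain_lengths, config@closed_domain_counts)
  if (any(dom_len >= chrom_len)) {
    stop("genome too short: a closed domain of ", max(dom_len),
         " bp does not fit a chromosome of ", chrom_len,
         " bp (binding constraint: domain length)")
  }
  .gr <- function(chr, ranges, ...) {
    GRanges(factor(chr, levels = chroms), ranges, ...)
  }
  domains <- .gr(character(0), IRanges())
  if (length(dom_len)) {
    dom_chr <- rep(chroms, length.out = length(dom_len))
    for (i in seq_along(dom_len)) {
      prev <- domains[seqnames(domains) == dom_chr[i]]
      for (try in 1:200) {
        st <- sample.int(chrom_len - dom_len[i], 1L)
        cand <- .gr(dom_chr[i], IRanges(st, width = dom_len[i]))
        if (!length(prev) || !any(countOverlaps(cand, prev))) break
        if (try == 200) stop("genome too short to place non-overlapping ",
                             "closed domains (binding constraint: total ",
                             "domain span)")
      }
      domains <- c(domains, cand)
    }
    domains <- sort(domains)
    mcols(domains)$name <- sprintf("closed_domain_%02d",
                                   seq_along(domains))
  }

  ## --- peak placement on a slot grid --------------------------------------
  slot_w <- 500L
  peak_w <- 200L
  slots_per_chrom <- (chrom_len - slot_w) %/% slot_w
  all_slots <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    data.frame(chrom = chroms[ci], slot = seq_len(slots_per_chrom))
  }))
  slot_start <- (all_slots$slot - 1L) * slot_w + 1L
  slot_gr <- GRanges(all_slots$chrom, IRanges(slot_start, width = slot_w))
  in_dom <- countOverlaps(slot_gr, domains, ignore.strand = TRUE) > 0L
  idx_in <- which(in_dom); idx_out <- which(!in_dom)

  pc <- config@peak_counts
  n_cone_in <- round(0.8 * pc[["cone_specific"]])
  n_cone_out <- pc[["cone_specific"]] - n_cone_in
  need_out <- pc[["shared_PR"]] + pc[["rod_specific"]] + pc[["non_PR"]] +
    n_cone_out + config@n_genes
  if (need_out > length(idx_out) || n_cone_in > length(idx_in)) {
    stop("genome too short to host the requested peaks and genes ",
         "(binding constraint: ", length(idx_out), " open-region slots for ",
         need_out, " elements)")
  }
  pick <- function(pool, n) {
    if (n == 0L) return(integer(0))
    sample(pool, n)
  }
  sel_in <- pick(idx_in, n_cone_in)
  remaining <- idx_out
  take <- function(n) {
    s <- pick(remaining, n)
    remaining <<- setdiff(remaining, s)
    s
  }
  sel <- list(shared_PR = take(pc[["shared_PR"]]),
              rod_specific = take(pc[["rod_specific"]]),
              cone_specific = c(sel_in, take(n_cone_out)),
              non_PR = take(pc[["non_PR"]]))
  gene_slots <- take(config@n_genes)

  peak_rows <- do.call(rbind, lapply(.PEAK_CLASSES, function(cl) {
    s <- sel[[cl]]
    if (!length(s)) return(NULL)
    data.frame(chrom = all_slots$chrom[s],
               summit = slot_start[s] + 150L +
                 sample.int(200L, length(s), replace = TRUE),
               class = cl, stringsAsFactors = FALSE)
  }))
  peak_rows <- peak_rows[order(peak_rows$chrom, peak_rows$summit), ]
  n_peaks <- nrow(peak_rows)
  peak_rows$name <- sprintf("peak_%05d", seq_len(n_peaks))
  peaks <- GRanges(peak_rows$chrom,
                   IRanges(peak_rows$summit - peak_w / 2L, width = peak_w))
  mcols(peaks)$name <- peak_rows$name
  mcols(peaks)$summit <- peak_rows$summit
  mcols(peaks)$class <- peak_rows$class
  seqlengths(peaks) <- chrom_sizes[seqlevels(peaks)]

  ## --- TSS table ------------------------------------------------------------
  # class-specific peaks each sponsor a nearby gene: rod-specific genes at
  # 2-30 kb, cone-specific at 20-80 kb (cone elements sit farther from
  # genes); remaining genes land on free slots
  rod_idx <- which(peak_rows$class == "rod_specific")
  cone_idx <- which(peak_rows$class == "cone_specific")
  # sparser sponsors for cone elements keep them gene-poor (their nearest
  # gene is typically a neighbouring element's sponsor tens of kb away)
  cone_idx <- cone_idx[seq_along(cone_idx) %% 3L == 1L]
  diff_idx <- c(rod_idx, cone_idx)
  n_dedicated <- min(length(diff_idx), config@n_genes)
  diff_idx <- diff_idx[seq_len(n_dedicated)]
  ded_dist <- ifelse(peak_rows$class[diff_idx] == "rod_specific",
                     sample(2000:10000, n_dedicated, replace = TRUE),
                     sample(25000:80000, n_dedicated, replace = TRUE))
  ded_pos <- peak_rows$summit[diff_idx] +
    ded_dist * sample(c(-1L, 1L), n_dedicated, replace = TRUE)
  ded_pos <- pmin(pmax(ded_pos, 1L), chrom_len)
  ded_chr <- peak_rows$chrom[diff_idx]
  n_free <- config@n_genes - n_dedicated
  free_chr <- all_slots$chrom[gene_slots][seq_len(n_free)]
  free_pos <- (slot_start[gene_slots] + sample.int(slot_w - 1L,
                                                   config@n_genes,
                                                   replace = TRUE))[
    seq_len(n_free)]
  tss <- GRanges(c(ded_chr, free_chr),
                 IRanges(c(ded_pos, free_pos), width = 1L),
                 strand = sample(c("+", "-"), config@n_genes,
                                 replace = TRUE))
  o <- order(as.character(seqnames(tss)), start(tss))
  tss <- tss[o]
  mcols(tss)$name <- sprintf("gene_%04d", seq_len(config@n_genes))
  seqlengths(tss) <- chrom_sizes[seqlevels(tss)]

  # repeats: random intervals plus heavy (80%) coverage of 5% of peaks
  n_rep <- max(10L, n_peaks %/% 10L)
  rep_chr <- sample(chroms, n_rep, replace = TRUE)
  rep_start <- vapply(rep_chr, function(ch) {
    sample.int(chrom_len - 1000L, 1L)
  }, integer(1L))
  repeats <- GRanges(rep_chr, IRanges(rep_start,
                                      width = sample(200:1000, n_rep,
                                                     replace = TRUE)))
  heavy <- sample(n_peaks, max(1L, n_peaks %/% 20L))
  repeats <- c(repeats, GRanges(seqnames(peaks)[heavy],
                                IRanges(start(peaks)[heavy],
                                        width = 160L)))
  repeats <- sort(reduce(repeats))

  ## --- genome sequence with planted motifs ---------------------------------
  genome_chr <- vapply(chroms, function(ch) .markov_seq(chrom_len),
                       character(1L))
  lib <- .sim_motif_library()
  # plant into 200 bp peak-local sequences, then splice each chromosome
  # once; in-place edits on multi-Mb strings are quadratic in total size
  peak_seq <- substring(genome_chr[peak_rows$chrom], start(peaks),
                        end(peaks))
  plant_rec <- list()
  for (i in seq_len(n_peaks)) {
    cl <- peak_rows$class[i]
    rates <- config@motif_plant_rates[[cl]]
    if (is.null(rates)) next
    used <- IRanges()
    for (mn in names(rates)) {
      if (runif(1) > rates[[mn]]) next
      pw <- lib[[mn]]
      w <- motifWidth(pw)
      # place within the central 120 bp, avoiding planted-motif overlap
      for (try in 1:20) {
        rel <- sample.int(120L - w, 1L) + 40L       # 0-based offset in peak
        cand <- IRanges(rel + 1L, width = w)
        if (!length(used) || !any(IRanges::overlapsAny(cand, used))) {
          used <- c(used, cand)
          strand_i <- sample(c("+", "-"), 1L)
          peak_seq[i] <- plantMotif(peak_seq[i], pw, rel, strand_i)
          plant_rec[[length(plant_rec) + 1L]] <-
            data.frame(peak = peak_rows$name[i], motif = mn,
                       offset = rel, strand = strand_i,
                       stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  planted <- if (length(plant_rec)) do.call(rbind, plant_rec) else
    data.frame(peak = character(), motif = character(), offset = integer(),
               strand = character(), stringsAsFactors = FALSE)
  for (ch in chroms) {
    pi <- which(peak_rows$chrom == ch)
    if (!length(pi)) next
    s <- start(peaks)[pi]; e <- end(peaks)[pi]
    gap_start <- c(1L, e + 1L)
    gap_end <- c(s - 1L, chrom_len)
    gaps <- substring(genome_chr[[ch]], gap_start, gap_end)
    pieces <- character(2L * length(pi) + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- gaps
    pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- peak_seq[pi]
    genome_chr[[ch]] <- paste(pieces, collapse = "")
  }
  genome <- DNAStringSet(genome_chr)
  names(genome) <- chroms

  ## --- group structure and counts ------------------------------------------
  groups <- c("rod", "green_cone", "blue_cone")
  n_rep_g <- config@n_replicates_per_group
  samples <- paste(rep(groups, each = n_rep_g), seq_len(n_rep_g),
                   sep = "_rep")
  group_of <- rep(groups, each = n_rep_g)
  depth <- runif(length(samples), 0.8, 1.25)
  names(depth) <- samples

  lfc_fac <- 2^(-config@lfc_planted)
  in_domain <- countOverlaps(peaks, domains, ignore.strand = TRUE) > 0L
  mean_for <- function(class, group, in_dom) {
    open <- config@nb_mean_open
    closed_spec <- open * lfc_fac
    if (class == "shared_PR") return(open)
    if (class == "non_PR") return(open)
    if (class == "rod_specific") {
      return(if (group == "rod") open else closed_spec)
    }
    # cone_specific
    if (group == "rod") {
      return(if (in_dom) config@nb_mean_closed else closed_spec)
    }
    open
  }
  mu <- matrix(0, n_peaks, length(samples),
               dimnames = list(peak_rows$name, samples))
  for (j in seq_along(samples)) {
    mu[, j] <- vapply(seq_len(n_peaks), function(i) {
      mean_for(peak_rows$class[i], group_of[j], in_domain[i])
    }, numeric(1L)) * depth[j]
  }
  size <- 1 / config@nb_dispersion
  atac <- matrix(rnbinom(length(mu), mu = mu, size = size),
                 nrow = n_peaks, dimnames = dimnames(mu))
  atac_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = atac),
    rowRanges = peaks,
    colData = DataFrame(group = group_of,
                        collapsed_group = ifelse(group_of == "rod", "rod",
                                                 "cone"),
                        row.names = samples))

  ## --- fragments ------------------------------------------------------------
  frag_list <- NULL
  if (fragments) {
    frag_list <- setNames(vector("list", length(samples)), samples)
    bg_rate_per_kb <- 0.5
    for (j in seq_along(samples)) {
      grp <- group_of[j]
      # peak fragments: exactly the NB count as NFR inserts inside the peak
      counts_j <- atac[, j]
      tot <- sum(counts_j)
      pi <- rep(seq_len(n_peaks), counts_j)
      mid <- mcols(peaks)$summit[pi] +
        pmin(pmax(round(rnorm(tot, 0, 30)), -(peak_w / 2L - 1L)),
             peak_w / 2L - 1L)
      ins <- sample(40:100, tot, replace = TRUE)
      st <- pmax(mid - ins %/% 2L, 1L)
      peak_fr <- .gr(as.character(seqnames(peaks))[pi],
                         IRanges(st, width = ins))
      # nucleosomal inserts (removed by the NFR filter)
      n_nuc <- rpois(1L, 0.3 * tot)
      nuc_pi <- sample(n_peaks, n_nuc, replace = TRUE,
                       prob = counts_j + 1)
      nuc_mid <- mcols(peaks)$summit[nuc_pi] + round(rnorm(n_nuc, 0, 120))
      nuc_ins <- pmax(round(rnorm(n_nuc, 200, 20)), 150L)
      nuc_fr <- .gr(as.character(seqnames(peaks))[nuc_pi],
                        IRanges(pmax(nuc_mid - nuc_ins %/% 2L, 1L),
                                width = nuc_ins))
      # genome-wide background, depleted in closed domains for rods
      n_bg <- rpois(1L, bg_rate_per_kb * config@genome_length / 1000 *
                      depth[j])
      bg_chr <- sample(chroms, n_bg, replace = TRUE)
      bg_mid <- floor(runif(n_bg) * (chrom_len - 300L)) + 150L
      bg <- .gr(bg_chr, IRanges(bg_mid, width = 1L))
      if (grp == "rod" && length(domains)) {
        inside <- countOverlaps(bg, domains, ignore.strand = TRUE) > 0L
        keep <- !inside | (runif(n_bg) < 0.1)
        bg <- bg[keep]
      }
      bg_ins <- sample(40:100, length(bg), replace = TRUE)
      bg_fr <- .gr(as.character(seqnames(bg)),
                       IRanges(pmax(start(bg) - bg_ins %/% 2L, 1L),
                               width = bg_ins))
      fr <- sort(c(peak_fr, nuc_fr, bg_fr))
      end(fr) <- pmin(end(fr), chrom_sizes[as.character(seqnames(fr))])
      mcols(fr)$insert_size <- width(fr)
      frag_list[[j]] <- fr
    }
  }

  ## --- per-group peak calls and non-PR external sets ------------------------
  open_in <- list(
    rod = c("shared_PR", "rod_specific", "non_PR"),
    green_cone = c("shared_PR", "cone_specific", "non_PR"),
    blue_cone = c("shared_PR", "cone_specific", "non_PR"))
  peak_calls <- lapply(open_in, function(classes) {
    p <- peaks[mcols(peaks)$class %in% classes]
    mcols(p)$score <- round(runif(length(p), 100, 1000))
    p
  })
  non_pr <- peaks[mcols(peaks)$class == "non_PR"]
  shift_amt <- sample(-40:40, length(non_pr), replace = TRUE)
  liver <- shift(granges(non_pr), shift_amt)
  mcols(liver)$name <- sprintf("liver_peak_%04d", seq_along(liver))
  non_pr_sets <- list(liver = liver)

  ## --- RNA counts coupled to differential peaks ----------------------------
  gene_ids <- mcols(tss)$name
  gene_dir <- setNames(rep("null", config@n_genes), gene_ids)
  peaks_ann <- nearestTSS(peaks, tss)
  # per-gene direction from the majority class of its assigned differential
  # peaks, so link-level concordance tracks expr_coupling without dilution
  # from genes claimed by several peaks
  diff_i <- which(peak_rows$class %in% c("rod_specific", "cone_specific"))
  by_gene <- split(peak_rows$class[diff_i],
                   mcols(peaks_ann)$nearest_gene[diff_i])
  for (g in names(by_gene)) {
    if (is.na(g)) next
    n_rod <- sum(by_gene[[g]] == "rod_specific")
    n_cone <- length(by_gene[[g]]) - n_rod
    major <- if (n_rod > n_cone) "rod_up" else if (n_cone > n_rod)
      "cone_up" else sample(c("rod_up", "cone_up"), 1L)
    conc <- runif(1) < config@expr_coupling
    gene_dir[[g]] <- if (conc) major else
      setdiff(c("rod_up", "cone_up"), major)
  }
  rna_groups <- c("rod", "cone")
  rna_samples <- paste(rep(rna_groups, each = n_rep_g),
                       seq_len(n_rep_g), sep = "_rep")
  rna_group_of <- rep(rna_groups, each = n_rep_g)
  rna_depth <- runif(length(rna_samples), 0.8, 1.25)
  base_expr <- 200
  rna_mu <- matrix(base_expr, config@n_genes, length(rna_samples),
                   dimnames = list(gene_ids, rna_samples))
  up_fac <- 2^config@lfc_planted
  for (g in seq_len(config@n_genes)) {
    if (gene_dir[[g]] == "rod_up") {
      rna_mu[g, rna_group_of == "rod"] <- base_expr * up_fac
    } else if (gene_dir[[g]] == "cone_up") {
      rna_mu[g, rna_group_of == "cone"] <- base_expr * up_fac
    }
  }
  rna_mu <- sweep(rna_mu, 2L, rna_depth, "*")
  rna <- matrix(rnbinom(length(rna_mu), mu = rna_mu, size = size),
                nrow = config@n_genes, dimnames = dimnames(rna_mu))
  rna_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = rna),
    colData = DataFrame(group = rna_group_of, row.names = rna_samples))

  ## --- CRE-seq reporter library --------------------------------------------
  cre <- .simulate_cre_library(config)

  truth <- list(
    peak_classes = setNames(peak_rows$class, peak_rows$name),
    domains = domains,
    gene_directions = gene_dir,
    planted_motifs = planted,
    cre_kmer_labels = cre$kmer_labels)

  list(genome = genome, chrom_sizes = chrom_sizes, tss = tss,
       repeats = repeats, domains = domains, peaks = peaks_ann,
       peak_calls = peak_calls, non_pr_peaks = non_pr_sets,
       atac_counts = atac_se, rna_counts = rna_se,
       fragments = frag_list, motif_library = lib,
       cre_table = cre$table, truth = truth, config = config)
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
  }, character(1L))
}

.simulate_cre_library <- function(config) {
  n <- config@cre_n_constructs
  len <- 84L
  seqs <- .random_dna(n, len)
  scheme <- dimerKmerScheme()
  # every native construct carries a CRX site; subsets get planted dimers
  for (i in seq_len(n)) {
    seqs[i] <- plantMotif(seqs[i], "CTAATCC",
                          sample.int(len - 7L, 1L) - 1L, "+")
    u <- runif(1)
    dim_pat <- if (u < 0.30) "TAATNNNATTA" else if (u < 0.45)
      "TAAGNNNCTTA" else if (u < 0.60) "TAATNNNCTTA" else NA
    if (!is.na(dim_pat)) {
      for (try in 1:10) {
        off <- sample.int(len - 11L, 1L) - 1L
        cand <- plantMotif(seqs[i], dim_pat, off,
                           sample(c("+", "-"), 1L))
        # re-planting may disrupt the CRX site; keep if still present
        if (grepl("CTAATCC", cand, fixed = TRUE) ||
            grepl("GGATTAG", cand, fixed = TRUE)) {
          seqs[i] <- cand
          break
        }
      }
    }
  }
  native_ids <- sprintf("construct_%04d_native", seq_len(n))
  mutant_seqs <- vapply(seqs, mutateCrxSites, character(1L),
                        USE.NAMES = FALSE)
  mutant_ids <- sprintf("construct_%04d_crx_mutant", seq_len(n))
  n_scr <- max(10L, n %/% 10L)
  scr_seqs <- .random_dna(n_scr, len)
  scr_ids <- sprintf("construct_%04d_scrambled", seq_len(n_scr))

  all_ids <- c(native_ids, mutant_ids, scr_ids)
  all_seqs <- c(seqs, mutant_seqs, scr_seqs)
  all_class <- rep(c("native", "crx_mutant", "scrambled"),
                   c(n, n, n_scr))
  pres <- .scan_kmer_presence(all_seqs, scheme)
  labels <- apply(pres, 1L, function(r) names(which(r)), simplify = FALSE)
  names(labels) <- all_ids
  has_homo <- pres[, "homotypic_TAAT"]
  expr <- rnorm(length(all_ids), 0, 1)
  repress <- has_homo & all_class == "native"
  expr[repress] <- expr[repress] - config@cre_repression_effect
  list(table = data.frame(construct_id = all_ids,
                          variant_class = all_class,
                          sequence = all_seqs, expression = expr,
                          stringsAsFactors = FALSE),
       kmer_labels = labels)
}

#' Write a simulated bundle to disk
#'
#' Emits every external format the pipeline reads: genome FASTA, TSS BED6,
#' repeat BED, per-group narrowPeak calls, per-sample fragment TSVs, count
#' TSVs (ATAC and RNA), HOMER-style motif text, and the CRE-seq construct
#' TSV. Writing is deterministic: the same bundle yields byte-identical
#' files.
#'
#' @param bundle output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  writeXStringSet(bundle$genome, fp("genome.fa"))
  write.table(data.frame(names(bundle$chrom_sizes), bundle$chrom_sizes),
              fp("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(bundle$tss, fp("tss.bed"))
  writeBed(bundle$repeats, fp("repeats.bed"))
  if (length(bundle$domains)) writeBed(bundle$domains, fp("domains.bed"))
  for (g in names(bundle$peak_calls)) {
    writeNarrowPeak(bundle$peak_calls[[g]],
                    fp(sprintf("peaks_%s.narrowPeak", g)))
  }
  for (g in names(bundle$non_pr_peaks)) {
    writeBed(bundle$non_pr_peaks[[g]], fp(sprintf("peaks_%s.bed", g)))
  }
  if (!is.null(bundle$fragments)) {
    for (s in names(bundle$fragments)) {
      writeFragments(bundle$fragments[[s]],
                     fp(sprintf("fragments_%s.tsv", s)))
    }
  }
  ac <- SummarizedExperiment::assay(bundle$atac_counts)
  write.table(data.frame(peak = rownames(ac), ac, check.names = FALSE),
              fp("atac_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rc <- SummarizedExperiment::assay(bundle$rna_counts)
  write.table(data.frame(gene = rownames(rc), rc, check.names = FALSE),
              fp("rna_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeHomerMotifs(bundle$motif_library, fp("motifs.txt"))
  write.table(bundle$cre_table, fp("cre_constructs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
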