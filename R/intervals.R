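#' @importFrom GenomicRanges reduce findOverlaps countOverlaps shift
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Re-center peaks on their summits at fixed width
#'
#' Replaces each peak interval by a fixed-width window centered on its
#' summit, the standardization under which all peak-level analyses here
#' operate (signal matrices, motif scans, sequence extraction). When a window
#' would run off a chromosome end (requires `chrom_sizes` or seqlengths),
#' the window is shifted inward rather than truncated, so every element
#' keeps the same width.
#'
#' @param peaks `GRanges` with an absolute `summit` metadata column.
#' @param width window width in bp; must be positive and even.
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   boundary shifting (falls back to `seqlengths(peaks)` when set).
#' @return `GRanges` of width-`width` summit-centered windows; the `summit`
#'   column is preserved.
#' @export
recenterOnSummit <- function(peaks, width = 200L, chrom_sizes = NULL) {
  if (width <= 0L || width %% 2L != 0L) {
    stop("width must be positive and even, got ", width)
  }
  summit <- mcols(peaks)$summit
  if (is.null(summit) || anyNA(summit)) {
    offenders <- if (is.null(summit)) "<all>" else {
      nm <- mcols(peaks)$name
      if (is.null(nm)) nm <- as.character(which(is.na(summit)))
      paste(head(nm[is.na(summit)], 5L), collapse = ", ")
    }
    stop("peaks lacking summits: ", offenders)
  }
  half <- width %/% 2L
  new_start <- summit - half          # 1-based start of [summit-w/2, ...)
  sizes <- chrom_sizes
  if (is.null(sizes)) sizes <- seqlengths(peaks)
  chr <- as.character(seqnames(peaks))
  len <- if (all(is.na(sizes)) || is.null(sizes)) rep(NA_integer_,
                                                      length(peaks))
         else unname(sizes[chr])
  new_start <- pmax(new_start, 1L)
  over <- !is.na(len) & (new_start + width - 1L > len)
  new_start[over] <- len[over] - width + 1L
  if (any(!is.na(len) & new_start < 1L)) {
    stop("chromosome shorter than requested window width")
  }
  out <- GRanges(chr, IRanges(new_start, width = width),
                 strand = strand(peaks))
  mcols(out) <- mcols(peaks)
  if (!is.null(sizes) && !all(is.na(sizes))) {
    sl <- sizes[intersect(names(sizes), seqlevels(out))]
    seqlengths(out)[names(sl)] <- sl
  }
  out
}

#' Merge per-sample peak sets into a reference atlas
#'
#' Takes the union of several peak sets and coalesces any intervals that
#' share at least 1 bp, producing the cross-sample "master list" all
#' downstream quantification runs over. Each atlas element records which
#' input sets contributed to it.
#'
#' @param sets named list of `GRanges` peak sets (unnamed lists get
#'   `set1..setN`).
#' @return `GRanges` sorted by (chrom, start) with metadata columns `name`
#'   (`atlas_%06d`), `sources` (CharacterList of contributing set names) and
#'   `n_sources`.
#' @export
mergePeakSets <- function(sets) {
  if (is(sets, "GRanges")) sets <- list(sets)
  if (!length(sets) || all(vapply(sets, length, 1L) == 0L)) {
    stop("need at least one non-empty peak set")
  }
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  pooled <- suppressWarnings(do.call(c, unname(lapply(sets, granges))))
  pooled <- GenomeInfoDb::sortSeqlevels(pooled)
  src <- rep(names(sets), vapply(sets, length, 1L))
  atlas <- reduce(sort(pooled), ignore.strand = TRUE)
  hits <- findOverlaps(atlas, pooled, ignore.strand = TRUE)
  src_list <- split(src[subjectHits(hits)], factor(queryHits(hits),
                                                   seq_along(atlas)))
  src_list <- lapply(src_list, function(s) sort(unique(s)))
  mcols(atlas)$name <- sprintf("atlas_%06d", seq_along(atlas))
  mcols(atlas)$sources <- IRanges::CharacterList(src_list)
  mcols(atlas)$n_sources <- unname(lengths(src_list))
  atlas
}

#' Filter fragments to the nucleosome-free fraction
#'
#' Keeps fragments with insert size at or below `max_insert` (default
#' 100 bp), the standard enrichment step for nucleosome-free reads in
#' ATAC-seq; fragments longer than the cutoff are removed, the 100 bp
#' boundary itself is retained. Order is preserved.
#'
#' @param fragments `GRanges` with an `insert_size` metadata column (falls
#'   back to `width()`).
#' @param max_insert inclusive insert-size cutoff in bp.
#' @return the filtered `GRanges`.
#' @export
filterNFR <- function(fragments, max_insert = 100L) {
  ins <- mcols(fragments)$insert_size
  if (is.null(ins)) ins <- width(fragments)
  fragments[ins <= max_insert]
}

#' Extract interval sequences from a genome
#'
#' Pulls the forward-strand sequence of each interval out of a named
#' `DNAStringSet` of chromosome sequences, named by the intervals' `name`
#' column when present.
#'
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @param gr `GRanges` of intervals to extract.
#' @return named character vector of sequences.
#' @export
extractSequences <- function(genome, gr) {
  chr <- as.character(seqnames(gr))
  bad <- setdiff(unique(chr), names(genome))
  if (length(bad)) stop("chromosomes missing from genome: ",
                        paste(bad, collapse = ", "))
  out <- vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chr[i]]], start(gr)[i],
                                    end(gr)[i]))
  }, character(1L))
  nm <- mcols(gr)$name
  names(out) <- if (!is.null(nm)) nm else paste0("region_", seq_along(gr))
  out
}

#' Assign each peak to its nearest TSS
#'
#' Distance is measured from the peak anchor (summit when present, interval
#' midpoint otherwise) to the TSS position, and reported signed on the
#' gene's strand: negative means the peak lies upstream of the TSS,
#' positive downstream. Ties in absolute distance break to the
#' lexicographically smaller gene id. Peaks on chromosomes without any TSS
#' get `gene_id = NA`, `tss_distance = Inf`, with a warning.
#'
#' @param peaks `GRanges`, optionally with a `summit` metadata column.
#' @param tss `GRanges` of width-1 TSS positions with a `name` (gene id)
#'   metadata column; unstranded records are treated as `+` with a warning.
#' @return `peaks` with metadata columns `nearest_gene` and `tss_distance`
#'   (signed bp) added.
#' @export
nearestTSS <- function(peaks, tss) {
  if (!length(tss)) stop("empty TSS table")
  gene <- mcols(tss)$name
  if (is.null(gene)) stop("TSS table needs a 'name' (gene id) column")
  tstr <- as.character(strand(tss))
  if (any(tstr == "*")) {
    warning("unstranded TSS records treated as '+' strand")
    tstr[tstr == "*"] <- "+"
  }
  anchor <- mcols(peaks)$summit
  if (is.null(anchor)) anchor <- rep(NA_integer_, length(peaks))
  mid <- (start(peaks) + end(peaks)) %/% 2L
  anchor <- ifelse(is.na(anchor), mid, anchor)
  tpos <- start(tss)
  tchr <- as.character(seqnames(tss))
  pchr <- as.character(seqnames(peaks))

  gene_out <- rep(NA_character_, length(peaks))
  dist_out <- rep(Inf, length(peaks))
  for (chr in unique(pchr)) {
    pi <- which(pchr == chr)
    ti <- which(tchr == chr)
    if (!length(ti)) next
    # order TSSs by position then gene id so that, at equal distance,
    # findInterval neighbours expose the lexicographically smaller gene first
    o <- order(tpos[ti], gene[ti])
    ti <- ti[o]
    pos <- tpos[ti]
    a <- anchor[pi]
    first_of <- match(pos, pos) # first index among TSSs sharing a position
    right <- findInterval(a, pos) # index of rightmost TSS <= a (0 if none)
    left_idx <- first_of[pmax(right, 1L)]
    right_idx <- pmin(right + 1L, length(pos))
    d_left <- abs(a - pos[left_idx]); d_left[right == 0L] <- Inf
    d_right <- abs(pos[right_idx] - a); d_right[right >= length(pos)] <- Inf
    g_left <- gene[ti][left_idx]; g_right <- gene[ti][right_idx]
    use_left <- d_left < d_right |
      (d_left == d_right & g_left <= g_right)
    best <- ifelse(use_left, ti[left_idx], ti[right_idx])
    gene_out[pi] <- gene[best]
    delta <- a - tpos[best]                       # + strand: downstream > 0
    dist_out[pi] <- ifelse(tstr[best] == "-", -delta, delta)
  }
  if (anyNA(gene_out)) {
    warning(sum(is.na(gene_out)),
            " peak(s) on chromosomes without any TSS; assigned NA / Inf")
  }
  mcols(peaks)$nearest_gene <- gene_out
  mcols(peaks)$tss_distance <- dist_out
  peaks
}
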