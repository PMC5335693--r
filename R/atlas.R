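#' Bin fragment signal around peak anchors
#'
#' Builds the elements x bins matrix behind summit-centered signal heatmaps:
#' each fragment contributes one count to the bin containing its midpoint
#' (symmetric under strand; a 5'-cut-site mode is available), within a
#' `window`-bp window centered on each element's anchor, split into
#' `bin_width`-bp bins. The conventional layout is 5 bp bins over a 3 kb
#' summit-centered window.
#'
#' @param elements `GRanges`; needs a `summit` column when
#'   `anchor = "summit"`.
#' @param fragments `GRanges` of fragments.
#' @param window window size in bp, divisible by `bin_width`.
#' @param bin_width bin size in bp.
#' @param anchor `"summit"` or `"midpoint"`.
#' @param mode `"midpoint"` counts fragment midpoints; `"cut"` counts both
#'   fragment ends (Tn5 insertion sites).
#' @param per_million divide by (total fragments / 1e6) if `TRUE`.
#' @return numeric matrix, rows = elements (named by `name` when present),
#'   columns = bins left to right; attributes `bin_width`, `window`,
#'   `anchor`.
#' @export
quantifySignal <- function(elements, fragments, window = 3000L,
                           bin_width = 5L, anchor = c("summit", "midpoint"),
                           mode = c("midpoint", "cut"),
                           per_million = FALSE) {
  anchor <- match.arg(anchor)
  mode <- match.arg(mode)
  if (window %% bin_width != 0L) {
    stop("window (", window, ") must be divisible by bin_width (", bin_width,
         ")")
  }
  n_bins <- window %/% bin_width
  apos <- if (anchor == "summit") {
    s <- mcols(elements)$summit
    if (is.null(s) || anyNA(s)) stop("anchor 'summit' requires a summit for ",
                                     "every element")
    s
  } else {
    (start(elements) + end(elements)) %/% 2L
  }
  if (mode == "midpoint") {
    fpos <- (start(fragments) + end(fragments)) %/% 2L
    fchr <- as.character(seqnames(fragments))
  } else {
    fpos <- c(start(fragments), end(fragments))
    fchr <- rep(as.character(seqnames(fragments)), 2L)
  }
  mat <- matrix(0, nrow = length(elements), ncol = n_bins)
  echr <- as.character(seqnames(elements))
  half <- window %/% 2L
  for (chr in unique(echr)) {
    ei <- which(echr == chr)
    p <- fpos[fchr == chr]
    if (!length(p)) next
    for (i in ei) {
      # bin j covers anchor - window/2 + [ (j-1)*bin, j*bin )
      rel <- p - (apos[i] - half)
      keep <- rel >= 0L & rel < window
      if (any(keep)) {
        tab <- tabulate(rel[keep] %/% bin_width + 1L, nbins = n_bins)
        mat[i, ] <- mat[i, ] + tab
      }
    }
  }
  if (per_million) mat <- mat / (length(fragments) / 1e6)
  nm <- mcols(elements)$name
  if (!is.null(nm)) rownames(mat) <- nm
  structure(mat, bin_width = bin_width, window = window, anchor = anchor)
}

#' Partition atlas elements into promoters and enhancers
#'
#' Promoter: the signed summit-to-TSS distance `d` satisfies
#' `-1000 < d < +100` on the gene's strand (strictly less than 1 kb upstream
#' and strictly less than 100 bp downstream of the nearest TSS); everything
#' else is an enhancer. The partition is exhaustive and exclusive.
#'
#' @param elements `GRanges`; `nearestTSS()` is applied first if the
#'   `tss_distance` column is absent (requires `tss`).
#' @param tss optional TSS `GRanges` (see [nearestTSS()]).
#' @param upstream,downstream open bounds of the promoter window in bp.
#' @return `elements` with a `region_class` factor column
#'   (`promoter`/`enhancer`).
#' @export
partitionPromoterEnhancer <- function(elements, tss = NULL,
                                      upstream = 1000L, downstream = 100L) {
  if (is.null(mcols(elements)$tss_distance)) {
    if (is.null(tss)) stop("elements lack tss_distance; supply a TSS table")
    elements <- nearestTSS(elements, tss)
  }
  d <- mcols(elements)$tss_distance
  promoter <- !is.na(d) & is.finite(d) & d > -upstream & d < downstream
  mcols(elements)$region_class <- factor(ifelse(promoter, "promoter",
                                                "enhancer"),
                                         levels = c("promoter", "enhancer"))
  elements
}

#' Annotate and filter elements by repeat overlap
#'
#' `repeatFraction` computes, per element, the fraction of its bases covered
#' by repeat intervals; `repeatFilter` drops elements whose fraction is
#' strictly greater than `max_fraction` (default 0.70, so exactly 70%
#' overlap is kept).
#'
#' @param elements `GRanges`.
#' @param repeats `GRanges` of repeat-masked intervals.
#' @param max_fraction strict upper bound on repeat overlap fraction.
#' @return `repeatFraction`: `elements` with a `repeat_fraction` column;
#'   `repeatFilter`: the surviving elements (fraction column attached).
#' @export
repeatFraction <- function(elements, repeats) {
  red <- reduce(repeats, ignore.strand = TRUE)
  hits <- findOverlaps(elements, red, ignore.strand = TRUE)
  ov <- width(IRanges::pintersect(
    IRanges::ranges(elements)[queryHits(hits)],
    IRanges::ranges(red)[subjectHits(hits)]))
  covered <- rep(0L, length(elements))
  if (length(hits)) {
    agg <- rowsum(ov, queryHits(hits))
    covered[as.integer(rownames(agg))] <- agg[, 1L]
  }
  mcols(elements)$repeat_fraction <- covered / width(elements)
  elements
}

#' @rdname repeatFraction
#' @export
repeatFilter <- function(elements, repeats, max_fraction = 0.70) {
  elements <- repeatFraction(elements, repeats)
  elements[mcols(elements)$repeat_fraction <= max_fraction]
}

#' Fraction of one peak set overlapping another
#'
#' Asymmetric: the fraction of `set_a` elements sharing at least 1 bp with
#' any `set_b` element.
#'
#' @param set_a,set_b `GRanges`.
#' @return a single fraction in `[0, 1]`.
#' @export
overlapFraction <- function(set_a, set_b) {
  if (!length(set_a)) stop("overlap fraction undefined for an empty query set")
  mean(countOverlaps(set_a, set_b, ignore.strand = TRUE) > 0L)
}

#' Classify atlas elements by photoreceptor specificity
#'
#' Combines a rod-vs-cone differential accessibility table with
#' non-photoreceptor peak sets: significantly more open in rods =>
#' `rod_specific`; significantly more open in cones => `cone_specific`; not
#' significant => `shared_PR`; any element overlapping (>= 1 bp) a
#' non-photoreceptor peak set is flagged `non_PR` regardless of the test.
#' When `filtered = TRUE`, a cascade of enhancer-focused filters is applied
#' (promoter removal, non-PR removal, repeat filter, in that order) and
#' per-stage survivor counts are attached as the `filter_cascade` attribute.
#'
#' @param elements `GRanges` atlas with `name` (and `region_class` /
#'   `repeat_fraction` columns when `filtered = TRUE`).
#' @param diff tibble-like data.frame from [nbDiffTest()] with rods as group
#'   A and cones as group B; `feature` must cover every element name.
#' @param non_pr_peaks optional list of `GRanges` for non-photoreceptor
#'   samples.
#' @param filtered apply the promoter / non-PR / repeat filter cascade.
#' @param repeats repeat intervals, required when `filtered = TRUE`.
#' @param max_repeat_fraction passed to [repeatFilter()].
#' @return `elements` with a `specificity` factor column; when filtered, the
#'   surviving subset with a `filter_cascade` attribute (named integer
#'   vector of per-stage survivor counts).
#' @export
classifySpecificity <- function(elements, diff, non_pr_peaks = list(),
                                filtered = FALSE, repeats = NULL,
                                max_repeat_fraction = 0.70) {
  nm <- mcols(elements)$name
  if (is.null(nm)) stop("elements need a 'name' column")
  idx <- match(nm, diff$feature)
  if (anyNA(idx)) {
    stop("elements absent from differential results: ",
         paste(head(nm[is.na(idx)], 5L), collapse = ", "))
  }
  call <- as.character(diff$call[idx])
  spec <- ifelse(call == "A_up", "rod_specific",
                 ifelse(call == "B_up", "cone_specific", "shared_PR"))
  if (length(non_pr_peaks)) {
    pooled <- reduce(suppressWarnings(
      do.call(c, unname(lapply(non_pr_peaks, granges)))), ignore.strand = TRUE)
    non_pr <- countOverlaps(elements, pooled, ignore.strand = TRUE) > 0L
    spec[non_pr] <- "non_PR"
  }
  mcols(elements)$specificity <- factor(spec, levels = .PEAK_CLASSES)
  if (!filtered) return(elements)

  cascade <- c(all = length(elements))
  kept <- elements
  rc <- mcols(kept)$region_class
  if (is.null(rc)) stop("filtered classification needs region_class ",
                        "(run partitionPromoterEnhancer first)")
  kept <- kept[rc != "promoter"]
  cascade["non_promoter"] <- length(kept)
  kept <- kept[mcols(kept)$specificity != "non_PR"]
  cascade["photoreceptor_only"] <- length(kept)
  if (is.null(repeats)) stop("filtered classification needs a repeat track")
  kept <- repeatFilter(kept, repeats, max_repeat_fraction)
  cascade["repeat_filtered"] <- length(kept)
  attr(kept, "filter_cascade") <- cascade
  kept
}
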