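#' @importFrom Biostrings DNAString matchPattern start
#' @importFrom stats wilcox.test median
NULL

#' K50 homeodomain monomer/dimer k-mer scheme
#'
#' The exact-match k-mer classes describing K50 homeodomain core
#' configurations: the TAAT and TAAG 4-bp monomer cores (with reverse
#' complements ATTA and CTTA) and the inverted-repeat dimer configurations
#' with a fixed 3-nt spacer: homotypic `TAAT[N]3ATTA`, homotypic 3'G
#' `TAAG[N]3CTTA`, and heterotypic `TAAT[N]3CTTA` (whose reverse complement
#' is `TAAG[N]3ATTA`). Each class is closed under reverse complement. The
#' spacer defaults to exactly 3 nt; a range can be supplied.
#'
#' @param spacer integer vector of allowed spacer lengths (default 3).
#' @return named list of classes; each entry is a character vector of the
#'   literal patterns (IUPAC `N` for spacer positions) matched on the
#'   forward strand.
#' @export
dimerKmerScheme <- function(spacer = 3L) {
  spc <- vapply(spacer, function(k) strrep("N", k), character(1L))
  pat <- function(a, b) paste0(a, spc, b)
  list(
    monomer_TAAT = c("TAAT", "ATTA"),
    monomer_TAAG = c("TAAG", "CTTA"),
    homotypic_TAAT = pat("TAAT", "ATTA"),
    homotypic_TAAG = pat("TAAG", "CTTA"),
    heterotypic = c(pat("TAAT", "CTTA"), pat("TAAG", "ATTA"))
  )
}

# vectorized presence scan over many sequences: one vmatchPattern pass per
# literal pattern instead of per (sequence, pattern)
.scan_kmer_presence <- function(sequences, scheme = dimerKmerScheme()) {
  x <- Biostrings::DNAStringSet(sequences)
  pres <- matrix(FALSE, length(x), length(scheme),
                 dimnames = list(names(sequences), names(scheme)))
  for (cl in names(scheme)) {
    for (pat in scheme[[cl]]) {
      hit <- lengths(Biostrings::vmatchPattern(pat, x, fixed = FALSE)) > 0L
      pres[, cl] <- pres[, cl] | hit
    }
  }
  pres
}

.match_offsets <- function(sequence, pattern) {
  m <- matchPattern(pattern, DNAString(sequence), fixed = FALSE)
  Biostrings::start(m) - 1L                      # 0-based offsets
}

#' Scan a sequence for homeodomain k-mer classes
#'
#' Exact matching on the forward strand of each class's literal patterns
#' (which already include the reverse-complement forms, so the call is
#' strand-symmetric). Spacer positions (`N`) match any base.
#'
#' @param sequence a single DNA string over `A,C,G,T`.
#' @param scheme a scheme from [dimerKmerScheme()].
#' @return list with `classes` (character vector of present class names)
#'   and `offsets` (named list of 0-based match offsets per present class).
#' @export
scanKmers <- function(sequence, scheme = dimerKmerScheme()) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("exact k-mer matching requires sequences over {A,C,G,T}")
  }
  offsets <- lapply(scheme, function(pats) {
    sort(unique(unlist(lapply(pats, .match_offsets, sequence = sequence))))
  })
  present <- names(offsets)[lengths(offsets) > 0L]
  list(classes = present, offsets = offsets[present])
}

#' Eliminate CRX binding sites by point mutation
#'
#' Replaces every forward-strand `CTAATCC` by `CTACTCC` and every
#' reverse-strand occurrence (`GGATTAG` on the forward strand) by `GGAGTAG`,
#' left to right and non-overlapping — the canonical single-base knockout of
#' the K50 homeodomain core in reporter constructs. Idempotent.
#'
#' @param sequence a DNA string.
#' @return the mutated sequence.
#' @export
mutateCrxSites <- function(sequence) {
  s <- gsub("CTAATCC", "CTACTCC", as.character(sequence), fixed = TRUE)
  gsub("GGATTAG", "GGAGTAG", s, fixed = TRUE)
}

#' Stratify reporter expression by k-mer class
#'
#' Splits constructs of one variant class into those carrying vs lacking a
#' k-mer class and compares expression with a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction; optionally exact for
#' small groups, falling back to a Monte-Carlo rank-sum permutation when
#' ties forbid the exact distribution).
#'
#' @param constructs data.frame with columns `variant_class`, `expression`,
#'   and logical class-presence columns (or a `kmer_labels` list column).
#' @param class_label name of the k-mer class to stratify on.
#' @param variant which variant class to analyze (default `"native"`).
#' @param exact use the exact/permutation null when both groups have
#'   `n <= 20`.
#' @param n_perm Monte-Carlo permutations for the tied small-n fallback.
#' @return list: `n_with`, `n_without`, `median_with`, `median_without`,
#'   `median_difference` (with minus without), `p_value`.
#' @export
stratifyExpression <- function(constructs, class_label,
                               variant = "native", exact = FALSE,
                               n_perm = 10000L) {
  sub <- constructs[constructs$variant_class == variant, , drop = FALSE]
  if (!nrow(sub)) stop("no constructs in variant class '", variant, "'")
  if (class_label %in% names(sub)) {
    has <- as.logical(sub[[class_label]])
  } else if ("kmer_labels" %in% names(sub)) {
    has <- vapply(sub$kmer_labels, function(k) class_label %in% k,
                  logical(1L))
  } else {
    stop("constructs carry no presence column for class '", class_label, "'")
  }
  x <- sub$expression[has]
  y <- sub$expression[!has]
  if (!length(x)) stop("empty stratum: constructs with '", class_label, "'")
  if (!length(y)) stop("empty stratum: constructs without '", class_label,
                       "'")
  if (exact && length(x) <= 20L && length(y) <= 20L) {
    if (!anyDuplicated(c(x, y))) {
      p <- wilcox.test(x, y, exact = TRUE)$p.value
    } else {
      obs <- sum(rank(c(x, y))[seq_along(x)])
      null <- replicate(n_perm, {
        r <- rank(c(x, y))[sample.int(length(x) + length(y))]
        sum(r[seq_along(x)])
      })
      p <- mean(abs(null - mean(null)) >= abs(obs - mean(null)))
      p <- max(p, 1 / n_perm)
    }
  } else {
    p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  if (identical(sort(x), sort(y))) p <- 1 # identical groups: no evidence
  list(n_with = length(x), n_without = length(y),
       median_with = median(x), median_without = median(y),
       median_difference = median(x) - median(y),
       p_value = p)
}
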