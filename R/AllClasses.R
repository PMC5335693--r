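#' @import methods
#' @importFrom S4Vectors SimpleList mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Position weight matrix with log-odds scoring metadata
#'
#' A `PWMotif` stores a motif as a 4 x width matrix of per-position base
#' probabilities (rows A, C, G, T), a background base composition, and a
#' default log-odds score threshold. Scoring uses natural-log odds
#' (`sum(log(p/q))` over matched positions), the convention under which a
#' "relaxed threshold of 5" is meaningful for typical 8-12 bp motifs.
#'
#' @slot name single motif identifier.
#' @slot consensus consensus string (argmax base per column).
#' @slot matrix 4 x width numeric matrix, columns sum to 1.
#' @slot background length-4 base probabilities used for log-odds.
#' @slot threshold default log-odds hit threshold (natural-log units).
#' @slot score optional enrichment score attached by upstream analyses
#'   (used to rank motifs during redundancy collapse); `NA_real_` if unset.
#'
#' @examples
#' m <- PWMotif("toy", matrix(c(.97,.01,.01,.01,
#'                              .01,.01,.01,.97), nrow = 4))
#' motifWidth(m)
#' @export
setClass("PWMotif",
  representation(
    name = "character",
    consensus = "character",
    matrix = "matrix",
    background = "numeric",
    threshold = "numeric",
    score = "numeric"
  )
)

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L) msg <- c(msg, "matrix must have 4 rows (A,C,G,T)")
  if (ncol(m) < 1L) msg <- c(msg, "motif width must be >= 1")
  if (any(m <= 0)) msg <- c(msg, "probabilities must be > 0 after smoothing")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    msg <- c(msg, "each position's base probabilities must sum to 1 (+/- 1e-6)")
  }
  if (length(object@background) != 4L || any(object@background <= 0)) {
    msg <- c(msg, "background must be 4 positive probabilities")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(msg)) msg else TRUE
})

#' Collection of PWMotif objects
#'
#' A thin `SimpleList` subclass holding named [PWMotif] objects; behaves as a
#' list (`[[`, `length`, `names`) with a compact show method.
#'
#' @export
setClass("MotifLibrary", contains = "SimpleList",
  prototype = prototype(elementType = "PWMotif"))

#' Simulation configuration for the synthetic photoreceptor dataset
#'
#' Parameters controlling every layer of the simulated study: genome, closed
#' domains, peak universe, fragment/count generation, planted motifs, gene
#' expression coupling, and the reporter (CRE-seq style) library. The defaults
#' encode the study conditions the pipeline is designed around: three
#' photoreceptor groups (rod, green cone, blue cone) with replicates, a peak
#' universe dominated by shared photoreceptor peaks with ~10x more
#' cone-specific than rod-specific peaks, megabase-scale rod-closed domains
#' that preferentially host the cone-specific peaks, and negative-binomial
#' counts with a planted |log2 fold change| of 2 between open and closed
#' states.
#'
#' @slot genome_length total genome size in bp.
#' @slot n_chromosomes number of chromosomes (genome split evenly).
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @slot n_replicates_per_group replicates for each of rod / green cone /
#'   blue cone.
#' @slot peak_counts named integer vector over classes `shared_PR`,
#'   `rod_specific`, `cone_specific`, `non_PR`.
#' @slot closed_domain_lengths,closed_domain_counts parallel vectors giving
#'   rod-closed domain spans (bp) and how many of each to place.
#' @slot nb_mean_open,nb_mean_closed expected fragment counts for a peak in
#'   its open / closed state.
#' @slot nb_dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @slot lfc_planted planted log2 fold change for class-specific peaks.
#' @slot n_genes number of genes / TSS records.
#' @slot expr_coupling probability that a differential peak's nearest gene is
#'   concordantly differential.
#' @slot motif_plant_rates named list: peak class -> named numeric vector of
#'   per-motif planting probabilities.
#' @slot cre_n_constructs native reporter constructs per arm.
#' @slot cre_repression_effect downward expression shift (in reporter sd
#'   units) for native constructs carrying the homotypic TAAT dimer.
#'
#' @seealso [simulateDataset()]
#' @export
setClass("SimConfig",
  representation(
    genome_length = "numeric",
    n_chromosomes = "integer",
    seed = "integer",
    n_replicates_per_group = "integer",
    peak_counts = "integer",
    closed_domain_lengths = "numeric",
    closed_domain_counts = "integer",
    nb_mean_open = "numeric",
    nb_mean_closed = "numeric",
    nb_dispersion = "numeric",
    lfc_planted = "numeric",
    n_genes = "integer",
    expr_coupling = "numeric",
    motif_plant_rates = "list",
    cre_n_constructs = "integer",
    cre_repression_effect = "numeric"
  )
)

.PEAK_CLASSES <- c("shared_PR", "rod_specific", "cone_specific", "non_PR")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genome_length < 1e4) msg <- c(msg, "genome_length too small")
  if (object@n_chromosomes < 1L) msg <- c(msg, "need >= 1 chromosome")
  if (!setequal(names(object@peak_counts), .PEAK_CLASSES)) {
    msg <- c(msg, sprintf("peak_counts must be named over: %s",
                          paste(.PEAK_CLASSES, collapse = ", ")))
  }
  if (any(object@peak_counts < 0L)) msg <- c(msg, "peak counts must be >= 0")
  if (object@nb_dispersion <= 0) msg <- c(msg, "nb_dispersion must be > 0")
  if (object@nb_mean_open <= 0 || object@nb_mean_closed <= 0) {
    msg <- c(msg, "NB means must be > 0")
  }
  if (object@expr_coupling < 0 || object@expr_coupling > 1) {
    msg <- c(msg, "expr_coupling must be in [0, 1]")
  }
  if (length(object@closed_domain_lengths) !=
      length(object@closed_domain_counts)) {
    msg <- c(msg, "closed domain lengths and counts must be parallel")
  }
  rates <- unlist(object@motif_plant_rates, use.names = FALSE)
  if (length(rates) && (any(rates < 0) || any(rates > 1))) {
    msg <- c(msg, "motif_plant_rates must be probabilities in [0, 1]")
  }
  if (object@n_replicates_per_group < 1L) {
    msg <- c(msg, "need >= 1 replicate per group")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s' (width %d, consensus %s, threshold %.2f)\n",
              object@name, ncol(object@matrix), object@consensus,
              object@threshold))
})

setMethod("show", "MotifLibrary", function(object) {
  cat(sprintf("MotifLibrary of %d motifs: %s\n", length(object),
              paste(utils::head(names(object), 8L), collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genome: %s bp over %d chromosome(s), seed %d\n",
              format(object@genome_length, big.mark = ","),
              object@n_chromosomes, object@seed))
  cat(sprintf("  peaks: %s\n",
              paste(sprintf("%s=%d", names(object@peak_counts),
                            object@peak_counts), collapse = ", ")))
  cat(sprintf("  groups: rod / green_cone / blue_cone x %d replicates\n",
              object@n_replicates_per_group))
  cat(sprintf("  NB: mean open %.0f, closed %.0f, dispersion %.3g, planted LFC %.1f\n",
              object@nb_mean_open, object@nb_mean_closed,
              object@nb_dispersion, object@lfc_planted))
})
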