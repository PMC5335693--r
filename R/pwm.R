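.BASES <- c("A", "C", "G", "T")

.consensus_of <- function(mat) {
  paste(.BASES[apply(mat, 2L, which.max)], collapse = "")
}

#' Construct a PWMotif
#'
#' Builds a [PWMotif] from a 4 x width probability matrix. Zero (or tiny)
#' probabilities are epsilon-smoothed before renormalization so that log-odds
#' scores are finite; motif files in the wild routinely contain exact zeros.
#'
#' @param name motif identifier.
#' @param matrix 4 x width numeric matrix of base probabilities
#'   (rows A, C, G, T), or a width x 4 matrix (auto-transposed).
#' @param background base composition for log-odds (default uniform).
#' @param threshold default log-odds hit threshold, natural-log units.
#' @param score optional enrichment score used for redundancy-collapse ranking.
#' @param epsilon smoothing floor added to every probability before
#'   renormalization.
#' @return a `PWMotif`.
#' @export
PWMotif <- function(name, matrix, background = rep(0.25, 4),
                    threshold = 5, score = NA_real_, epsilon = 1e-3) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
  if (nrow(m) != 4L) stop("PWMotif matrix must be 4 x width (rows A,C,G,T)")
  # smooth only when needed so that re-reading a written motif is stable
  if (any(m <= 0)) m <- m + epsilon
  if (any(abs(colSums(m) - 1) > 1e-6)) m <- sweep(m, 2L, colSums(m), "/")
  rownames(m) <- .BASES
  new("PWMotif", name = as.character(name), consensus = .consensus_of(m),
      matrix = m, background = background / sum(background),
      threshold = threshold, score = score)
}

#' @describeIn PWMotif motif width (number of positions).
#' @param x a `PWMotif`.
#' @export
motifWidth <- function(x) ncol(x@matrix)

#' @describeIn PWMotif the 4 x width probability matrix.
#' @export
motifMatrix <- function(x) x@matrix

#' @describeIn PWMotif the motif name.
#' @export
motifName <- function(x) x@name

#' @describeIn PWMotif the consensus sequence (argmax base per position).
#' @export
motifConsensus <- function(x) x@consensus

#' @describeIn PWMotif the per-motif enrichment score (NA if unset).
#' @export
motifScore <- function(x) x@score

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps complementary base rows, so the
#' returned motif scores the opposite strand.
#'
#' @param x a [PWMotif].
#' @param ... ignored.
#' @return a `PWMotif` for the reverse complement.
#' @importFrom Biostrings reverseComplement
#' @export
#' @aliases reverseComplement,PWMotif-method
setMethod("reverseComplement", "PWMotif", function(x, ...) {
  m <- x@matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(x@matrix))),
                drop = FALSE]
  rownames(m) <- .BASES
  initialize(x, matrix = m, consensus = .consensus_of(m))
})

#' Construct a MotifLibrary
#'
#' @param ... `PWMotif` objects, or a single list of them.
#' @return a [MotifLibrary] named by motif names.
#' @export
MotifLibrary <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "PWMotif")) {
    xs <- xs[[1L]]
  }
  ok <- vapply(xs, is, logical(1L), class2 = "PWMotif")
  if (!all(ok)) stop("all elements must be PWMotif objects")
  names(xs) <- vapply(xs, motifName, character(1L))
  new("MotifLibrary", SimpleList(xs))
}

#' Read / write HOMER-style motif files
#'
#' The format is a header line `>consensus<TAB>name<TAB>threshold` followed by
#' one line per motif position with four tab-separated base probabilities
#' (A, C, G, T). `readHomerMotifs` smooths zeros via [PWMotif()];
#' `writeHomerMotifs` writes probabilities at full precision so that a
#' read/write round trip is lossless up to the smoothing applied on first
#' read.
#'
#' @param path file path.
#' @return `readHomerMotifs`: a [MotifLibrary].
#' @export
readHomerMotifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no motif headers ('>') found in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  motifs <- lapply(seq_along(hdr), function(i) {
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "\t")[[1L]]
    name <- if (length(fields) >= 2L) fields[2L] else fields[1L]
    thr <- if (length(fields) >= 3L) as.numeric(fields[3L]) else 5
    body <- lines[(hdr[i] + 1L):ends[i]]
    rows <- lapply(seq_along(body), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(body[j], "\t")[[1L]]))
      if (length(v) != 4L || anyNA(v)) {
        stop(sprintf("malformed probability row %d of motif '%s'", j, name))
      }
      v
    })
    PWMotif(name, t(do.call(rbind, rows)), threshold = thr)
  })
  MotifLibrary(motifs)
}

#' @rdname readHomerMotifs
#' @param library a [MotifLibrary].
#' @export
writeHomerMotifs <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in as.list(library)) {
    writeLines(sprintf(">%s\t%s\t%.6g", motifConsensus(m), motifName(m),
                       m@threshold), con)
    apply(motifMatrix(m), 2L, function(p) {
      writeLines(paste(sprintf("%.10f", p), collapse = "\t"), con)
    })
  }
  invisible(path)
}

#' Trim low-information flanking positions from a PWM
#'
#' Removes leading and trailing columns whose information content
#' (`2 + sum(p * log2(p))`) is below `min_bits`; interior columns are never
#' removed even if uninformative.
#'
#' @param pwm a [PWMotif].
#' @param min_bits strict lower bound in bits (default 1.0).
#' @return the trimmed `PWMotif`.
#' @export
trimLowInfo <- function(pwm, min_bits = 1.0) {
  m <- motifMatrix(pwm)
  ic <- apply(m, 2L, function(p) 2 + sum(p * log2(p)))
  keep <- ic >= min_bits
  if (!any(keep)) stop("all positions fall below the information threshold")
  i1 <- which(keep)[1L]
  i2 <- rev(which(keep))[1L]
  m2 <- m[, i1:i2, drop = FALSE]
  initialize(pwm, matrix = m2, consensus = .consensus_of(m2))
}
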