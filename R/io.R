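#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqnames
#' @importFrom utils read.table write.table head
NULL

# All genomic coordinates in files follow the BED convention: 0-based,
# half-open.  In-memory GRanges are 1-based closed as usual for
# Bioconductor; readers/writers convert at the boundary.  The `summit`
# metadata column, when present, is an absolute 1-based position.

.read_tsv_checked <- function(path, n_min_fields, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min_fields)
  if (length(bad)) {
    stop(sprintf("%s line %d has %d field(s); expected >= %d", what,
                 bad[1L], nf[bad[1L]], n_min_fields))
  }
  fields
}

.check_coords <- function(start0, end0, what, lines = seq_along(start0)) {
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric start/end", what, lines[bad[1L]]))
  }
  bad <- which(start0 < 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: negative start %d", what, lines[bad[1L]],
                 start0[bad[1L]]))
  }
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop(sprintf("%s line %d: end (%d) must exceed start (%d)", what,
                 lines[bad[1L]], end0[bad[1L]], start0[bad[1L]]))
  }
  invisible(TRUE)
}

#' Read and write narrowPeak files
#'
#' Ten-column ENCODE narrowPeak. Column 10 is the summit offset from the
#' 0-based peak start (-1 for "no summit"); it is surfaced as an absolute
#' 1-based `summit` metadata column (`NA` when absent). A read/write round
#' trip reproduces canonical records byte-for-byte.
#'
#' @param path file path.
#' @return `readNarrowPeak`: a [GenomicRanges::GRanges] with metadata columns
#'   `name`, `score`, `signalValue`, `pValue`, `qValue`, `summit`.
#' @export
readNarrowPeak <- function(path) {
  fields <- .read_tsv_checked(path, 10L, "narrowPeak")
  if (is.null(fields)) return(GRanges(summit = integer()))
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  .check_coords(start0, end0, "narrowPeak")
  off <- suppressWarnings(as.integer(m[, 10L]))
  if (anyNA(off)) {
    stop(sprintf("narrowPeak line %d: non-integer summit offset",
                 which(is.na(off))[1L]))
  }
  summit <- ifelse(off < 0L, NA_integer_, start0 + off + 1L)
  bad <- which(!is.na(summit) & (summit <= start0 | summit > end0))
  if (length(bad)) {
    stop(sprintf("narrowPeak line %d: summit offset %d outside interval",
                 bad[1L], off[bad[1L]]))
  }
  gr <- GRanges(m[, 1L], IRanges(start0 + 1L, end0),
                strand = ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*"))
  mcols(gr) <- DataFrame(name = m[, 4L],
                         score = suppressWarnings(as.numeric(m[, 5L])),
                         signalValue = suppressWarnings(as.numeric(m[, 7L])),
                         pValue = suppressWarnings(as.numeric(m[, 8L])),
                         qValue = suppressWarnings(as.numeric(m[, 9L])),
                         summit = summit)
  gr
}

#' @rdname readNarrowPeak
#' @param peaks a `GRanges` as produced by `readNarrowPeak` (missing metadata
#'   columns are filled with format defaults).
#' @export
writeNarrowPeak <- function(peaks, path) {
  n <- length(peaks)
  mc <- mcols(peaks)
  g <- function(col, default) if (col %in% names(mc)) mc[[col]] else
    rep(default, n)
  summit <- g("summit", NA_integer_)
  off <- ifelse(is.na(summit), -1L, summit - start(peaks))
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = g("name", "."),
    score = g("score", 0),
    strand = sub("\\*", ".", as.character(strand(peaks))),
    signalValue = g("signalValue", 0),
    pValue = g("pValue", -1),
    qValue = g("qValue", -1),
    peak = off)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write BED files
#'
#' BED3/BED6 (extra columns beyond 6 are ignored on read). Coordinates are
#' 0-based half-open on disk, 1-based closed in the returned `GRanges`.
#'
#' @param path file path.
#' @return `readBed`: a `GRanges`; BED6 columns become `name` and `score`
#'   metadata.
#' @export
readBed <- function(path) {
  fields <- .read_tsv_checked(path, 3L, "BED")
  if (is.null(fields)) return(GRanges())
  nf <- min(lengths(fields))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(nf)))
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  .check_coords(start0, end0, "BED")
  str <- if (nf >= 6L) ifelse(m[, 6L] %in% c("+", "-"), m[, 6L], "*") else "*"
  gr <- GRanges(m[, 1L], IRanges(start0 + 1L, end0), strand = str)
  if (nf >= 4L) mcols(gr)$name <- m[, 4L]
  if (nf >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(m[, 5L]))
  gr
}

#' @rdname readBed
#' @param gr a `GRanges`; written as BED6 if it carries `name`/`score`/strand
#'   information, BED3 otherwise.
#' @export
writeBed <- function(gr, path) {
  mc <- mcols(gr)
  has6 <- any(c("name", "score") %in% names(mc)) ||
    any(as.character(strand(gr)) != "*")
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (has6) {
    df$name <- if ("name" %in% names(mc)) mc$name else "."
    df$score <- if ("score" %in% names(mc)) mc$score else 0
    df$strand <- sub("\\*", ".", as.character(strand(gr)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write fragment tables
#'
#' Three-column TSV (chrom, start, end; 0-based half-open), the minimal
#' BEDPE-like representation of sequenced fragments. The documented entry
#' point for alignment-derived data is a fragment table exported upstream
#' (e.g. with `bedtools bamtobed`); BAM parsing is out of scope.
#'
#' @param path file path.
#' @return `readFragments`: a `GRanges` with an `insert_size` metadata column
#'   (`width`, i.e. end - start in 0-based coordinates).
#' @export
readFragments <- function(path) {
  fields <- .read_tsv_checked(path, 3L, "fragment")
  if (is.null(fields)) return(GRanges(insert_size = integer()))
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  .check_coords(start0, end0, "fragment")
  gr <- GRanges(m[, 1L], IRanges(start0 + 1L, end0))
  mcols(gr)$insert_size <- end0 - start0
  gr
}

#' @rdname readFragments
#' @param fragments a `GRanges` of fragments.
#' @export
writeFragments <- function(fragments, path) {
  df <- data.frame(chrom = as.character(seqnames(fragments)),
                   start = start(fragments) - 1L, end = end(fragments))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#'
#' @param path TSV with chromosome name and length.
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  fields <- .read_tsv_checked(path, 2L, "chrom.sizes")
  if (is.null(fields)) stop("empty chrom.sizes file: ", path)
  m <- do.call(rbind, lapply(fields, `[`, 1:2))
  sizes <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(sizes)) stop("chrom.sizes line ", which(is.na(sizes))[1L],
                         ": non-integer length")
  stats::setNames(sizes, m[, 1L])
}

#' Write a 4-column bedGraph (no track line)
#'
#' @param gr a `GRanges` with a numeric `score` metadata column.
#' @param path output path.
#' @export
writeBedGraph <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   score = mcols(gr)$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
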