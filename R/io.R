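#' Read and write the pipeline's tabular and sequence formats
#'
#' Thin wrappers over Biostrings and base TSV I/O fixing the column
#' contracts used throughout the package: counts (transcript id + one
#' integer column per sample), sample design (sample, stage, replicate),
#' GO table (transcript, term), domain table (gene, domain), regulatory
#' map (regulator, target, optional effect).
#'
#' @param path file path.
#' @name rootapex-io
NULL

#' @rdname rootapex-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname rootapex-io
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname rootapex-io
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname rootapex-io
#' @param counts matrix transcripts x samples.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(transcript = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname rootapex-io
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "stage") %in% names(d)))
  if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
  d
}

#' @rdname rootapex-io
#' @param x a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname rootapex-io
#' @export
read_regmap <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target") %in% names(d)))
  d
}

#' Write and read similarity hits in 12-column tabular form
#'
#' The conventional tab-separated dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore); coordinates
#' are 1-based inclusive in the file and converted from/to the package's
#' 0-based half-open spans.
#'
#' @param hits data.frame of hits with the package's columns.
#' @param path file path.
#' @return `read_hits`: data.frame with file columns plus 0-based spans.
#' @export
write_hits <- function(hits, path) {
  d <- data.frame(
    qseqid = hits$query, sseqid = hits$target,
    pident = round(100 * hits$identity, 3), length = hits$length,
    mismatch = hits$length - hits$n_ident - hits$gaps,
    gapopen = hits$gapopen,
    qstart = hits$qstart + 1L, qend = hits$qend,
    sstart = hits$sstart + 1L, send = hits$send,
    evalue = format(hits$evalue, digits = 3),
    bitscore = round(hits$bits, 1), stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("qseqid", "sseqid", "pident", "length",
                                "mismatch", "gapopen", "qstart", "qend",
                                "sstart", "send", "evalue", "bitscore"))
  d$qstart0 <- d$qstart - 1L
  d$sstart0 <- d$sstart - 1L
  d
}
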