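#' Identify annotation-free transcripts among a DET set
#'
#' Returns the DETs with zero annotation records from any source. A hit
#' annotated as "uncharacterized" or "hypothetical" protein still counts
#' as an annotation (it has a hit); only transcripts entirely absent from
#' the table are candidates for lineage-specific transcripts.
#'
#' @param det_ids character vector of DET ids.
#' @param annotation_table data.frame with a `transcript` column (one row
#'   per annotation assignment; a `source` column is conventional).
#' @return sorted character vector of unannotated DET ids.
#' @export
unannotated_dets <- function(det_ids, annotation_table) {
  sort(setdiff(det_ids, unique(annotation_table$transcript)))
}

#' Flag transcripts with a significant hit in another transcriptome
#'
#' Nucleotide-mode similarity search (both strands) of each query against
#' a second species' transcript catalog; a transcript is flagged when any
#' target yields an E-value below `max_e` (database size = total length of
#' the other catalog).
#'
#' @param ids transcripts to test (must be names of `query_seqs`).
#' @param query_seqs named character vector of query sequences.
#' @param other_seqs named character vector, the other transcriptome; may
#'   be empty (no transcript is flagged).
#' @param max_e E-value threshold (default 1e-10, exclusive).
#' @return data.frame: transcript, best_evalue, hit (logical).
#' @export
cross_species_check <- function(ids, query_seqs, other_seqs, max_e = 1e-10) {
  missing <- setdiff(ids, names(query_seqs))
  if (length(missing))
    stop("missing sequence for id(s): ", paste(missing, collapse = ", "))
  if (length(other_seqs) == 0)
    return(data.frame(transcript = ids, best_evalue = NA_real_, hit = FALSE,
                      stringsAsFactors = FALSE))
  sm <- .score_matrix(query_seqs[ids], other_seqs, "nucleotide")
  dblen <- sum(nchar(other_seqs))
  best <- apply(sm$score, 1, max)
  ev <- unname(evalue(bit_score(best, "nucleotide"), nchar(query_seqs[ids]),
                      dblen))
  data.frame(transcript = ids, best_evalue = ev, hit = ev < max_e,
             stringsAsFactors = FALSE)
}

# longest ATG..stop ORF within one translated frame given codon vector;
# returns c(start_codon_idx, n_codons_peptide) or NULL
.frame_orf <- function(codons) {
  starts <- which(codons == "ATG")
  stops <- which(codons %in% .STOPS)
  if (!length(starts) || !length(stops)) return(NULL)
  best <- NULL
  for (s in starts) {
    nxt <- stops[stops > s]
    if (!length(nxt)) next
    pep <- nxt[1] - s
    if (is.null(best) || pep > best[2]) best <- c(s, pep)
  }
  best
}

#' Classify the longest open reading frame of each transcript
#'
#' Scans all six frames with the standard genetic code; a candidate ORF is
#' an ATG followed by an in-frame stop codon (the stop is required - ORFs
#' running off the contig end are not counted). The longest ORF per
#' transcript is reported, with peptide length in amino acids (Met
#' included, stop excluded) and a length class among `[200,Inf)`,
#' `[100,200)`, `[50,100)`, `[1,50)`, `none`. Coordinates are 0-based
#' half-open on the forward strand and include the stop codon.
#'
#' @param ids transcripts to scan (names of `seqs`); default all.
#' @param seqs named character vector of ACGT sequences.
#' @return data.frame: transcript, frame (+1..+3, -1..-3 or NA), start,
#'   end, peptide_aa, class.
#' @export
classify_orfs <- function(seqs, ids = names(seqs)) {
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop("missing sequence for id(s): ", paste(missing, collapse = ", "))
  rows <- lapply(ids, function(id) {
    seq <- toupper(seqs[[id]])
    bad <- regmatches(seq, regexpr("[^ACGT]", seq))
    if (length(bad) && nzchar(bad))
      stop("non-ACGT character '", bad, "' at position ",
           regexpr("[^ACGT]", seq), " of ", id)
    n <- nchar(seq)
    rc <- .revcomp(seq)
    best <- NULL
    for (f in 1:3) {
      for (str in c("+", "-")) {
        s <- if (str == "+") seq else rc
        w <- ((n - f + 1) %/% 3)
        if (w < 2) next
        codons <- substring(s, f + 3 * (0:(w - 1)), f + 3 * (0:(w - 1)) + 2)
        orf <- .frame_orf(codons)
        if (is.null(orf)) next
        if (is.null(best) || orf[2] > best$pep) {
          # nt span on the scanned strand, incl. stop codon
          from <- f + 3 * (orf[1] - 1) - 1          # 0-based
          to <- from + 3 * (orf[2] + 1)
          if (str == "-") { tmp <- from; from <- n - to; to <- n - tmp }
          best <- list(pep = as.integer(orf[2]), frame = paste0(str, f),
                       start = as.integer(from), end = as.integer(to))
        }
      }
    }
    if (is.null(best))
      return(data.frame(transcript = id, frame = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        peptide_aa = 0L, class = "none",
                        stringsAsFactors = FALSE))
    data.frame(transcript = id, frame = best$frame, start = best$start,
               end = best$end, peptide_aa = best$pep,
               class = orf_class(best$pep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peptide-length class
#'
#' Half-open bins: `[200,Inf)`, `[100,200)`, `[50,100)`, `[1,50)`, `none`
#' for length 0.
#'
#' @param peptide_aa peptide length(s) in amino acids.
#' @return character class label(s).
#' @export
orf_class <- function(peptide_aa) {
  cut_lab <- function(x) {
    if (x >= 200) ">=200" else if (x >= 100) "100-200"
    else if (x >= 50) "50-100" else if (x >= 1) "<50" else "none"
  }
  vapply(peptide_aa, cut_lab, character(1))
}
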