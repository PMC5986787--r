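#' RPKM normalization of a count matrix
#'
#' `RPKM_{g,s} = 1e9 * C_{g,s} / (N_s * L_g)`: reads per kilobase of
#' transcript per million mapped reads. When `mapped_totals` is not given,
#' the per-sample column totals of the matrix stand in for the mapped-read
#' totals (the standard surrogate when the original mapping is not
#' available).
#'
#' @param counts integer matrix, transcripts x samples, with dimnames.
#' @param lengths named vector of transcript lengths in nt.
#' @param mapped_totals named per-sample read totals; default column sums.
#' @return numeric matrix of RPKM values with the dimnames of `counts`.
#' @export
#' @examples
#' m <- matrix(c(10, 0), 1, 2, dimnames = list("t1", c("a", "b")))
#' rpkm(m, c(t1 = 1000), mapped_totals = c(a = 1e6, b = 1e6))
rpkm <- function(counts, lengths, mapped_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry transcript and sample names")
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for transcripts: ",
         paste(head(setdiff(rownames(counts), names(lengths))), collapse = ", "))
  L <- lengths[rownames(counts)]
  if (any(!is.finite(L) | L <= 0))
    stop("non-positive length for transcript(s): ",
         paste(head(rownames(counts)[!is.finite(L) | L <= 0]), collapse = ", "))
  N <- mapped_totals[colnames(counts)]
  if (any(is.na(N) | N <= 0))
    stop("non-positive mapped total for sample(s): ",
         paste(head(colnames(counts)[is.na(N) | N <= 0]), collapse = ", "))
  sweep(counts / L, 2, N, "/") * 1e9
}

#' Per-stage mean expression
#'
#' Arithmetic mean of (unlogged) per-sample values over each stage's
#' samples.
#'
#' @param expr matrix, transcripts x samples.
#' @param design data.frame with columns `sample` and `stage`.
#' @return matrix, transcripts x stages (stage order of the design).
#' @export
stage_means <- function(expr, design) {
  stopifnot(all(design$sample %in% colnames(expr)))
  stages <- unique(design$stage)
  out <- sapply(stages, function(st) {
    cols <- design$sample[design$stage == st]
    rowMeans(expr[, cols, drop = FALSE])
  })
  colnames(out) <- stages
  out
}

#' Rank candidate reference genes by expression stability
#'
#' Stability is the coefficient of variation (sample standard deviation,
#' n - 1 denominator, divided by the mean) of the per-stage mean RPKM
#' values; candidates are ranked by ascending CV with lexicographic
#' transcript-id tie-break. Low CV identifies transcripts suitable as
#' RT-qPCR internal references.
#'
#' @param expr RPKM matrix, transcripts x samples.
#' @param design data.frame with `sample` and `stage`.
#' @param candidates transcript ids to rank (must be rows of `expr`).
#' @return data.frame (transcript, mean_rpkm, cv) sorted by cv.
#' @export
reference_gene_rank <- function(expr, design, candidates) {
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing))
    stop("candidates absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  sm <- stage_means(expr[candidates, , drop = FALSE], design)
  mu <- rowMeans(sm)
  if (any(mu == 0)) stop("candidate(s) with zero mean expression: ",
                         paste(candidates[mu == 0], collapse = ", "))
  cv <- apply(sm, 1, sd) / mu
  out <- data.frame(transcript = candidates, mean_rpkm = unname(mu),
                    cv = unname(cv), stringsAsFactors = FALSE)
  out <- out[order(out$cv, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assembly summary statistics of a transcript catalog
#'
#' Contig count, mean/min/max length, N25/N50/N75, and the length-class
#' fractions (400-2000, 2000-4000, >4000 nt) conventionally reported for
#' de novo plant transcriptome assemblies.
#'
#' @param lengths numeric vector of contig lengths (nt), or a named list
#'   /character vector of sequences whose `nchar` is used.
#' @return named list of statistics.
#' @export
assembly_stats <- function(lengths) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) > 0, all(lengths > 0))
  sl <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sl)
  nq <- function(q) sl[which(cum >= q * sum(sl))[1]]
  list(n_contigs = length(lengths), mean_length = mean(lengths),
       min_length = min(lengths), max_length = max(lengths),
       n25 = nq(0.25), n50 = nq(0.5), n75 = nq(0.75),
       frac_400_2000 = mean(lengths >= 400 & lengths < 2000),
       frac_2000_4000 = mean(lengths >= 2000 & lengths <= 4000),
       frac_gt_4000 = mean(lengths > 4000))
}
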