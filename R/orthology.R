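# Karlin-Altschul parameters for the two scoring schemes (standard BLAST
# table values for gapped +2/-3 open 5 ext 2, and BLOSUM62 open 11 ext 1)
.KA <- list(nucleotide = c(lambda = 0.625, K = 0.41),
            protein = c(lambda = 0.267, K = 0.041))
.NT_GAP <- c(open = 5L, ext = 2L)
.AA_GAP <- c(open = 11L, ext = 1L)

.nt_submat <- function() {
  s <- matrix(-3L, 4, 4, dimnames = list(.BASES, .BASES))
  diag(s) <- 2L
  s
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

.encode <- function(seq, alphabet) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(ch, alphabet)
  if (anyNA(code))
    stop("invalid character '", ch[which(is.na(code))[1]], "' at position ",
         which(is.na(code))[1])
  code - 1L
}

.revcomp <- function(seq) {
  ch <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "", fixed = TRUE)[[1]])
  paste(ch, collapse = "")
}

.six_frames <- function(seq) {
  n <- nchar(seq)
  rc <- .revcomp(seq)
  frames <- list()
  for (f in 1:3) {
    w <- ((n - f + 1) %/% 3) * 3
    fwd <- if (w >= 3) substr(seq, f, f + w - 1) else ""
    rev <- if (w >= 3) substr(rc, f, f + w - 1) else ""
    frames[[paste0("+", f)]] <- if (nzchar(fwd))
      as.character(Biostrings::translate(Biostrings::DNAString(fwd),
                                         if.fuzzy.codon = "X")) else ""
    frames[[paste0("-", f)]] <- if (nzchar(rev))
      as.character(Biostrings::translate(Biostrings::DNAString(rev),
                                         if.fuzzy.codon = "X")) else ""
  }
  frames
}

#' Raw-to-bit score conversion and E-value
#'
#' `bits = (lambda * S - ln K) / ln 2` with the Karlin-Altschul parameters
#' of the scoring scheme, and `E = m * n * 2^(-bits)` for a query of
#' length `m` against a database of total length `n`.
#'
#' @param bitscore bit score(s).
#' @param m query length; `n` database length (positive).
#' @return expected number of chance hits at this score.
#' @export
#' @examples
#' evalue(40, 1000, 1000)  # ~9.1e-7
evalue <- function(bitscore, m, n) {
  if (any(m <= 0) || any(n <= 0)) stop("lengths must be positive")
  m * n * 2^(-bitscore)
}

#' @rdname evalue
#' @param score raw alignment score.
#' @param mode `"nucleotide"` or `"protein"` scoring scheme.
#' @export
bit_score <- function(score, mode = c("nucleotide", "protein")) {
  ka <- .KA[[match.arg(mode)]]
  unname((ka[["lambda"]] * score - log(ka[["K"]])) / log(2))
}

.hit_from_aln <- function(aln, qlen, dblen, mode, strand = "+", frame = NA) {
  bits <- unname(bit_score(aln$score, mode))
  qspan <- if (aln$length > 0) aln$qend - aln$qstart + 1 else 0
  list(score = aln$score, bits = bits,
       evalue = unname(evalue(bits, qlen, dblen)),
       qstart = if (is.na(aln$qstart)) NA_integer_ else aln$qstart - 1L,
       qend = aln$qend,  # 0-based half-open
       sstart = if (is.na(aln$sstart)) NA_integer_ else aln$sstart - 1L,
       send = aln$send,
       length = aln$length, n_ident = aln$n_ident, gaps = aln$gaps,
       gapopen = aln$gapopen,
       identity = if (aln$length > 0) aln$n_ident / aln$length else 0,
       coverage = qspan / qlen, strand = strand, frame = frame)
}

#' Best local alignment between two sequences
#'
#' Smith-Waterman with affine gaps (a gap of length L costs open + ext*L).
#' Nucleotide mode scores match +2 / mismatch -3 with gap open 5, extend 2
#' and searches both strands of the query; translated mode aligns a
#' protein query against all six frame translations of a nucleotide target
#' with BLOSUM62, gap open 11, extend 1 (tBLASTn-like). The best cell is
#' chosen deterministically (maximum score, ties by smallest end
#' coordinates); spans are reported 0-based half-open on the reported
#' strand/frame.
#'
#' @param query,target sequences (character scalars); in translated mode
#'   the query is a protein.
#' @param mode `"nucleotide"` or `"translated"`.
#' @return object of class `sw_hit`: score, bits, evalue (database = the
#'   single target), qstart/qend/sstart/send, length, n_ident, identity,
#'   coverage (aligned query span / query length), strand, frame.
#' @export
local_align <- function(query, target, mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  if (mode == "nucleotide") {
    S <- .nt_submat()
    qi <- .encode(query, .BASES)
    ti <- .encode(target, .BASES)
    fwd <- .sw_align(qi, ti, S, .NT_GAP["open"], .NT_GAP["ext"])
    rev <- .sw_align(.encode(.revcomp(query), .BASES), ti, S,
                     .NT_GAP["open"], .NT_GAP["ext"])
    best <- if (rev$score > fwd$score)
      .hit_from_aln(rev, nchar(query), nchar(target), "nucleotide", "-")
    else .hit_from_aln(fwd, nchar(query), nchar(target), "nucleotide", "+")
  } else {
    B <- .blosum62()
    alpha <- rownames(B)
    qi <- .encode(query, alpha)
    frames <- .six_frames(target)
    best <- NULL
    for (fr in names(frames)) {
      if (!nzchar(frames[[fr]])) next
      a <- .sw_align(qi, .encode(frames[[fr]], alpha), B,
                     .AA_GAP["open"], .AA_GAP["ext"])
      if (is.null(best) || a$score > best$aln$score)
        best <- list(aln = a, frame = fr)
    }
    if (is.null(best)) stop("target too short to translate")
    best <- .hit_from_aln(best$aln, nchar(query), nchar(target) %/% 3,
                          "protein", frame = best$frame)
  }
  class(best) <- "sw_hit"
  best
}

#' @export
print.sw_hit <- function(x, ...) {
  cat(sprintf("local hit: score %d (%.1f bits), E = %.3g, identity %.1f%%, coverage %.1f%%\n",
              x$score, x$bits, x$evalue, 100 * x$identity, 100 * x$coverage))
  cat(sprintf("  query [%d,%d) x target [%d,%d), strand %s frame %s\n",
              x$qstart, x$qend, x$sstart, x$send, x$strand, x$frame))
  invisible(x)
}

# strand-aware all-vs-all raw score matrix (max over query strands);
# S(rc(a), b) = S(a, rc(b)), so one matrix serves both search directions
.score_matrix <- function(a_seqs, b_seqs, mode) {
  if (mode == "nucleotide") {
    S <- .nt_submat(); go <- .NT_GAP["open"]; ge <- .NT_GAP["ext"]
    ai <- lapply(a_seqs, .encode, alphabet = .BASES)
    ri <- lapply(a_seqs, function(s) .encode(.revcomp(s), .BASES))
    bi <- lapply(b_seqs, .encode, alphabet = .BASES)
    fwd <- .sw_score_matrix(ai, bi, S, go, ge)
    rev <- .sw_score_matrix(ri, bi, S, go, ge)
    list(score = pmax(fwd, rev), strand = ifelse(rev > fwd, "-", "+"))
  } else {
    B <- .blosum62(); alpha <- rownames(B)
    ai <- lapply(a_seqs, .encode, alphabet = alpha)
    best <- matrix(0L, length(a_seqs), length(b_seqs))
    strand <- matrix("+", length(a_seqs), length(b_seqs))
    frames_all <- lapply(b_seqs, .six_frames)
    for (f in 1:6) {
      bi <- lapply(frames_all, function(fr) {
        s <- fr[[f]]
        if (nzchar(s)) .encode(s, alpha) else 0L
      })
      sc <- .sw_score_matrix(bi, ai, B, .AA_GAP["open"], .AA_GAP["ext"])
      sc <- t(sc)
      upd <- sc > best
      best[upd] <- sc[upd]
      strand[upd] <- names(frames_all[[1]])[f]
    }
    list(score = best, strand = strand)
  }
}

# best hit of query i among targets: max score, ties by longer alignment,
# then lexicographic target id
.best_of_row <- function(scores, ids, aln_len) {
  mx <- max(scores)
  if (mx <= 0) return(NA_integer_)
  cand <- which(scores == mx)
  if (length(cand) > 1) {
    len <- aln_len(cand)
    cand <- cand[len == max(len)]
    cand <- cand[order(ids[cand])][1]
  }
  cand
}

#' Call orthologues by best bidirectional hit with filter gates
#'
#' All-vs-all Smith-Waterman search between two sequence catalogs. For
#' each query the best hit is the maximum raw score (ties broken by longer
#' alignment, then lexicographic target id). A pair is `bidirectional`
#' when the two sequences are each other's best hit and both directions
#' pass the gates (query coverage > `min_cov`, E-value < `max_e`, and the
#' query's annotated domain set is a subset of the hit's - queries without
#' domain annotation pass vacuously); a passing best hit without
#' reciprocity is reported `unidirectional`; queries with no passing hit
#' are `unmapped`.
#'
#' @param set_a,set_b named character vectors of sequences (unique ids).
#' @param domains_a,domains_b optional data.frames with columns `gene` and
#'   `domain`.
#' @param min_cov minimum query coverage (fraction, default 0.40,
#'   exclusive).
#' @param max_e maximum E-value (default 1e-10, exclusive).
#' @param mode `"nucleotide"` (both strands) or `"translated"` (set_a are
#'   proteins searched against six-frame translations of set_b).
#' @return data.frame with one row per `set_a` query: query, target,
#'   class, score, bits, evalue, coverage, identity, strand, domain_ok.
#' @export
call_orthologs <- function(set_a, set_b, domains_a = NULL, domains_b = NULL,
                           min_cov = 0.40, max_e = 1e-10,
                           mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  if (anyDuplicated(names(set_a)) || anyDuplicated(names(set_b)))
    stop("duplicated sequence ids")
  if (is.null(names(set_a)) || is.null(names(set_b)))
    stop("sequences must be named")
  sm <- .score_matrix(set_a, set_b, mode)
  M <- sm$score
  ka_mode <- if (mode == "nucleotide") "nucleotide" else "protein"
  db_b <- sum(nchar(set_b)); db_a <- sum(nchar(set_a))
  if (mode == "translated") db_b <- db_b %/% 3

  dom <- function(tab) {
    if (is.null(tab)) return(list())
    split(as.character(tab$domain), as.character(tab$gene))
  }
  dom_a <- dom(domains_a); dom_b <- dom(domains_b)

  aln_cache <- new.env()
  get_aln <- function(i, j) {  # full alignment of a_i vs b_j on best strand
    key <- paste(i, j)
    if (!is.null(aln_cache[[key]])) return(aln_cache[[key]])
    a <- set_a[[i]]; b <- set_b[[j]]
    h <- if (mode == "nucleotide") {
      q <- if (sm$strand[i, j] == "-") .revcomp(a) else a
      aln <- .sw_align(.encode(q, .BASES), .encode(b, .BASES), .nt_submat(),
                       .NT_GAP["open"], .NT_GAP["ext"])
      .hit_from_aln(aln, nchar(a), db_b, "nucleotide", sm$strand[i, j])
    } else {
      B <- .blosum62()
      fr <- .six_frames(b)[[sm$strand[i, j]]]
      aln <- .sw_align(.encode(a, rownames(B)), .encode(fr, rownames(B)), B,
                       .AA_GAP["open"], .AA_GAP["ext"])
      .hit_from_aln(aln, nchar(a), db_b, "protein", frame = sm$strand[i, j])
    }
    aln_cache[[key]] <- h
    h
  }

  best_a <- vapply(seq_along(set_a), function(i)
    .best_of_row(M[i, ], names(set_b),
                 function(cand) vapply(cand, function(j) get_aln(i, j)$length,
                                       numeric(1))), integer(1))
  best_b <- vapply(seq_along(set_b), function(j)
    .best_of_row(M[, j], names(set_a),
                 function(cand) vapply(cand, function(i) get_aln(i, j)$length,
                                       numeric(1))), integer(1))

  passes <- function(h, qid, tid, dq) {
    if (h$coverage <= min_cov || h$evalue >= max_e) return(FALSE)
    qd <- dq[[qid]]
    is.null(qd) || all(qd %in% dom_b[[tid]]) || length(qd) == 0
  }

  rows <- lapply(seq_along(set_a), function(i) {
    j <- best_a[i]
    qid <- names(set_a)[i]
    base <- data.frame(query = qid, target = NA_character_,
                       class = "unmapped", score = NA_real_, bits = NA_real_,
                       evalue = NA_real_, coverage = NA_real_,
                       identity = NA_real_, strand = NA_character_,
                       domain_ok = NA, stringsAsFactors = FALSE)
    if (is.na(j)) return(base)
    h <- get_aln(i, j)
    tid <- names(set_b)[j]
    qd <- dom_a[[qid]]
    dom_ok <- is.null(qd) || length(qd) == 0 || all(qd %in% dom_b[[tid]])
    fwd_pass <- h$coverage > min_cov && h$evalue < max_e && dom_ok
    if (!fwd_pass) return(base)
    # reciprocal direction: same raw score, b_j as query against db A
    recip <- !is.na(best_b[j]) && best_b[j] == i
    if (recip) {
      cov_b <- if (mode == "nucleotide") {
        (h$send - h$sstart) / nchar(set_b[[j]])
      } else {
        3 * (h$send - h$sstart) / nchar(set_b[[j]])
      }
      bits_b <- unname(bit_score(h$score, ka_mode))
      e_b <- unname(evalue(bits_b, if (mode == "nucleotide") nchar(set_b[[j]])
                           else nchar(set_b[[j]]) %/% 3, db_a))
      bd <- dom_b[[tid]]
      dom_ok_b <- is.null(bd) || length(bd) == 0 || all(bd %in% dom_a[[qid]])
      recip <- cov_b > min_cov && e_b < max_e && dom_ok_b
    }
    data.frame(query = qid, target = tid,
               class = if (recip) "bidirectional" else "unidirectional",
               score = h$score, bits = h$bits, evalue = h$evalue,
               coverage = h$coverage, identity = h$identity,
               strand = as.character(h$strand), domain_ok = dom_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
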