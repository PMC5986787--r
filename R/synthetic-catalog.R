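.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

random_seq <- function(len) paste(sample(.BASES, len, replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

# all 61 sense codons
.sense_codons <- function() {
  all3 <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
  setdiff(all3, .STOPS)
}

# Overwrite seq with ATG + n_codons sense codons + a stop, at an in-frame
# (frame +1) position. Returns the sequence and the 0-based half-open span.
plant_orf <- function(seq, n_codons) {
  orf <- paste0("ATG", paste(sample(.sense_codons(), n_codons - 1, replace = TRUE),
                             collapse = ""), sample(.STOPS, 1))
  nt <- nchar(orf)
  len <- nchar(seq)
  if (nt > len) stop("sequence too short for planted ORF")
  max_start <- (len - nt) %/% 3
  at <- 3 * sample.int(max_start + 1, 1) - 3  # 0-based, multiple of 3
  list(seq = paste0(substr(seq, 1, at), orf, substr(seq, at + nt + 1, len)),
       start = at, end = at + nt)
}

#' Simulate a transcript catalog with planted orthologues, ORFs and GO terms
#'
#' Generates a query catalog of `n_transcripts` random ACGT sequences and a
#' reference catalog in which the first `n_orthologues` queries appear as
#' copies mutated by point substitution at `mutation_rate`. A
#' `paralog_fraction` of those orthologues also receive a second,
#' near-identical reference copy (0.005 substitutions/base) emulating the
#' allelic variants of a tetraploid, and `n_decoys` unrelated reference
#' sequences are appended. An `orf_fraction` of queries carry a planted
#' in-frame ORF of known codon count. The GO table assigns background terms
#' at random and plants one enriched term on the same DE transcript set that
#' [simulate_counts()] uses.
#'
#' @param params a [sim_params()] object.
#' @return list with `query` and `reference` (named character vectors of
#'   sequences), `domains` (data.frame gene/domain covering both catalogs),
#'   `go` (data.frame transcript/term over the query catalog) and `truth`
#'   (list: `orthologue_map` named query->reference ids, `paralogues`,
#'   `orf_table` data.frame transcript/peptide_aa/start/end,
#'   `enriched_term`, `de_transcripts`).
#' @export
simulate_catalog <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  de_ids <- planted_de_ids(params)
  set.seed(.stream_seed(params, "catalog"))
  n <- params$n_transcripts
  ids <- transcript_ids(n)
  lens <- round(runif(n, params$length_range[1], params$length_range[2]))
  query <- vapply(lens, random_seq, character(1))
  names(query) <- ids

  # planted ORFs: peptide lengths from a mixture matching the long/medium/
  # short proportions seen in de novo root transcriptomes (~6/28/66%)
  n_orf <- round(params$orf_fraction * n)
  orf_tab <- data.frame(transcript = character(0), peptide_aa = integer(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  if (n_orf > 0) {
    orf_ids <- sort(sample(ids, n_orf))
    for (id in orf_ids) {
      cls <- sample(c("long", "mid", "short"), 1, prob = c(0.06, 0.28, 0.66))
      pep <- switch(cls,
                    long = sample(200:280, 1),
                    mid = sample(100:199, 1),
                    short = sample(50:99, 1))
      max_pep <- (nchar(query[[id]]) %/% 3) - 1
      pep <- min(pep, max_pep)
      pl <- plant_orf(query[[id]], pep)
      query[[id]] <- pl$seq
      orf_tab <- rbind(orf_tab, data.frame(
        transcript = id, peptide_aa = pep, start = pl$start, end = pl$end,
        stringsAsFactors = FALSE))
    }
  }

  # orthologues + paralogue near-copies + decoys
  orth_q <- ids[seq_len(params$n_orthologues)]
  ref <- character(0)
  omap <- character(0)
  for (i in seq_along(orth_q)) {
    rid <- sprintf("r%05d", i)
    ref[rid] <- mutate_seq(query[[orth_q[i]]], params$mutation_rate)
    omap[orth_q[i]] <- rid
  }
  n_par <- round(params$paralog_fraction * length(orth_q))
  par_of <- character(0)
  if (n_par > 0) {
    par_src <- sample(orth_q, n_par)
    for (i in seq_along(par_src)) {
      rid <- sprintf("p%05d", i)
      ref[rid] <- mutate_seq(query[[par_src[i]]],
                             max(params$mutation_rate * 2, 0.005))
      par_of[rid] <- par_src[i]
    }
  }
  if (params$n_decoys > 0) {
    dl <- round(runif(params$n_decoys, params$length_range[1],
                      params$length_range[2]))
    dec <- vapply(dl, random_seq, character(1))
    names(dec) <- sprintf("d%05d", seq_len(params$n_decoys))
    ref <- c(ref, dec)
  }

  # domains: orthologous pairs share a domain set; decoys get their own
  domains <- data.frame(gene = character(0), domain = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_along(orth_q)) {
    dset <- sprintf("SF%04d", sample.int(500, sample(1:3, 1)))
    domains <- rbind(domains,
                     data.frame(gene = orth_q[i], domain = dset,
                                stringsAsFactors = FALSE),
                     data.frame(gene = omap[[orth_q[i]]], domain = dset,
                                stringsAsFactors = FALSE))
  }

  # GO table: ~2 background terms per transcript, one planted enriched term
  bg_terms <- sprintf("GO:%07d", 1000 + seq_len(19))
  enriched <- "GO:0000042"
  go <- data.frame(transcript = character(0), term = character(0),
                   stringsAsFactors = FALSE)
  n_bg <- rpois(n, 2)
  keep <- n_bg > 0
  if (any(keep)) {
    go <- data.frame(
      transcript = rep(ids[keep], n_bg[keep]),
      term = unlist(lapply(n_bg[keep], function(k) sample(bg_terms, k))),
      stringsAsFactors = FALSE)
  }
  in_de <- ids %in% de_ids
  gets <- runif(n) < ifelse(in_de, 0.4, 0.02)
  if (any(gets))
    go <- rbind(go, data.frame(transcript = ids[gets], term = enriched,
                               stringsAsFactors = FALSE))
  go <- go[order(go$transcript, go$term), , drop = FALSE]
  rownames(go) <- NULL

  list(query = query, reference = ref, domains = domains, go = go,
       truth = list(orthologue_map = omap, paralogues = par_of,
                    orf_table = orf_tab, enriched_term = enriched,
                    de_transcripts = de_ids))
}

#' Simulate a toy directed regulatory map with seeds, neighbours and decoys
#'
#' Builds an edge list in which every neighbour node is connected to a
#' randomly chosen seed (random edge direction), a few neighbour-neighbour
#' edges are added, and `extra_nodes` decoy nodes form edges only among
#' themselves, so they must not survive seed-plus-first-neighbour
#' extraction.
#'
#' @param n_seeds,n_neighbours,extra_nodes node counts (>= 0; at least one
#'   seed).
#' @param seed RNG seed.
#' @return list with `map` (data.frame regulator/target/effect) and `seeds`
#'   (character vector).
#' @export
simulate_regmap <- function(n_seeds, n_neighbours, extra_nodes, seed = 1L) {
  stopifnot(n_seeds >= 1, n_neighbours >= 0, extra_nodes >= 0)
  set.seed(seed)
  seeds <- sprintf("S%03d", seq_len(n_seeds))
  nb <- if (n_neighbours) sprintf("N%03d", seq_len(n_neighbours)) else character(0)
  xx <- if (extra_nodes) sprintf("X%03d", seq_len(extra_nodes)) else character(0)
  eff <- function(k) sample(c("activation", "repression"), k, replace = TRUE)
  edges <- data.frame(regulator = character(0), target = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  for (v in nb) {
    s <- sample(seeds, 1)
    e <- if (runif(1) < 0.5) c(s, v) else c(v, s)
    edges <- rbind(edges, data.frame(regulator = e[1], target = e[2],
                                     effect = eff(1), stringsAsFactors = FALSE))
  }
  if (length(nb) >= 2) {
    k <- min(length(nb) %/% 2, 3L)
    for (i in seq_len(k)) {
      uv <- sample(nb, 2)
      edges <- rbind(edges, data.frame(regulator = uv[1], target = uv[2],
                                       effect = eff(1), stringsAsFactors = FALSE))
    }
  }
  if (length(seeds) >= 2)
    edges <- rbind(edges, data.frame(regulator = seeds[1], target = seeds[2],
                                     effect = eff(1), stringsAsFactors = FALSE))
  if (length(xx) >= 2) {
    for (i in seq_len(length(xx) - 1))
      edges <- rbind(edges, data.frame(regulator = xx[i], target = xx[i + 1],
                                       effect = eff(1), stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  list(map = edges, seeds = seeds)
}
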