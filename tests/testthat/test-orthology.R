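test_that("local alignment matches closed forms and strand symmetry", {
  set.seed(1)
  a <- random_dna(100)
  h <- local_align(a, a)
  expect_equal(h$score, 200)       # 100 matches at +2
  expect_equal(h$coverage, 1)
  expect_equal(h$identity, 1)
  expect_identical(c(h$qstart, h$qend), c(0L, 100L))
  # reverse-complement query hits on the minus strand with the same score
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(a, "")[[1]]), collapse = ""))
  hr <- local_align(rc, a)
  expect_equal(hr$score, 200)
  expect_identical(hr$strand, "-")
  expect_error(local_align("", a), "empty")
  expect_error(local_align("ACGU", a), "invalid character")
})

test_that("alignment scores equal a plain dynamic-programming reference", {
  set.seed(2)
  S <- oracle_nt_matrix()
  for (i in 1:20) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    mine <- rootapex:::.sw_score(rootapex:::.encode(a, c("A", "C", "G", "T")),
                                 rootapex:::.encode(b, c("A", "C", "G", "T")),
                                 rootapex:::.nt_submat(), 5L, 2L)
    expect_equal(mine, oracle_sw_score(a, b, S, 5, 2))
  }
})

test_that("alignment scores agree with an independent aligner", {
  set.seed(3)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  mat <- mat[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  for (i in 1:10) {
    a <- random_dna(300)
    b <- if (i %% 2) random_dna(300) else
      paste0(substr(a, 50, 250), random_dna(80))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
    mine <- rootapex:::.sw_score(rootapex:::.encode(a, c("A", "C", "G", "T")),
                                 rootapex:::.encode(b, c("A", "C", "G", "T")),
                                 rootapex:::.nt_submat(), 5L, 2L)
    expect_equal(mine, ref)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(evalue(40, 1000, 1000), 1e6 * 2^-40)
  expect_equal(evalue(40, 1000, 1000), 9.09e-7, tolerance = 1e-2)
  # linear in database length; vanishing at infinite score
  expect_equal(evalue(30, 500, 2000) / evalue(30, 500, 1000), 2)
  expect_equal(evalue(Inf, 1e6, 1e9), 0)
  expect_error(evalue(10, -5, 100), "positive")
  # bit-score conversion is affine in the raw score
  b1 <- bit_score(100, "nucleotide")
  b2 <- bit_score(200, "nucleotide")
  expect_equal(b2 - b1, 0.625 * 100 / log(2))
})

test_that("translated mode finds a planted protein in all six frames", {
  set.seed(4)
  pep <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ"
  codons <- c(M = "ATG", K = "AAA", T = "ACT", A = "GCT", Y = "TAT",
              I = "ATT", Q = "CAA", R = "CGT", S = "TCT", F = "TTT",
              V = "GTT", H = "CAT", L = "CTT", E = "GAA", G = "GGT",
              P = "CCT", D = "GAT", N = "AAT", W = "TGG", C = "TGT")
  nt <- paste(codons[strsplit(pep, "")[[1]]], collapse = "")
  target_fwd <- paste0(random_dna(30), nt, random_dna(31))
  h <- local_align(pep, target_fwd, mode = "translated")
  expect_gte(h$identity, 0.99)
  expect_true(startsWith(h$frame, "+"))
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(target_fwd, "")[[1]]), collapse = ""))
  h2 <- local_align(pep, rc, mode = "translated")
  expect_equal(h2$score, h$score)
  expect_true(startsWith(h2$frame, "-"))
})

test_that("identical catalogs map onto themselves bidirectionally", {
  set.seed(5)
  a <- stats::setNames(vapply(rep(300, 6), random_dna, character(1)),
                       sprintf("a%02d", 1:6))
  b <- stats::setNames(a, sprintf("b%02d", 1:6))
  oc <- call_orthologs(a, b)
  expect_true(all(oc$class == "bidirectional"))
  expect_identical(oc$target, sprintf("b%02d", 1:6))
  expect_true(all(oc$identity == 1))
  expect_error(call_orthologs(c(a, a), b), "duplicated")
})

test_that("planted orthologues are recovered exactly with decoys and paralogues", {
  p <- sim_params(n_transcripts = 15, n_orthologues = 12, n_decoys = 4,
                  mutation_rate = 0.02, length_range = c(400, 900), seed = 6)
  cs <- simulate_catalog(p)
  oc <- call_orthologs(cs$query, cs$reference,
                       domains_a = cs$domains, domains_b = cs$domains)
  truth <- cs$truth$orthologue_map
  got <- stats::setNames(oc$target, oc$query)[names(truth)]
  expect_identical(unname(got), unname(truth))
  # queries without planted orthologue must not map to a planted copy of
  # someone else with bidirectional support
  rest <- oc[!(oc$query %in% names(truth)), ]
  expect_false(any(rest$class == "bidirectional"))
})

test_that("best-hit tables equal a brute-force all-vs-all oracle", {
  p <- sim_params(n_transcripts = 8, n_orthologues = 6, n_decoys = 3,
                  mutation_rate = 0.03, length_range = c(300, 500), seed = 7)
  cs <- simulate_catalog(p)
  oc <- call_orthologs(cs$query, cs$reference)
  # oracle: independent per-pair scoring through Biostrings on both strands
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  mat <- mat[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  sc <- function(x, y) max(
    Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                  Biostrings::DNAString(y), type = "local",
                                  substitutionMatrix = mat, gapOpening = 5,
                                  gapExtension = 2, scoreOnly = TRUE),
    Biostrings::pairwiseAlignment(Biostrings::DNAString(revcomp(x)),
                                  Biostrings::DNAString(y), type = "local",
                                  substitutionMatrix = mat, gapOpening = 5,
                                  gapExtension = 2, scoreOnly = TRUE))
  M <- outer(seq_along(cs$query), seq_along(cs$reference),
             Vectorize(function(i, j) sc(cs$query[[i]], cs$reference[[j]])))
  best_ref <- names(cs$reference)[apply(M, 1, which.max)]
  hit <- !is.na(oc$target)
  expect_identical(oc$target[hit], best_ref[hit])
  # and the reported raw scores agree
  expect_identical(oc$score[hit],
                   M[cbind(which(hit), match(oc$target[hit],
                                             names(cs$reference)))])
})

test_that("BBH classification is symmetric and monotone in thresholds", {
  p <- sim_params(n_transcripts = 10, n_orthologues = 8, n_decoys = 2,
                  mutation_rate = 0.02, length_range = c(300, 600), seed = 8)
  cs <- simulate_catalog(p)
  ab <- call_orthologs(cs$query, cs$reference)
  ba <- call_orthologs(cs$reference, cs$query)
  keys_ab <- with(ab[ab$class == "bidirectional", ], paste(query, target))
  keys_ba <- with(ba[ba$class == "bidirectional", ], paste(target, query))
  expect_setequal(keys_ab, keys_ba)
  expect_gt(length(keys_ab), 0)
  # relaxing the E threshold never removes reported pairs
  strict <- call_orthologs(cs$query, cs$reference, max_e = 1e-30)
  loose <- call_orthologs(cs$query, cs$reference, max_e = 1e-5)
  kept <- strict$query[strict$class != "unmapped"]
  expect_true(all(kept %in% loose$query[loose$class != "unmapped"]))
})

test_that("the domain gate rejects queries with unmatched domains", {
  set.seed(9)
  a <- stats::setNames(vapply(rep(400, 3), random_dna, character(1)),
                       c("qa", "qb", "qc"))
  b <- stats::setNames(a, c("ra", "rb", "rc"))
  dom_a <- data.frame(gene = c("qa", "qb"), domain = c("SF1", "SF9"))
  dom_b <- data.frame(gene = c("ra", "rb"), domain = c("SF1", "SF2"))
  oc <- call_orthologs(a, b, domains_a = dom_a, domains_b = dom_b)
  expect_identical(oc$class[oc$query == "qa"], "bidirectional")  # SF1 present
  expect_identical(oc$class[oc$query == "qb"], "unmapped")       # SF9 absent
  expect_identical(oc$class[oc$query == "qc"], "bidirectional")  # vacuous
})

test_that("tabular hit files round-trip with 1-based inclusive coordinates", {
  set.seed(10)
  a <- random_dna(200)
  h <- local_align(a, paste0(random_dna(40), substr(a, 21, 180), random_dna(40)))
  hits <- data.frame(query = "q1", target = "t1", identity = h$identity,
                     length = h$length, n_ident = h$n_ident, gaps = h$gaps,
                     gapopen = h$gapopen, qstart = h$qstart, qend = h$qend,
                     sstart = h$sstart, send = h$send, evalue = h$evalue,
                     bits = h$bits)
  f <- tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- read_hits(f)
  expect_equal(back$qstart, h$qstart + 1)   # file is 1-based inclusive
  expect_equal(back$qend, h$qend)
  expect_equal(back$qstart0, h$qstart)      # converted back internally
  expect_equal(back$bitscore, round(h$bits, 1))
})
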