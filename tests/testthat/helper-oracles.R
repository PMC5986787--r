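# Independent reference computations used to check the package's
# implementations. Each oracle takes the most direct route available
# (closed form, full enumeration, plain dynamic programming) and shares
# no code with the implementation under test.

# conditional exact p via the negative-hypergeometric split weights
# (binomial closed form when phi = 0)
oracle_exact_p <- function(sa, na, sb, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  k <- 0:t
  if (phi == 0) {
    lw <- dbinom(k, t, na / (na + nb), log = TRUE)
  } else {
    r1 <- na / phi
    r2 <- nb / phi
    lw <- lgamma(k + r1) - lgamma(k + 1) - lgamma(r1) +
      lgamma(t - k + r2) - lgamma(t - k + 1) - lgamma(r2)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sum(w[w <= w[sa + 1] * (1 + 1e-12)])
}

# hypergeometric upper tail by direct pmf summation
oracle_hyper_p <- function(N, M, n, k) {
  i <- k:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# plain-R affine-gap Smith-Waterman best score (gap length L costs
# open + ext * L); S is a character-indexed substitution matrix
oracle_sw_score <- function(a, b, S, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]], E[i, j], F[i, j])
    }
  }
  max(H)
}

oracle_nt_matrix <- function() {
  b <- c("A", "C", "G", "T")
  S <- matrix(-3, 4, 4, dimnames = list(b, b))
  diag(S) <- 2
  S
}

# brute-force longest ORF: enumerate every ATG in all six frames and walk
# codons to the first in-frame stop
oracle_longest_orf <- function(seq) {
  revcomp <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                               collapse = "")
  best <- 0
  for (s in c(seq, revcomp(seq))) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    for (start in seq_len(max(0, n - 5))) {
      if (!(ch[start] == "A" && ch[start + 1] == "T" && ch[start + 2] == "G"))
        next
      pos <- start + 3
      pep <- 1
      while (pos + 2 <= n) {
        cod <- paste(ch[pos:(pos + 2)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (pep > best) best <- pep
          break
        }
        pep <- pep + 1
        pos <- pos + 3
      }
    }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# adjusted Rand index (Hubert & Arabie) from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
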