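# a small expression matrix with three stage groups whose between-stage
# shift dwarfs the replicate noise
planted_stage_expr <- function(n_transcripts = 300, noise_sd = 0.1,
                               shift_sd = 2, seed = 1) {
  set.seed(seed)
  stages <- c("initial", "intermediate", "terminal")
  mu <- matrix(rnorm(n_transcripts * 3, sd = shift_sd), n_transcripts, 3,
               dimnames = list(sprintf("t%04d", 1:n_transcripts), stages))
  x <- mu[, rep(1:3, each = 2)] +
    matrix(rnorm(n_transcripts * 6, sd = noise_sd), n_transcripts, 6)
  colnames(x) <- paste0(rep(stages, each = 2), "_r", 1:2)
  2^x  # return on the raw scale; pca_samples logs it again
}

test_that("sample PCA satisfies its spectral identities", {
  x <- planted_stage_expr(seed = 2)
  pc <- pca_samples(x)
  expect_equal(sum(pc$var_fraction), 1)
  # reconstruction with all components reproduces the standardized matrix
  z <- pc$scores %*% t(pc$rotation)
  lx <- log2(x + 1)
  lx <- lx[apply(lx, 1, sd) > 0, ]
  zs <- t((lx - rowMeans(lx)) / apply(lx, 1, sd))
  expect_lt(max(abs(z - zs)), 1e-8)
  # duplicate samples coincide on all components
  xx <- cbind(x, dup = x[, 1])
  pc2 <- pca_samples(xx)
  expect_lt(max(abs(pc2$scores["dup", ] - pc2$scores[1, ])), 1e-8)
  expect_error(pca_samples(x[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA recovers planted stage structure", {
  x <- planted_stage_expr(seed = 3)
  pc <- pca_samples(x)
  expect_gte(sum(pc$var_fraction[1:2]), 0.9)
  # replicates are mutual nearest neighbours in PC1-PC2
  d <- as.matrix(dist(pc$scores[, 1:2]))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_identical(unname(nn[colnames(x)]),
                   c(2L, 1L, 4L, 3L, 6L, 5L))
})

test_that("cross-species co-projection aligns matched stages", {
  xa <- planted_stage_expr(seed = 4)
  # species B: same planted stage signal, permuted transcript ids, a
  # species-specific scale and shift removed by per-species standardization
  perm <- sample(rownames(xa))
  xb <- 4 * xa[perm, ] + 100
  rownames(xb) <- paste0("b_", perm)
  colnames(xb) <- paste0("B_", colnames(xa))
  pairs <- data.frame(query = perm, target = paste0("b_", perm))
  cp <- pca_coproject(xa, xb, pairs)
  expect_identical(cp$group, rep(c("a", "b"), each = 6))
  sc <- cp$scores[, 1:2]
  stage_of <- rep(rep(c("initial", "intermediate", "terminal"), each = 2), 2)
  cross <- function(scores) {
    d <- as.matrix(dist(scores))
    same <- d[1:6, 7:12][outer(stage_of[1:6], stage_of[7:12], "==")]
    diff <- d[1:6, 7:12][outer(stage_of[1:6], stage_of[7:12], "!=")]
    mean(same) / mean(diff)
  }
  expect_lt(cross(sc), 0.5)  # matched stages much closer than mismatched
  # shuffling the orthologue pairing destroys cross-species clustering
  set.seed(1)
  pairs_shuf <- data.frame(query = pairs$query,
                           target = sample(pairs$target))
  cps <- pca_coproject(xa, xb, pairs_shuf)
  expect_gt(cross(cps$scores[, 1:2]), cross(sc))
  expect_error(pca_coproject(xa, xb, pairs[1:10, ]), "orthologue pairs")
})

test_that("exact species copy co-projects onto identical coordinates", {
  xa <- planted_stage_expr(seed = 5)
  xb <- xa
  rownames(xb) <- paste0("b_", rownames(xa))
  colnames(xb) <- paste0("B_", colnames(xa))
  pairs <- data.frame(query = rownames(xa), target = rownames(xb))
  cp <- pca_coproject(xa, xb, pairs)
  expect_lt(max(abs(cp$scores[1:6, ] - cp$scores[7:12, ])), 1e-8)
})

test_that("k-means clustering descends and recovers planted archetypes", {
  set.seed(7)
  arch <- rbind(up_terminal = c(-1, -1, 1),
                down_terminal = c(1, 1, -1),
                peak_intermediate = c(-1, 1, -1))
  truth <- rep(1:3, each = 60)
  X <- arch[truth, ] + matrix(rnorm(540, sd = 0.1), 180, 3)
  rownames(X) <- sprintf("g%03d", 1:180)
  colnames(X) <- c("initial", "intermediate", "terminal")
  cl <- kmeans_profiles(X, 3, seed = 5)
  expect_gte(oracle_ari(cl$cluster, truth), 0.9)
  # deterministic given seed
  cl2 <- kmeans_profiles(X, 3, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)
  # k = n: singleton clusters at zero cost
  sml <- X[1:5, ]
  cl5 <- kmeans_profiles(sml, 5, seed = 1)
  expect_equal(cl5$tot_withinss, 0)
  expect_identical(sort(unname(cl5$cluster)), 1:5)
  # monotone descent: converged objective no worse than one Lloyd step
  z <- (X - rowMeans(X)) / apply(X, 1, sd)
  set.seed(5)
  init <- rootapex:::.kmeanspp_init(z, 3)
  one <- suppressWarnings(kmeans(z, init, iter.max = 1, algorithm = "Lloyd"))
  expect_lte(cl$tot_withinss, one$tot.withinss + 1e-9)
  expect_error(kmeans_profiles(X, 200, seed = 1), "k must")
})

test_that("hypergeometric enrichment equals direct tail summation", {
  # worked case: N=10, M=5, n=3, k=3 -> C(5,3)/C(10,3) = 10/120
  go <- data.frame(transcript = letters[1:5], term = "T1")
  e <- go_enrichment(letters[1:3], letters[1:10], go)
  expect_equal(e$pvalue, 10 / 120)
  expect_equal(e$pvalue, oracle_hyper_p(10, 5, 3, 3))
  # random configurations against the pmf-summation oracle
  set.seed(11)
  for (i in 1:20) {
    N <- sample(20:60, 1)
    M <- sample(3:(N - 5), 1)
    n <- sample(3:15, 1)
    uni <- sprintf("u%03d", 1:N)
    members <- sample(uni, M)
    det <- sample(uni, n)
    k <- sum(det %in% members)
    if (k == 0) next
    res <- go_enrichment(det, uni, data.frame(transcript = members,
                                              term = "TX"))
    expect_equal(res$pvalue, oracle_hyper_p(N, M, n, k), tolerance = 1e-12)
  }
})

test_that("enrichment skips zero-overlap terms and ignores relabeling", {
  go <- data.frame(transcript = c("a", "b", "x", "y"),
                   term = c("T1", "T1", "T2", "T2"))
  e <- go_enrichment(c("a", "b"), c("a", "b", "x", "y", "z"), go)
  expect_identical(e$term, "T1")
  # universe relabeling leaves p unchanged
  ids <- sprintf("g%02d", 1:20)
  go2 <- data.frame(transcript = ids[1:8], term = "T")
  p1 <- go_enrichment(ids[1:5], ids, go2)$pvalue
  relab <- stats::setNames(sprintf("h%02d", 20:1), ids)
  go3 <- data.frame(transcript = relab[ids[1:8]], term = "T")
  p2 <- go_enrichment(unname(relab[ids[1:5]]), unname(relab[ids]), go3)$pvalue
  expect_equal(p1, p2)
  expect_error(go_enrichment("q", character(0), go), "universe")
  expect_error(go_enrichment("zz", c("a", "b"), go), "subset")
})
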