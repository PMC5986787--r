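.standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  (x - mu) / s
}

#' Sample-level principal component analysis
#'
#' The correlation-matrix convention: each transcript is standardized to
#' mean 0 and unit variance across samples (after an optional
#' `log2(x + 1)` transform, the default, for variance stabilization), and
#' the samples are decomposed by SVD. Zero-variance and low-expression
#' transcripts are removed first.
#'
#' @param expr expression matrix (RPKM), transcripts x samples.
#' @param transform `"log2"` (default, log2(x+1)) or `"raw"`.
#' @param min_expression keep transcripts whose maximum value across
#'   samples is at least this (on the raw scale); default 0.
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `var_fraction`, `sdev`, `n_transcripts`, and `group` (NULL here;
#'   filled by [pca_coproject()]).
#' @export
pca_samples <- function(expr, transform = c("log2", "raw"), min_expression = 0) {
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  expr <- expr[apply(expr, 1, max) >= min_expression, , drop = FALSE]
  x <- if (transform == "log2") log2(expr + 1) else expr
  x <- x[apply(x, 1, sd) > 0, , drop = FALSE]
  if (nrow(x) == 0) stop("no transcript with nonzero variance")
  z <- .standardize_rows(x)
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, var_fraction = vf, sdev = pc$sdev,
                 rotation = pc$rotation, n_transcripts = nrow(z),
                 group = NULL), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$var_fraction))
  cat(sprintf("PCA of %d samples on %d transcripts; PC1..%d explain %s\n",
              nrow(x$scores), x$n_transcripts, k,
              paste(sprintf("%.1f%%", 100 * x$var_fraction[1:k]), collapse = ", ")))
  invisible(x)
}

#' Co-project two species' samples into one principal-component space
#'
#' Restricts both expression matrices to one-to-one orthologous transcript
#' pairs, standardizes each transcript within each species separately
#' (removing species-level location and scale), concatenates the samples
#' and runs [pca_samples()] machinery on the joint matrix. Sample
#' provenance is kept in `group`.
#'
#' @param expr_a,expr_b expression matrices of the two species.
#' @param pairs data.frame with columns `query` (rows of `expr_a`) and
#'   `target` (rows of `expr_b`); must contain at least `min_pairs`
#'   one-to-one pairs present in both matrices.
#' @param transform as in [pca_samples()].
#' @param min_pairs minimum usable orthologue pairs (default 50).
#' @return `pca_result` with `group` labelling each sample "a" or "b".
#' @export
pca_coproject <- function(expr_a, expr_b, pairs, transform = c("log2", "raw"),
                          min_pairs = 50) {
  transform <- match.arg(transform)
  pairs <- pairs[pairs$query %in% rownames(expr_a) &
                 pairs$target %in% rownames(expr_b), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$query) & !duplicated(pairs$target), , drop = FALSE]
  if (nrow(pairs) < min_pairs)
    stop("under-determined co-projection: only ", nrow(pairs),
         " one-to-one orthologue pairs shared (need ", min_pairs, ")")
  a <- as.matrix(expr_a)[pairs$query, , drop = FALSE]
  b <- as.matrix(expr_b)[pairs$target, , drop = FALSE]
  if (transform == "log2") { a <- log2(a + 1); b <- log2(b + 1) }
  ok <- apply(a, 1, sd) > 0 & apply(b, 1, sd) > 0
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  z <- cbind(.standardize_rows(a), .standardize_rows(b))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, var_fraction = vf, sdev = pc$sdev,
                 rotation = pc$rotation, n_transcripts = nrow(z),
                 group = rep(c("a", "b"), c(ncol(a), ncol(b)))),
            class = "pca_result")
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, each
# further centre with probability proportional to squared distance to the
# nearest chosen centre
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centres[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centres[i + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centres[i + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centres, , drop = FALSE]
}

#' Cluster expression profiles by k-means
#'
#' Profiles (per-stage mean expression of each transcript) are z-scored
#' per transcript across stages ("normalized and centered"), seeded with
#' k-means++ from the given RNG seed, and refined by Lloyd iterations to a
#' fixed point (at most 300). Constant profiles cannot be z-scored and are
#' an error.
#'
#' @param profiles matrix, transcripts x stages (per-stage means).
#' @param k number of clusters, `1 <= k <= nrow(profiles)`.
#' @param seed RNG seed for the initialization.
#' @param scale z-score rows first (default TRUE).
#' @return list: `cluster` (named assignment), `centers`, `withinss`,
#'   `tot_withinss`, `k`.
#' @export
kmeans_profiles <- function(profiles, k, seed = 1L, scale = TRUE) {
  x <- as.matrix(profiles)
  if (k < 1 || k > nrow(x)) stop("k must lie in [1, number of profiles]")
  if (scale) {
    s <- apply(x, 1, sd)
    if (any(s == 0)) stop("constant profile(s) cannot be z-scored: ",
                          paste(head(rownames(x)[s == 0]), collapse = ", "))
    x <- .standardize_rows(x)
  }
  if (k == nrow(x)) {
    cl <- seq_len(nrow(x)); names(cl) <- rownames(x)
    return(list(cluster = cl, centers = x, withinss = rep(0, k),
                tot_withinss = 0, k = k))
  }
  set.seed(seed)
  init <- unique(.kmeanspp_init(x, k))
  while (nrow(init) < k) {  # duplicate rows chosen: pad with jittered copies
    init <- unique(rbind(init, init[1, ] + rnorm(ncol(x), sd = 1e-6)))
  }
  km <- kmeans(x, centers = init, iter.max = 300, algorithm = "Lloyd")
  list(cluster = stats::setNames(km$cluster, rownames(x)), centers = km$centers,
       withinss = km$withinss, tot_withinss = km$tot.withinss, k = k)
}

#' Hypergeometric GO over-representation test
#'
#' For each term annotated to at least one member of the test set, the
#' upper-tail hypergeometric probability of drawing `k` or more annotated
#' transcripts when sampling `n = |det_ids|` from a universe of `N` with
#' `M` term members: `p = sum_{i >= k} C(M,i) C(N-M, n-i) / C(N,n)`.
#' BH adjustment is applied across the tested terms; terms with zero
#' overlap are skipped.
#'
#' @param det_ids test set (e.g. DETs of one direction); must be contained
#'   in `universe_ids`.
#' @param universe_ids the annotation universe (e.g. all annotated
#'   transcripts in the expression matrix).
#' @param go_table data.frame with columns `transcript` and `term`.
#' @param direction optional label stored in the output.
#' @return data.frame: term, universe, term_size, sample_size, overlap,
#'   pvalue, qvalue (sorted by pvalue).
#' @export
#' @examples
#' go <- data.frame(transcript = c("a", "b", "c"), term = "GO:1")
#' go_enrichment(c("a", "b"), letters[1:10], go)
go_enrichment <- function(det_ids, universe_ids, go_table, direction = NA) {
  universe_ids <- unique(universe_ids)
  if (length(universe_ids) == 0) stop("empty universe")
  if (!all(det_ids %in% universe_ids))
    stop("det_ids must be a subset of universe_ids")
  det_ids <- unique(det_ids)
  go <- unique(go_table[go_table$transcript %in% universe_ids,
                        c("transcript", "term")])
  N <- length(universe_ids)
  n <- length(det_ids)
  terms <- split(go$transcript, go$term)
  rows <- lapply(names(terms), function(tm) {
    members <- terms[[tm]]
    k <- sum(det_ids %in% members)
    if (k == 0) return(NULL)
    M <- length(members)
    data.frame(term = tm, universe = N, term_size = M, sample_size = n,
               overlap = k,
               pvalue = phyper(k - 1, M, N - M, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), universe = integer(0),
                      term_size = integer(0), sample_size = integer(0),
                      overlap = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  out$qvalue <- bh_fdr(out$pvalue)
  out$direction <- direction
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
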