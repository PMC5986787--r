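.parse_pair <- function(pair, stages) {
  if (length(pair) == 1) pair <- strsplit(pair, ":", fixed = TRUE)[[1]]
  if (length(pair) != 2) stop("pair must name two stages, e.g. 'initial:terminal'")
  if (!all(pair %in% stages))
    stop("unknown stage(s): ", paste(setdiff(pair, stages), collapse = ", "))
  pair
}

#' Equalize library sizes by quantile adjustment
#'
#' Maps each count to the equivalent quantile of a library scaled to the
#' geometric mean of the observed library sizes, the equal-size pseudo-data
#' the conditional exact test requires. The negative binomial with mean mu
#' and dispersion phi is approximated by a gamma distribution with the same
#' mean and variance (shape mu/(1 + phi mu), scale 1 + phi mu), and the
#' observed count's gamma quantile under the sample's expected mean is
#' mapped to the count with the same quantile at the common depth.
#'
#' @param counts matrix, transcripts x samples (one experimental group or
#'   several; proportions are pooled across all columns).
#' @param dispersion NB dispersion used for the variance model.
#' @return list with `pseudo` (equalized matrix, continuous) and
#'   `common_size` (geometric-mean library size).
#' @export
equalize_libraries <- function(counts, dispersion = 0) {
  counts <- as.matrix(counts)
  N <- colSums(counts)
  if (any(N <= 0)) stop("sample(s) with zero total count: ",
                        paste(colnames(counts)[N <= 0], collapse = ", "))
  N0 <- exp(mean(log(N)))
  p <- rowSums(counts) / sum(counts)
  pseudo <- counts
  for (s in seq_len(ncol(counts))) {
    mu_in <- pmax(p * N[s], 1e-8)
    mu_out <- pmax(p * N0, 1e-8)
    sh_in <- mu_in / (1 + dispersion * mu_in)
    sh_out <- mu_out / (1 + dispersion * mu_out)
    u <- pgamma(counts[, s], shape = sh_in, scale = 1 + dispersion * mu_in)
    u <- pmin(u, 1 - 1e-12)
    pseudo[, s] <- qgamma(u, shape = sh_out, scale = 1 + dispersion * mu_out)
  }
  list(pseudo = pseudo, common_size = N0)
}

# conditional log-likelihood of a common dispersion given equalized counts,
# summed over transcripts; groups = factor over columns
.cond_ll <- function(pseudo, groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in levels(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(rowSums(lgamma(y + r))) - nrow(y) * n * lgamma(r) +
      sum(lgamma(n * r) - lgamma(z + n * r))
  }
  ll
}

#' Common dispersion by quantile-adjusted conditional maximum likelihood
#'
#' Estimates a single negative-binomial dispersion for a two-stage
#' comparison: library sizes are equalized by quantile adjustment to their
#' geometric mean, and the dispersion maximizing the conditional
#' log-likelihood (conditioning each group on its pseudo-count total)
#' summed over transcripts is found; equalization and maximization are
#' alternated until stable. Under-dispersed data yield 0.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param design data.frame with `sample` and `stage`.
#' @param pair two stage labels (vector or "a:b").
#' @return list with `dispersion`, `method` and `common_size`.
#' @export
estimate_common_dispersion <- function(counts, design, pair) {
  pair <- .parse_pair(pair, design$stage)
  keep <- design$stage %in% pair
  if (sum(keep) < 2) stop("need at least 2 samples across the stage pair")
  counts <- as.matrix(counts)[, design$sample[keep], drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero count matrix")
  groups <- factor(design$stage[keep], levels = pair)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  phi <- 0
  eq <- NULL
  for (it in 1:3) {
    eq <- equalize_libraries(counts, phi)
    opt <- optimize(function(lphi) .cond_ll(eq$pseudo, groups, exp(lphi)),
                    interval = log(c(1e-6, 4)), maximum = TRUE, tol = 1e-4)
    cand <- exp(opt$maximum)
    if (opt$objective <= .cond_ll(eq$pseudo, groups, 1e-6) + 1e-8 ||
        cand < 2e-6) cand <- 0
    if (abs(cand - phi) < 1e-4) { phi <- cand; break }
    phi <- cand
  }
  list(dispersion = phi, method = "qCML common", common_size = eq$common_size)
}

# two-sided conditional exact p given group sums at equal library sizes
.exact_p <- function(sa, na, sb, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  k <- 0:t
  m <- t / (na + nb)
  if (phi > 0) {
    lp <- dnbinom(k, size = na / phi, mu = na * m, log = TRUE) +
      dnbinom(t - k, size = nb / phi, mu = nb * m, log = TRUE)
  } else {
    lp <- dpois(k, na * m, log = TRUE) + dpois(t - k, nb * m, log = TRUE)
  }
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[sa + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Exact negative-binomial test for a two-group count split
#'
#' Two-sided conditional exact test: conditioning on the transcript's total
#' count across both groups (library sizes must already be equal), the
#' probability of every split of the total between the groups is computed
#' under a common-mean negative binomial (Poisson when `phi = 0`), and the
#' p-value is the summed probability of all splits at most as likely as the
#' observed one (ties included).
#'
#' @param group_a,group_b non-negative integer count vectors (one entry per
#'   sample; library sizes assumed equalized).
#' @param phi common NB dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' exact_test(c(5, 5), c(5, 5), phi = 0)  # observed split is the mode: p = 1
exact_test <- function(group_a, group_b, phi = 0) {
  if (any(c(group_a, group_b) < 0)) stop("negative counts")
  if (phi < 0) stop("phi must be >= 0")
  .exact_p(sum(group_a), length(group_a), sum(group_b), length(group_b), phi)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment.
#'
#' @param pvalues numeric vector in `[0, 1]`; NA/NaN are an error.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues))) stop("non-finite p-value(s)")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-value(s) outside [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Exact-test differential expression for one stage pair
#'
#' Runs the complete test for every transcript: common-dispersion
#' estimation (unless supplied), quantile equalization of library sizes to
#' the geometric mean, rounding of pseudo-counts to integers, the
#' conditional exact test on per-group pseudo-count sums, and BH
#' adjustment. Fold changes are ratios of per-stage mean RPKM oriented
#' later/earlier stage.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param design data.frame with `sample` and `stage`.
#' @param lengths named transcript lengths (nt) for RPKM.
#' @param pair two stage labels, earlier first (vector or "a:b").
#' @param dispersion optional fixed dispersion; default qCML estimate.
#' @return data.frame: transcript, pair, fc, log2fc, direction, pvalue,
#'   qvalue, plus the per-stage mean RPKM columns `mean_<stage>`.
#' @export
de_test <- function(counts, design, lengths, pair, dispersion = NULL) {
  pair <- .parse_pair(pair, design$stage)
  keep <- design$stage %in% pair
  sub <- design[keep, , drop = FALSE]
  counts <- as.matrix(counts)
  cm <- counts[, sub$sample, drop = FALSE]
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, design, pair)$dispersion
  eq <- equalize_libraries(cm, dispersion)
  pseudo <- round(eq$pseudo)
  ga <- sub$sample[sub$stage == pair[1]]
  gb <- sub$sample[sub$stage == pair[2]]
  sa <- rowSums(pseudo[, ga, drop = FALSE])
  sb <- rowSums(pseudo[, gb, drop = FALSE])
  pv <- vapply(seq_len(nrow(pseudo)), function(i)
    .exact_p(sa[i], length(ga), sb[i], length(gb), dispersion), numeric(1))
  expr <- rpkm(cm, lengths)
  sm <- stage_means(expr, sub)
  fc <- sm[, pair[2]] / sm[, pair[1]]
  out <- data.frame(
    transcript = rownames(cm), pair = paste(pair, collapse = ":"),
    fc = unname(fc), log2fc = unname(log2(fc)),
    direction = ifelse(fc >= 1, "up", "down"),
    pvalue = pv, qvalue = bh_fdr(pv), stringsAsFactors = FALSE)
  out[[paste0("mean_", pair[1])]] <- unname(sm[, pair[1]])
  out[[paste0("mean_", pair[2])]] <- unname(sm[, pair[2]])
  attr(out, "dispersion") <- dispersion
  rownames(out) <- NULL
  out
}

#' Apply the differential-expression filter cascade
#'
#' A transcript is a DET when it passes all three criteria: fold change at
#' least `fc_min` in either direction, q-value at most `q_max`, and the
#' expression floor under the selected mode - `stage-mean` (default)
#' requires the per-stage mean RPKM to exceed `rpkm_floor` in both compared
#' stages; `all-samples` requires RPKM >= `rpkm_floor` in every sample of
#' both stages. Transcripts whose earlier-stage mean is zero have infinite
#' fold change; they are retained when the other criteria pass and flagged
#' in `zero_mean`.
#'
#' @param results output of [de_test()].
#' @param expr RPKM matrix covering the tested samples.
#' @param design data.frame with `sample` and `stage`.
#' @param mode `"stage-mean"` or `"all-samples"`.
#' @param fc_min,q_max,rpkm_floor filter thresholds.
#' @return `results` with logical columns pass_fc, pass_fdr, pass_rpkm,
#'   zero_mean and det.
#' @export
det_filter <- function(results, expr, design, mode = c("stage-mean", "all-samples"),
                       fc_min = 2, q_max = 0.005, rpkm_floor = 3) {
  mode <- match.arg(mode)
  pair <- strsplit(results$pair[1], ":", fixed = TRUE)[[1]]
  stopifnot(all(results$transcript %in% rownames(expr)))
  fc <- results$fc
  zero_mean <- !is.finite(fc) | fc == 0
  mag <- pmax(fc, 1 / fc)  # Inf when a stage mean is 0
  pass_fc <- mag >= fc_min
  pass_fdr <- results$qvalue <= q_max
  sub <- design[design$stage %in% pair, , drop = FALSE]
  e <- expr[results$transcript, sub$sample, drop = FALSE]
  if (mode == "stage-mean") {
    sm <- stage_means(e, sub)
    pass_rpkm <- sm[, pair[1]] > rpkm_floor & sm[, pair[2]] > rpkm_floor
  } else {
    pass_rpkm <- apply(e >= rpkm_floor, 1, all)
  }
  results$pass_fc <- pass_fc
  results$pass_fdr <- pass_fdr
  results$pass_rpkm <- unname(pass_rpkm)
  results$zero_mean <- zero_mean
  results$det <- pass_fc & pass_fdr & unname(pass_rpkm)
  results
}
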