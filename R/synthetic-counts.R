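#' Transcript identifiers used by all generators
#' @param n number of transcripts
#' @return character vector "t00001", ...
#' @keywords internal
transcript_ids <- function(n) sprintf("t%05d", seq_len(n))

# Deterministic selection of the planted DE set (shared between the count
# and catalog generators so GO enrichment can be planted on the same ids).
planted_de_ids <- function(params) {
  n_de <- floor(params$de_fraction * params$n_transcripts)
  if (n_de == 0) return(character(0))
  set.seed(.stream_seed(params, "de"))
  sort(sample(transcript_ids(params$n_transcripts), n_de))
}

#' Simulate a stage-structured count matrix with planted fold changes
#'
#' Draws negative-binomial counts for each transcript and sample,
#' `c ~ NB(mean = L_s * q_g, dispersion = phi)` with `Var = mu + phi mu^2`.
#' Baseline relative abundances `q_g` are log-normal and renormalized per
#' stage so each sample's expected depth equals its library size. Planted
#' DE transcripts have their abundance multiplied by `fold_change` in the
#' terminal stage (up-regulated half) or in all pre-terminal stages
#' (down-regulated half), so the planted contrast is earliest vs terminal.
#'
#' @param params a [sim_params()] object.
#' @return list with `counts` (integer matrix, transcripts x samples),
#'   `design` (data.frame: sample, stage, replicate), `lengths` (named nt
#'   vector) and `truth` (list: `de_transcripts` data.frame with transcript,
#'   pair, log2fc_true, direction; `library_sizes`).
#' @export
#' @examples
#' sim <- simulate_counts(sim_params(n_transcripts = 50, seed = 3))
#' dim(sim$counts)
simulate_counts <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  de_ids <- planted_de_ids(params)
  set.seed(.stream_seed(params, "counts"))
  n <- params$n_transcripts
  ids <- transcript_ids(n)
  stages <- params$stages
  reps <- params$replicates_per_stage
  design <- data.frame(
    sample = paste0(rep(stages, each = reps), "_r", seq_len(reps)),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), times = length(stages)),
    stringsAsFactors = FALSE)

  lengths <- round(runif(n, params$length_range[1], params$length_range[2]))
  names(lengths) <- ids
  q <- rlnorm(n, meanlog = 0, sdlog = 1.5)
  names(q) <- ids

  direction <- character(0)
  if (length(de_ids)) {
    direction <- rep(c("up", "down"), length.out = length(de_ids))
    names(direction) <- de_ids
  }
  terminal <- stages[length(stages)]
  # per-stage abundance, renormalized to proportions
  qs <- sapply(stages, function(st) {
    v <- q
    if (length(de_ids)) {
      if (st == terminal) {
        up <- de_ids[direction == "up"]
        v[up] <- v[up] * params$fold_change
      } else {
        dn <- de_ids[direction == "down"]
        v[dn] <- v[dn] * params$fold_change
      }
    }
    v / sum(v)
  })

  lib <- round(rnorm(nrow(design), params$library_size_mean,
                     0.05 * params$library_size_mean))
  lib <- pmax(lib, 1)
  names(lib) <- design$sample

  counts <- matrix(0L, n, nrow(design), dimnames = list(ids, design$sample))
  for (s in seq_len(nrow(design))) {
    mu <- lib[s] * qs[, design$stage[s]]
    counts[, s] <- if (params$dispersion == 0) rpois(n, mu)
      else rnbinom(n, size = 1 / params$dispersion, mu = mu)
  }
  storage.mode(counts) <- "integer"

  truth_de <- data.frame(transcript = character(0), pair = character(0),
                         log2fc_true = numeric(0), direction = character(0),
                         stringsAsFactors = FALSE)
  if (length(de_ids)) {
    truth_de <- data.frame(
      transcript = de_ids,
      pair = paste0(stages[1], ":", terminal),
      log2fc_true = ifelse(direction == "up", 1, -1) * log2(params$fold_change),
      direction = unname(direction), stringsAsFactors = FALSE)
  }
  list(counts = counts, design = design, lengths = lengths,
       truth = list(de_transcripts = truth_de, library_sizes = lib))
}
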