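#' Simulation parameters for the synthetic-data generators
#'
#' Bundles every knob the generators use. The defaults describe the study
#' design the pipeline is built around: three developmental stages of a
#' primary-root apex (initial, intermediate, terminal) with two biological
#' replicates each, negative-binomial counts at a desk-scale sequencing
#' depth, a planted differentially expressed fraction, and a transcript
#' catalog whose reference copies diverge by point substitutions only.
#'
#' @param n_transcripts number of transcripts in the catalog / count matrix.
#' @param stages ordered character vector of stage labels.
#' @param replicates_per_stage biological replicates per stage.
#' @param library_size_mean expected reads per sample.
#' @param dispersion negative-binomial dispersion phi (Var = mu + phi mu^2);
#'   0 gives Poisson counts. Default 0.01 (biological coefficient of
#'   variation 0.1, the canonical value for genetically homogeneous
#'   material under controlled conditions); appropriate here because each
#'   simulated replicate emulates a pool of hundreds of root apices,
#'   which strongly averages between-plant variation.
#' @param de_fraction fraction of transcripts with a planted fold change.
#' @param fold_change planted fold change (>= 1) between the terminal and
#'   earlier stages; planted transcripts split evenly between up- and
#'   down-regulation at the terminal stage.
#' @param n_orthologues number of query transcripts with a planted
#'   orthologue in the reference catalog.
#' @param mutation_rate per-base substitution probability applied to
#'   planted orthologues.
#' @param orf_fraction fraction of query transcripts carrying a planted
#'   in-frame ORF (ATG ... stop) of known codon count.
#' @param paralog_fraction fraction of planted orthologues that also get a
#'   near-identical second reference copy (allelic variant / paralogue, as
#'   expected for a tetraploid), to exercise best-hit tie-breaking.
#' @param n_decoys unrelated reference-only sequences.
#' @param length_range transcript length range in nt (uniform draw); the
#'   400-nt floor mirrors the minimum contig length of de novo assemblies
#'   this pipeline consumes.
#' @param seed master RNG seed; each generator derives its own stream.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(n_transcripts = 100, seed = 7)
#' p$stages
sim_params <- function(n_transcripts = 2000,
                       stages = c("initial", "intermediate", "terminal"),
                       replicates_per_stage = 2,
                       library_size_mean = 1e6,
                       dispersion = 0.01,
                       de_fraction = 0.1,
                       fold_change = 4,
                       n_orthologues = 50,
                       mutation_rate = 0.02,
                       orf_fraction = 0.66,
                       paralog_fraction = 0.2,
                       n_decoys = 10,
                       length_range = c(400, 4000),
                       seed = 1L) {
  p <- list(n_transcripts = as.integer(n_transcripts), stages = as.character(stages),
            replicates_per_stage = as.integer(replicates_per_stage),
            library_size_mean = library_size_mean, dispersion = dispersion,
            de_fraction = de_fraction, fold_change = fold_change,
            n_orthologues = as.integer(n_orthologues),
            mutation_rate = mutation_rate, orf_fraction = orf_fraction,
            paralog_fraction = paralog_fraction, n_decoys = as.integer(n_decoys),
            length_range = as.numeric(length_range), seed = as.integer(seed))
  stopifnot(p$n_transcripts > 0, length(p$stages) >= 2,
            p$replicates_per_stage > 0, p$library_size_mean > 0,
            p$n_orthologues >= 0, p$n_orthologues <= p$n_transcripts,
            p$n_decoys >= 0, length(p$length_range) == 2,
            p$length_range[1] >= 1, diff(p$length_range) >= 0)
  if (!is.finite(p$dispersion) || p$dispersion < 0)
    stop("dispersion must be a finite value >= 0")
  for (f in c("de_fraction", "orf_fraction", "mutation_rate", "paralog_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$fold_change < 1) stop("fold_change must be >= 1")
  class(p) <- "sim_params"
  p
}

# one RNG stream per generator: fixed offsets from the master seed so adding
# a generator never shifts the draws of another
.stream_seed <- function(params, what) {
  offset <- c(counts = 101L, de = 211L, catalog = 307L, regmap = 401L)[[what]]
  (params$seed %% 2000000000L) + offset
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat(sprintf("  %d transcripts, stages %s x %d replicates\n",
              x$n_transcripts, paste(x$stages, collapse = "/"),
              x$replicates_per_stage))
  cat(sprintf("  library %.3g reads, dispersion %.3g, DE %.0f%% at FC %.3g\n",
              x$library_size_mean, x$dispersion, 100 * x$de_fraction,
              x$fold_change))
  cat(sprintf("  %d orthologues at %.3g substitutions/base, %d decoys, seed %d\n",
              x$n_orthologues, x$mutation_rate, x$n_decoys, x$seed))
  invisible(x)
}
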