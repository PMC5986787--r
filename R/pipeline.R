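#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. All
#' thresholds default to the filter cascade the pipeline is built around
#' (fold change >= 2, q <= 0.005, RPKM floor 3 in stage-mean mode,
#' orthologue coverage > 0.40, E-value < 1e-10). Either pass a list /
#' YAML path of input file locations, or set `simulate` to generate the
#' bundled synthetic study.
#'
#' @param config named list or path to a YAML file; entries override the
#'   defaults below.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    simulate = TRUE,
    sim = list(n_transcripts = 300, n_orthologues = 12, n_decoys = 3,
               length_range = c(400, 1200)),
    counts = NULL, design = NULL, lengths = NULL, query_fasta = NULL,
    reference_fasta = NULL, go_table = NULL, domain_table = NULL,
    regmap = NULL, seeds_file = NULL, other_fasta = NULL,
    pairs = "initial:terminal", fc_min = 2, q_max = 0.005, rpkm_floor = 3,
    rpkm_mode = "stage-mean", k = 3, min_cov = 0.40, max_e = 1e-10,
    seed = 1, out_dir = tempfile("rootapex_run_"))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$fc_min >= 1, cfg$q_max > 0, cfg$q_max <= 1,
            cfg$rpkm_floor >= 0, cfg$min_cov >= 0, cfg$min_cov < 1,
            cfg$max_e > 0, cfg$k >= 1)
  if (!cfg$rpkm_mode %in% c("stage-mean", "all-samples"))
    stop("rpkm_mode must be 'stage-mean' or 'all-samples'")
  if (!isTRUE(cfg$simulate)) {
    needed <- c("counts", "design", "lengths", "query_fasta")
    for (f in needed) {
      if (is.null(cfg[[f]])) stop("config entry '", f, "' is required when simulate = FALSE")
      if (!file.exists(cfg[[f]])) stop("missing input file for '", f, "': ", cfg[[f]])
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, differential expression for every configured
#' stage pair, PCA, k-means clustering of DET profiles, GO enrichment,
#' orthologue calling, regulatory-map projection and the
#' lineage-specific-transcript analysis, writing TSV outputs and a JSON
#' run manifest (inputs, parameters, seeds, output hashes) under
#' `config$out_dir`. Reruns with an identical configuration reproduce the
#' same outputs. Any stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced
#'   through it).
#' @return the manifest, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(x, p)
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    log <- .log_stage(log, "simulate", "generating synthetic study")
    params <- do.call(sim_params, utils::modifyList(
      list(seed = config$seed), config$sim))
    sim <- step("simulate", simulate_counts(params))
    cat_sim <- step("simulate", simulate_catalog(params))
    reg <- step("simulate", simulate_regmap(n_seeds = 3, n_neighbours = 8,
                                            extra_nodes = 4,
                                            seed = params$seed))
    counts <- sim$counts; design <- sim$design; lengths <- sim$lengths
    query <- cat_sim$query; reference <- cat_sim$reference
    go_tab <- cat_sim$go; dom_tab <- cat_sim$domains
    regmap <- reg$map; seeds <- reg$seeds
    # regulatory-map sources are reference-catalog genes here: alias the
    # seed/neighbour ids onto reference ids so projection is exercised
    src_ids <- sort(unique(c(regmap$regulator, regmap$target)))
    alias <- stats::setNames(
      rep(names(reference)[seq_len(min(length(src_ids), length(reference)))],
          length.out = length(src_ids)), src_ids)
    other <- NULL
  } else {
    log <- .log_stage(log, "load", "reading input files")
    counts <- step("load", read_counts(config$counts))
    design <- step("load", read_design(config$design))
    ltab <- step("load", read.delim(config$lengths, stringsAsFactors = FALSE))
    lengths <- stats::setNames(ltab[[2]], ltab[[1]])
    query <- step("load", read_fasta(config$query_fasta))
    reference <- if (!is.null(config$reference_fasta))
      step("load", read_fasta(config$reference_fasta)) else NULL
    go_tab <- if (!is.null(config$go_table))
      step("load", read.delim(config$go_table, stringsAsFactors = FALSE)) else NULL
    dom_tab <- if (!is.null(config$domain_table))
      step("load", read.delim(config$domain_table, stringsAsFactors = FALSE)) else NULL
    regmap <- if (!is.null(config$regmap)) step("load", read_regmap(config$regmap)) else NULL
    seeds <- if (!is.null(config$seeds_file))
      step("load", readLines(config$seeds_file)) else NULL
    other <- if (!is.null(config$other_fasta))
      step("load", read_fasta(config$other_fasta)) else NULL
    alias <- NULL
  }

  # --- quantify -------------------------------------------------------
  log <- .log_stage(log, "quantify", "RPKM normalization")
  expr <- step("quantify", rpkm(counts, lengths))
  emit(data.frame(transcript = rownames(expr), expr, check.names = FALSE),
       "rpkm.tsv")

  # --- differential expression ---------------------------------------
  pairs <- as.list(config$pairs)
  det_ids <- character(0)
  de_tables <- list()
  for (pr in pairs) {
    log <- .log_stage(log, "de", paste("testing", pr))
    res <- step("de", de_test(counts, design, lengths, pr))
    res <- step("de", det_filter(res, expr, design, mode = config$rpkm_mode,
                                 fc_min = config$fc_min, q_max = config$q_max,
                                 rpkm_floor = config$rpkm_floor))
    de_tables[[pr]] <- res
    det_ids <- union(det_ids, res$transcript[res$det])
    emit(res, paste0("de_", gsub(":", "_vs_", pr), ".tsv"))
  }

  # --- profiles -------------------------------------------------------
  log <- .log_stage(log, "pca", "sample PCA")
  pca <- step("pca", pca_samples(expr))
  emit(data.frame(sample = rownames(pca$scores), pca$scores[, 1:min(3, ncol(pca$scores)), drop = FALSE]),
       "pca_scores.tsv")
  emit(data.frame(component = seq_along(pca$var_fraction),
                  var_fraction = pca$var_fraction), "pca_variance.tsv")

  if (length(det_ids) >= config$k) {
    log <- .log_stage(log, "cluster", sprintf("k-means on %d DETs", length(det_ids)))
    sm <- stage_means(log2(expr + 1), design)
    prof <- sm[det_ids, , drop = FALSE]
    prof <- prof[apply(prof, 1, sd) > 0, , drop = FALSE]
    cl <- step("cluster", kmeans_profiles(prof, k = min(config$k, nrow(prof)),
                                          seed = config$seed))
    emit(data.frame(transcript = names(cl$cluster), cluster = cl$cluster),
         "clusters.tsv")
  }

  if (!is.null(go_tab) && length(det_ids)) {
    log <- .log_stage(log, "enrich", "hypergeometric GO enrichment")
    universe <- intersect(rownames(expr), unique(go_tab$transcript))
    enr <- step("enrich", go_enrichment(intersect(det_ids, universe),
                                        universe, go_tab))
    emit(enr, "enrichment.tsv")
  }

  # --- orthology + network -------------------------------------------
  ortho <- NULL
  if (!is.null(reference)) {
    n_orth <- if (isTRUE(config$simulate)) config$sim$n_orthologues
      else length(query)
    qsub <- query[seq_len(min(n_orth + 10, length(query)))]
    log <- .log_stage(log, "ortho", sprintf("BBH search %d x %d",
                                            length(reference), length(qsub)))
    ortho <- step("ortho", call_orthologs(
      reference, qsub,
      domains_a = dom_tab, domains_b = dom_tab,
      min_cov = config$min_cov, max_e = config$max_e))
    emit(ortho, "orthologs.tsv")
  }

  if (!is.null(regmap) && !is.null(seeds) && !is.null(ortho)) {
    log <- .log_stage(log, "project", "regulatory-map projection")
    sub <- step("project", extract_subgraph(regmap, seeds))
    prs <- ortho
    if (!is.null(alias)) {  # synthetic run: map-node -> reference id -> transcript
      ref_of <- alias[prs$query]
      prs2 <- prs
      prs2$query <- names(alias)[match(prs$query, alias)]
      prs <- prs2[!is.na(prs2$query), , drop = FALSE]
    }
    net <- step("project", project_network(sub, prs, expr, design))
    export_network(net, file.path(config$out_dir, "network"))
    outputs <- c(outputs, file.path(config$out_dir,
                                    paste0("network", c(".sif", ".graphml", ".nodes.tsv"))))
  }

  # --- lineage-specific ----------------------------------------------
  if (length(det_ids)) {
    log <- .log_stage(log, "orphans", "lineage-specific transcript analysis")
    ann <- if (!is.null(go_tab)) go_tab else
      data.frame(transcript = character(0))
    orphan_ids <- step("orphans", unannotated_dets(det_ids, ann))
    orphan_ids <- intersect(orphan_ids, names(query))
    if (length(orphan_ids)) {
      orfs <- step("orphans", classify_orfs(query, orphan_ids))
      if (!is.null(other)) {
        flags <- step("orphans", cross_species_check(orphan_ids, query, other,
                                                     max_e = config$max_e))
        orfs <- merge(orfs, flags, by = "transcript")
      }
      emit(orfs, "orphans.tsv")
    }
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "rootapex",
    version = as.character(utils::packageVersion("rootapex")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    log = log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
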