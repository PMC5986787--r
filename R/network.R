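.map_graph <- function(map) {
  stopifnot(all(c("regulator", "target") %in% names(map)))
  g <- igraph::graph_from_data_frame(
    map[, c("regulator", "target",
            setdiff(names(map), c("regulator", "target"))), drop = FALSE],
    directed = TRUE)
  g
}

#' Extract the seed-plus-first-neighbour subgraph of a regulatory map
#'
#' Node set = seeds plus every node adjacent to a seed in either
#' direction; edge set = the induced subgraph (all map edges with both
#' endpoints in the node set, so neighbour-neighbour interactions are
#' kept). With `seed_incident_only = TRUE` only edges touching a seed are
#' retained (the stricter reading).
#'
#' @param map data.frame edge list with columns `regulator`, `target` and
#'   optional annotation columns (e.g. `effect`).
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   map are reported with a warning, and it is an error if none is found.
#' @param seed_incident_only drop neighbour-neighbour edges (default
#'   FALSE).
#' @return a regulatory map data.frame (same columns as `map`), with
#'   attribute `nodes` (sorted node ids of the subgraph).
#' @export
extract_subgraph <- function(map, seeds, seed_incident_only = FALSE) {
  stopifnot(length(seeds) > 0)
  g <- .map_graph(map)
  known <- seeds[seeds %in% igraph::V(g)$name]
  if (length(known) == 0) stop("no seed found in the map")
  if (length(known) < length(seeds))
    warning("seed(s) not in map: ",
            paste(setdiff(seeds, known), collapse = ", "))
  nb <- unique(unlist(lapply(known, function(s)
    igraph::neighbors(g, s, mode = "all")$name)))
  nodes <- sort(unique(c(known, nb)))
  keep <- map$regulator %in% nodes & map$target %in% nodes
  if (seed_incident_only)
    keep <- keep & (map$regulator %in% known | map$target %in% known)
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes") <- nodes
  attr(out, "seeds") <- sort(known)
  out
}

#' Project a regulatory subgraph onto a target transcriptome
#'
#' Each source node is replaced by its orthologous target transcript;
#' nodes with no orthologue are dropped together with their incident
#' edges. When several target transcripts map to one source node, the one
#' with the best supporting bit score (lexicographic id tie-break)
#' represents the node and the rest are recorded as alternates. Node
#' attributes carry the orthology class and the mean over all samples of
#' `log2(RPKM + 1)` (and per-stage means when a design is given);
#' transcripts absent from the expression matrix are kept with
#' `expr_absent = TRUE`.
#'
#' @param subgraph output of [extract_subgraph()] (or any edge list).
#' @param pairs orthologue table with columns `query` (source ids),
#'   `target` (target transcript ids), `class` and optionally `bits`;
#'   rows with class `unmapped` or missing target are ignored.
#' @param expr RPKM matrix over target transcripts.
#' @param design optional data.frame (`sample`, `stage`) for per-stage
#'   node attributes.
#' @return list of class `projected_network`: `edges` (data.frame
#'   regulator/target in target-species ids + `effect` if present),
#'   `nodes` (data.frame node, source, class, mean_log2_rpkm,
#'   expr_absent, alternates, module), sorted deterministically.
#' @export
project_network <- function(subgraph, pairs, expr, design = NULL) {
  pairs <- pairs[!is.na(pairs$target) & pairs$class != "unmapped", , drop = FALSE]
  if (nrow(pairs) == 0) stop("empty orthologue pair list")
  nodes <- attr(subgraph, "nodes")
  if (is.null(nodes))
    nodes <- sort(unique(c(subgraph$regulator, subgraph$target)))
  pairs <- pairs[pairs$query %in% nodes, , drop = FALSE]
  if (is.null(pairs$bits)) pairs$bits <- 0
  # best target per source node, alternates preserved
  reps <- lapply(split(pairs, pairs$query), function(d) {
    d <- d[order(-d$bits, d$target), , drop = FALSE]
    list(best = d[1, ], alternates = d$target[-1])
  })
  mapped <- names(reps)
  node_tab <- do.call(rbind, lapply(mapped, function(src) {
    b <- reps[[src]]$best
    data.frame(node = b$target, source = src, class = b$class,
               alternates = paste(reps[[src]]$alternates, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  keep <- subgraph$regulator %in% mapped & subgraph$target %in% mapped
  edges <- subgraph[keep, , drop = FALSE]
  to_target <- stats::setNames(node_tab$node, node_tab$source)
  edges$regulator <- unname(to_target[edges$regulator])
  edges$target <- unname(to_target[edges$target])
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL

  node_tab$expr_absent <- !(node_tab$node %in% rownames(expr))
  lx <- log2(expr + 1)
  node_tab$mean_log2_rpkm <- ifelse(node_tab$expr_absent, NA_real_,
                                    rowMeans(lx)[node_tab$node])
  if (!is.null(design)) {
    sm <- stage_means(lx, design)
    for (st in colnames(sm))
      node_tab[[paste0("log2_rpkm_", st)]] <-
        ifelse(node_tab$expr_absent, NA_real_, sm[node_tab$node, st])
  }
  node_tab <- node_tab[order(node_tab$node), , drop = FALSE]
  rownames(node_tab) <- NULL
  net <- structure(list(edges = edges, nodes = node_tab,
                        dropped = setdiff(nodes, mapped)),
                   class = "projected_network")
  net$nodes$module <- decompose_modules(net)
  net
}

#' Label weakly connected components of a projected network
#'
#' Modules are numbered deterministically: components are sorted by their
#' smallest member id and labelled 1, 2, ...
#'
#' @param network a `projected_network`.
#' @return integer module label per node, in the order of `network$nodes`.
#' @export
decompose_modules <- function(network) {
  nodes <- network$nodes$node
  g <- igraph::graph_from_data_frame(
    network$edges[, c("regulator", "target"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = nodes))
  comp <- igraph::components(g, mode = "weak")$membership
  smallest <- tapply(names(comp), comp, min)
  relabel <- stats::setNames(rank(smallest, ties.method = "first"),
                             names(smallest))
  unname(as.integer(relabel[as.character(comp[nodes])]))
}

#' @export
print.projected_network <- function(x, ...) {
  cat(sprintf("projected network: %d nodes, %d edges, %d module(s); %d source node(s) dropped\n",
              nrow(x$nodes), nrow(x$edges), max(c(0L, x$nodes$module)),
              length(x$dropped)))
  invisible(x)
}

#' Export a projected network for Cytoscape
#'
#' Writes a SIF interaction file, a GraphML file, and a node-attribute
#' TSV.
#'
#' @param network a `projected_network`.
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>.graphml` and `<prefix>.nodes.tsv` are written.
#' @return invisibly, the written paths.
#' @export
export_network <- function(network, prefix) {
  rel <- if ("effect" %in% names(network$edges)) network$edges$effect
    else rep("regulates", nrow(network$edges))
  sif <- paste(network$edges$regulator, rel, network$edges$target)
  sif_path <- paste0(prefix, ".sif")
  writeLines(sif, sif_path)
  g <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(name = network$nodes$node,
                          network$nodes[, setdiff(names(network$nodes), "node"),
                                        drop = FALSE]))
  gml_path <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  nodes_path <- paste0(prefix, ".nodes.tsv")
  write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sif_path, gml_path, nodes_path))
}
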