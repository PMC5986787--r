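star_map <- function() {
  data.frame(regulator = "hub", target = paste0("leaf", 1:5),
             effect = "activation", stringsAsFactors = FALSE)
}

test_that("subgraph extraction keeps seeds, first neighbours and their edges", {
  m <- star_map()
  # seed = one leaf: the hub is its only neighbour
  sub <- extract_subgraph(m, "leaf2")
  expect_identical(attr(sub, "nodes"), c("hub", "leaf2"))
  expect_identical(nrow(sub), 1L)
  # seeds = all nodes reproduce the map
  sub_all <- extract_subgraph(m, c("hub", paste0("leaf", 1:5)))
  expect_identical(sub_all$regulator, m$regulator)
  expect_identical(sub_all$target, m$target)
  # decoy components never touching seeds are excluded
  m2 <- rbind(m, data.frame(regulator = "x1", target = "x2",
                            effect = "activation"))
  sub2 <- extract_subgraph(m2, "hub")
  expect_false(any(c("x1", "x2") %in% attr(sub2, "nodes")))
  expect_error(extract_subgraph(m, "nope"), "no seed")
  expect_warning(extract_subgraph(m, c("hub", "nope")), "nope")
})

test_that("induced semantics keep neighbour-neighbour edges; strict mode drops them", {
  m <- data.frame(regulator = c("s", "n1", "n1"),
                  target = c("n1", "n2", "s"), stringsAsFactors = FALSE)
  m <- rbind(m, data.frame(regulator = "n2", target = "n1"))
  # with seed s: neighbours are n1 (n2 is NOT adjacent to s)
  sub <- extract_subgraph(m, "s")
  expect_identical(attr(sub, "nodes"), c("n1", "s"))
  # seed n1: nodes s, n1, n2; induced keeps the n2->n1 and n1->n2 edges
  sub2 <- extract_subgraph(m, "n1")
  expect_identical(nrow(sub2), 4L)
  sub3 <- extract_subgraph(m, "n1", seed_incident_only = TRUE)
  expect_identical(nrow(sub3), 4L)  # all edges touch n1 here
  sub4 <- extract_subgraph(rbind(m, data.frame(regulator = "s", target = "n2")),
                           "s")
  # now n2 is a neighbour; induced subgraph keeps n1<->n2 interactions
  expect_identical(nrow(sub4), 5L)
  sub5 <- extract_subgraph(rbind(m, data.frame(regulator = "s", target = "n2")),
                           "s", seed_incident_only = TRUE)
  expect_identical(nrow(sub5), 3L)
})

test_that("identity orthology projects a network isomorphic to the subgraph", {
  rm_ <- simulate_regmap(2, 6, 3, seed = 8)
  sub <- extract_subgraph(rm_$map, rm_$seeds)
  nodes <- attr(sub, "nodes")
  pairs <- data.frame(query = nodes, target = paste0("pp_", nodes),
                      class = "bidirectional", bits = 50)
  expr <- matrix(7, length(nodes), 2,
                 dimnames = list(paste0("pp_", nodes), c("s1", "s2")))
  net <- project_network(sub, pairs, expr)
  expect_identical(nrow(net$nodes), length(nodes))
  expect_identical(nrow(net$edges), nrow(sub))
  expect_identical(sort(net$nodes$node), sort(paste0("pp_", nodes)))
  expect_equal(net$nodes$mean_log2_rpkm, rep(log2(8), length(nodes)))
  expect_length(net$dropped, 0)
})

test_that("unmapped nodes are dropped with exactly their incident edges", {
  path <- data.frame(regulator = c("a", "b"), target = c("b", "c"),
                     stringsAsFactors = FALSE)
  sub <- extract_subgraph(path, c("a", "b", "c"))
  expr <- matrix(0, 2, 1, dimnames = list(c("A", "C"), "s1"))
  pairs <- data.frame(query = c("a", "c"), target = c("A", "C"),
                      class = "unidirectional", bits = 1)
  net <- project_network(sub, pairs, expr)
  expect_identical(net$nodes$node, c("A", "C"))
  expect_identical(nrow(net$edges), 0L)
  expect_identical(net$dropped, "b")
  # zero RPKM everywhere -> node attribute log2(1) = 0
  expect_equal(net$nodes$mean_log2_rpkm, c(0, 0))
  expect_error(project_network(sub, pairs[0, ], expr), "empty")
})

test_that("multi-mapped source nodes keep the best-scoring transcript", {
  sub <- data.frame(regulator = "a", target = "b", stringsAsFactors = FALSE)
  attr(sub, "nodes") <- c("a", "b")
  pairs <- data.frame(query = c("a", "a", "b"),
                      target = c("A1", "A2", "B"),
                      class = c("bidirectional", "unidirectional",
                                "bidirectional"),
                      bits = c(10, 90, 5))
  expr <- matrix(1, 3, 1, dimnames = list(c("A1", "A2", "B"), "s1"))
  net <- project_network(sub, pairs, expr)
  arow <- net$nodes[net$nodes$source == "a", ]
  expect_identical(arow$node, "A2")
  expect_identical(arow$alternates, "A1")
})

test_that("module decomposition labels weak components deterministically", {
  tri <- function(p) data.frame(regulator = paste0(p, c(1, 2, 3)),
                                target = paste0(p, c(2, 3, 1)),
                                stringsAsFactors = FALSE)
  m <- rbind(tri("a"), tri("b"))
  sub <- extract_subgraph(m, unique(c(m$regulator, m$target)))
  nodes <- attr(sub, "nodes")
  pairs <- data.frame(query = nodes, target = toupper(nodes),
                      class = "bidirectional", bits = 1)
  expr <- matrix(1, 6, 1, dimnames = list(toupper(nodes), "s1"))
  net <- project_network(sub, pairs, expr)
  expect_identical(max(net$nodes$module), 2L)
  expect_identical(as.integer(table(net$nodes$module)), c(3L, 3L))
  # module 1 contains the smallest node id
  expect_identical(net$nodes$module[net$nodes$node == min(net$nodes$node)], 1L)
  # fully connected map -> one module
  m1 <- tri("z")
  sub1 <- extract_subgraph(m1, unique(c(m1$regulator, m1$target)))
  p1 <- data.frame(query = attr(sub1, "nodes"),
                   target = toupper(attr(sub1, "nodes")),
                   class = "bidirectional", bits = 1)
  e1 <- matrix(1, 3, 1, dimnames = list(toupper(attr(sub1, "nodes")), "s1"))
  expect_identical(max(project_network(sub1, p1, e1)$nodes$module), 1L)
})

test_that("exports write SIF, GraphML and node attributes", {
  rm_ <- simulate_regmap(1, 4, 0, seed = 2)
  sub <- extract_subgraph(rm_$map, rm_$seeds)
  nodes <- attr(sub, "nodes")
  pairs <- data.frame(query = nodes, target = paste0("pp_", nodes),
                      class = "bidirectional", bits = 1)
  expr <- matrix(2, length(nodes), 1,
                 dimnames = list(paste0("pp_", nodes), "s1"))
  net <- project_network(sub, pairs, expr)
  pre <- file.path(tempdir(), "nettest")
  paths <- export_network(net, pre)
  expect_true(all(file.exists(paths)))
  expect_length(readLines(paste0(pre, ".sif")), nrow(net$edges))
  g <- igraph::read_graph(paste0(pre, ".graphml"), format = "graphml")
  expect_equal(as.integer(igraph::vcount(g)), nrow(net$nodes))
  expect_equal(as.integer(igraph::ecount(g)), nrow(net$edges))
})
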