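test_that("degree counts distinct neighbors; in/out count directed edges", {
  tri <- gene_network(tibble::tibble(from = c("A", "B", "C"),
                                     to = c("B", "C", "A")),
                      directed = TRUE)
  d <- degree_stats(tri)
  expect_equal(d$degree, c(2L, 2L, 2L))
  expect_equal(d$indegree, c(1L, 1L, 1L))
  expect_equal(d$outdegree, c(1L, 1L, 1L))

  iso <- gene_network(tibble::tibble(from = "A", to = "B"),
                      nodes = tibble::tibble(node = c("A", "B", "Z")),
                      directed = TRUE)
  z <- degree_stats(iso)[degree_stats(iso)$node == "Z", ]
  expect_equal(unlist(z[c("degree", "indegree", "outdegree")],
                      use.names = FALSE), c(0L, 0L, 0L))
})

test_that("a reciprocal-heavy hub reproduces the 17/16/16 degree pattern", {
  spokes <- sprintf("s%02d", 1:17)
  edges <- dplyr::bind_rows(
    tibble::tibble(from = spokes[1:16], to = "hub"),   # 16 in-neighbors
    tibble::tibble(from = "hub", to = spokes[2:17]))   # 16 out, 15 reciprocal
  net <- gene_network(edges, directed = TRUE)
  hub <- degree_stats(net)[degree_stats(net)$node == "hub", ]
  expect_equal(hub$degree, 17L)
  expect_equal(hub$indegree, 16L)
  expect_equal(hub$outdegree, 16L)
})

test_that("betweenness matches closed forms on path and star", {
  path <- gene_network(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  b <- betweenness_stats(path)
  expect_equal(b$betweenness[b$node == "B"], 1)
  expect_equal(b$betweenness[b$node != "B"], c(0, 0))

  star <- gene_network(tibble::tibble(from = "c", to = sprintf("l%d", 1:6)))
  bs <- betweenness_stats(star)
  expect_equal(bs$betweenness[bs$node == "c"], 1)

  tiny <- gene_network(tibble::tibble(from = "A", to = "B"))
  expect_equal(betweenness_stats(tiny)$betweenness, c(0, 0))
})

test_that("betweenness equals brute-force geodesic enumeration on seeded digraphs", {
  for (seed in c(101, 202)) {
    edges <- random_digraph(12, 30, seed)
    net <- gene_network(edges, directed = TRUE)
    oracle <- oracle_betweenness(as.data.frame(net$edges),
                                 net$nodes$node, directed = TRUE)
    expect_equal(net$nodes$betweenness, unname(oracle[net$nodes$node]),
                 tolerance = 1e-12)
  }
  # undirected case
  edges <- random_digraph(10, 16, 303)
  net <- gene_network(edges, directed = FALSE)
  oracle <- oracle_betweenness(as.data.frame(net$edges), net$nodes$node,
                               directed = FALSE)
  expect_equal(net$nodes$betweenness, unname(oracle[net$nodes$node]),
               tolerance = 1e-12)
})

test_that("k-core matches hand pruning and the iterative oracle", {
  tri_pend <- gene_network(tibble::tibble(from = c("A", "B", "C", "C"),
                                          to = c("B", "C", "A", "D")))
  k <- k_core_stats(tri_pend)
  expect_equal(k$k_core[k$node %in% c("A", "B", "C")], c(2L, 2L, 2L))
  expect_equal(k$k_core[k$node == "D"], 1L)

  clique5 <- gene_network(
    tibble::as_tibble(as.data.frame(t(combn(paste0("v", 1:5), 2)),
                                    col.names = c("from", "to"))) |>
      setNames(c("from", "to")))
  expect_true(all(k_core_stats(clique5)$k_core == 4L))

  er <- random_digraph(30, 60, 404)
  net <- gene_network(er, directed = FALSE)
  oracle <- oracle_kcore(as.data.frame(net$edges), net$nodes$node)
  expect_equal(net$nodes$k_core, unname(oracle[net$nodes$node]))
})

test_that("graph invariants hold on seeded graphs", {
  edges <- random_digraph(15, 40, 505)
  net <- gene_network(edges, directed = TRUE)
  d <- degree_stats(net)
  expect_equal(sum(d$indegree), nrow(net$edges))
  expect_equal(sum(d$outdegree), nrow(net$edges))
  expect_true(all(net$nodes$k_core <= net$nodes$degree))
  # nestedness: (k+1)-core members are a subset of k-core members
  for (k in sort(unique(net$nodes$k_core))) {
    expect_true(all(net$nodes$node[net$nodes$k_core >= k + 1] %in%
                      net$nodes$node[net$nodes$k_core >= k]))
  }
})

test_that("betweenness is invariant under node relabeling", {
  edges <- random_digraph(10, 25, 606)
  net <- gene_network(edges, directed = TRUE)
  relabel <- setNames(sprintf("x%02d", sample(10)), unique(
    c(edges$from, edges$to)))
  edges2 <- tibble::tibble(from = unname(relabel[edges$from]),
                           to = unname(relabel[edges$to]))
  net2 <- gene_network(edges2, directed = TRUE)
  m <- match(unname(relabel[net$nodes$node]), net2$nodes$node)
  expect_equal(net2$nodes$betweenness[m], net$nodes$betweenness,
               tolerance = 1e-12)
})

test_that("self-loops are dropped and duplicate edges collapsed", {
  net <- gene_network(tibble::tibble(from = c("A", "A", "A"),
                                     to = c("A", "B", "B")),
                      directed = TRUE)
  expect_equal(nrow(net$edges), 1)
})

test_that("GraphML and edge-TSV writers round-trip losslessly", {
  edges <- random_digraph(8, 14, 707)
  edges$sign <- sample(c("+", "-"), nrow(edges), replace = TRUE)
  nodes <- tibble::tibble(node = sort(unique(c(edges$from, edges$to))),
                          regulation = "up")
  net <- gene_network(edges, nodes = nodes, directed = TRUE)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- read_graphml(gml)
  expect_equal(back$nodes$node, net$nodes$node)
  expect_equal(back$nodes$degree, net$nodes$degree)
  expect_equal(back$nodes$betweenness, net$nodes$betweenness,
               tolerance = 1e-12)
  expect_setequal(paste(back$edges$from, back$edges$to, back$edges$sign),
                  paste(net$edges$from, net$edges$to, net$edges$sign))
  expect_equal(back$nodes$regulation, net$nodes$regulation)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(net, tsv)
  back2 <- read_edge_tsv(tsv, nodes = nodes)
  expect_equal(back2$edges, net$edges, ignore_attr = TRUE)
  expect_true(back2$directed)
})

test_that("tidy and glance summarize a network", {
  net <- gene_network(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  expect_s3_class(tidy(net), "tbl_df")
  g <- glance(net)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_edges, 2L)
  expect_equal(g$n_components, 1L)
})
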