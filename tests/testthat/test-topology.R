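test_that("degree histogram bins log-degrees evenly and conserves counts", {
  star <- igraph::make_star(10, mode = "undirected")  # degrees 9, 1 x 9
  h <- degree_histogram(star)
  expect_identical(nrow(h), 10L)
  expect_identical(sum(h$count), 10L)
  expect_identical(sum(h$count > 0), 2L)   # two occupied bins
  expect_equal(h$count[1], 9)              # the nine leaves at ln(1) = 0
  expect_equal(h$count[10], 1)             # the hub in the closed last bin
  # all-equal degrees collapse into a single degenerate bin
  ring <- igraph::make_ring(6)
  h1 <- degree_histogram(ring)
  expect_identical(nrow(h1), 1L)
  expect_identical(sum(h1$count), 6L)
  expect_equal(h1$center, log(2))
  # half-open convention: a degree on an interior boundary falls upward
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "b", "c", "c", "c", "c"),
               to = c("x1", "x2", "x3", "x4", "x5", "x6", "x7")),
    directed = FALSE)
  # degrees: a = 1, b = 2, c = 4, leaves x1..x7 = 1; ln-degrees 0, .69, 1.39
  # breaks are [0, .693), [.693, 1.386]: b's ln(2) boundary falls upward
  h2 <- degree_histogram(g, n_bins = 2)
  expect_identical(h2$count, c(8L, 2L))
  expect_identical(sum(h2$count), 10L)
})

test_that("betweenness matches simple closed forms", {
  path3 <- igraph::make_graph(~ a - b - c)
  b <- betweenness_centrality(path3)
  expect_equal(b[["b"]], 1)
  expect_equal(unname(b[c("a", "c")]), c(0, 0))
  star <- igraph::make_star(4, center = 1, mode = "undirected")
  expect_equal(max(betweenness_centrality(star)), 3)  # C(3,2) pairs
})

test_that("betweenness equals brute-force geodesic enumeration on random
           graphs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.15, 0.45))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    expect_equal(sort(betweenness_centrality(g)),
                 sort(brute_betweenness(g)), tolerance = 1e-9,
                 label = paste("graph", rep))
  }
})

test_that("dense subregion mining finds cliques and honors the haircut", {
  # a 5-clique with a pendant chain: top cluster is exactly the clique
  clique <- igraph::make_full_graph(5)
  igraph::V(clique)$name <- paste0("k", 1:5)
  chain <- igraph::make_graph(~ k5 - p1 - p2 - p3)
  g <- igraph::simplify(igraph::union(clique, chain))
  cl <- dense_subregions(g)
  expect_gte(length(cl), 1)
  expect_setequal(cl[[1]]$nodes, paste0("k", 1:5))
  expect_equal(cl[[1]]$n_edges, 10)
  # two disjoint cliques: two clusters, no shared nodes
  g2 <- igraph::graph_from_data_frame(
    rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:5), 2))) |>
      as.data.frame(), directed = FALSE)
  cl2 <- dense_subregions(g2)
  expect_identical(length(cl2), 2L)
  expect_length(intersect(cl2[[1]]$nodes, cl2[[2]]$nodes), 0)
  expect_setequal(cl2[[1]]$nodes, paste0("b", 1:5))  # larger clique first
  # haircut: every member keeps within-cluster degree >= 2, clusters
  # are connected
  set.seed(5)
  g3 <- igraph::sample_gnp(40, 0.12)
  igraph::V(g3)$name <- paste0("n", 1:40)
  for (cc in dense_subregions(g3)) {
    sub <- igraph::induced_subgraph(g3, cc$nodes)
    expect_true(igraph::is_connected(sub))
    expect_true(all(igraph::degree(sub) >= 2))
  }
  expect_identical(dense_subregions(igraph::make_empty_graph(0)), list())
})

test_that("fisher_2x2 matches the hypergeometric closed form", {
  expect_equal(fisher_2x2(3, 1, 1, 3, "greater"), 17 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_2x2(0, 5, 7, 0, "greater"), 1)
  # tail identity on a symmetric table: P(>=) + P(<=) - P(=) = 1
  point <- stats::dhyper(2, 4, 4, 4)
  expect_equal(fisher_2x2(2, 2, 2, 2, "greater") +
               fisher_2x2(2, 2, 2, 2, "less") - point, 1,
               tolerance = 1e-12)
  expect_identical(fisher_2x2(0, 0, 0, 0), 1)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # order-preserving
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("category representation flags the loaded cluster", {
  co <- tiny_cohort(seed = 1)
  db <- co$pathway_db
  # pick one (category, tissue) cluster and make the network exactly it
  cat1 <- db$categories[[1]]
  members <- names(db$categories)[db$categories == cat1]
  rel <- list(t1 = paste0(members, "|islet"))
  net0 <- build_network(co$pci, db$links, threshold = 1.5)  # no edges
  tpn <- assemble_network(rel, list(direct = character(),
                                    path2 = character(),
                                    path3 = character()),
                          net0, traits = "t1", pathway_db = db)
  res <- category_representation(tpn, db,
                                 tissues = c("adipose", "islet", "liver"))
  top <- res[1, ]
  expect_identical(top$category, cat1)
  expect_identical(top$tissue, "islet")
  expect_true(all(res$over_p >= top$over_p))
  expect_true(all(res$over_p >= 0 & res$over_p <= 1))
  # empty network: nothing over-represented
  tpn0 <- assemble_network(list(t1 = character()),
                           list(direct = character(), path2 = character(),
                                path3 = character()),
                           net0, traits = "t1", pathway_db = db)
  res0 <- category_representation(tpn0, db,
                                  tissues = c("adipose", "islet", "liver"))
  expect_true(all(res0$over_p == 1))
})

test_that("interaction enhancement ranks saturated nodes first", {
  co <- tiny_cohort(seed = 2)
  net <- build_network(co$pci, co$pathway_db$links, threshold = 0.55)
  res <- interaction_enhancement(net)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$fdr >= res$p))
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$degree <= res$opportunities))
  # constructed case: node A realizes all 4 of its opportunities while the
  # rest of a complete candidate set stays empty -> A is the clear top hit
  nodes <- paste0("pw", 1:5, "|t")
  cand <- as.data.frame(t(combn(nodes, 2)), stringsAsFactors = FALSE)
  names(cand) <- c("from", "to")
  cand$type <- "curated"
  edges <- cand[cand$from == nodes[1] | cand$to == nodes[1], ]
  edges$r <- 0.9
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  toy <- structure(list(graph = g, edges = edges, candidates = cand,
                        threshold = 0.5), class = "pathway_network")
  res2 <- interaction_enhancement(toy)
  expect_identical(res2$node[1], nodes[1])
  expect_equal(res2$p[1],
               fisher_2x2(4, 0, 0, 6, "greater"), tolerance = 1e-12)
  expect_lt(res2$p[1], min(res2$p[-1]))
  # uniform realization: nothing stands out
  edges_u <- cand
  edges_u$r <- 0.9
  gu <- igraph::graph_from_data_frame(edges_u[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = nodes))
  toy_u <- structure(list(graph = gu, edges = edges_u, candidates = cand,
                          threshold = 0.5), class = "pathway_network")
  res_u <- interaction_enhancement(toy_u)
  expect_true(all(res_u$p == 1))
})
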