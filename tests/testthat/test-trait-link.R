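test_that("trait relevance finds perfect monotone drivers and handles
           degenerate traits", {
  co <- tiny_cohort(seed = 1)
  node <- rownames(co$pci)[5]
  traits <- cbind(drv = exp(co$pci[node, ]),           # monotone, |rho| = 1
                  flat = rep(1, ncol(co$pci)),
                  gone = rep(NA_real_, ncol(co$pci)))
  rownames(traits) <- colnames(co$pci)
  expect_warning(
    trait_relevant(co$pci, traits[, c("drv", "flat")],
                   r_threshold = 0.999),
    "constant or has <3")
  rel <- suppressWarnings(
    trait_relevant(co$pci, traits, r_threshold = 0.999))
  expect_true(node %in% rel$drv)
  expect_identical(rel$flat, character())
  expect_identical(rel$gone, character())
})

test_that("trait-permutation null keeps the false relevance rate near p_cut", {
  co <- tiny_cohort(seed = 6, n_active = 0)
  # traits are pure noise here: anything called relevant is a false call
  rel <- trait_relevant(co$pci, co$traits, p_cut = 0.005, n_perm = 400,
                        seed = 31)
  rate <- sum(lengths(rel)) / (nrow(co$pci) * ncol(co$traits))
  expect_lt(rate, 0.03)
})

test_that("linking classes match their defining rules on a toy graph", {
  # X--A, Y--B relevance; A--B edge; C adjacent to both A and B
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")),
    directed = FALSE)
  relevant <- list(X = "A", Y = "B")
  cls <- classify_linking(relevant, g)
  expect_identical(cls$direct, character(0))
  expect_setequal(cls$path2, c("A", "B"))
  expect_true("C" %in% cls$path3)
  # a node relevant to two traits is direct
  cls2 <- classify_linking(list(X = "A", Y = c("A", "B")), g)
  expect_identical(cls2$direct, "A")
  # empty relevance: all classes empty
  cls0 <- classify_linking(list(X = character(), Y = character()), g)
  expect_identical(lengths(cls0), c(direct = 0L, path2 = 0L, path3 = 0L))
})

test_that("classify_linking equals exhaustive triple enumeration on random
           graphs", {
  for (seed in 1:50) {
    case <- random_linking_case(seed)
    got <- classify_linking(case$relevant, case$graph)
    want <- brute_linking(case$relevant, case$graph)
    expect_identical(lapply(got, sort), want,
                     label = paste("case seed", seed))
  }
})

test_that("assembly keeps only included pathway nodes and typed edges", {
  co <- tiny_cohort(seed = 1)
  net <- build_network(co$pci, co$pathway_db$links, threshold = 0.6)
  traits8 <- colnames(co$traits)
  # empty relevance: eight isolated trait nodes
  empty_rel <- stats::setNames(
    rep(list(character()), length(traits8)), traits8)
  tpn0 <- assemble_network(empty_rel,
                           list(direct = character(), path2 = character(),
                                path3 = character()),
                           net, traits = traits8)
  expect_equal(igraph::vcount(tpn0$graph), 8)
  expect_equal(igraph::ecount(tpn0$graph), 0)
  # bookkeeping: node count = traits + |relevant U linking|
  rel <- trait_relevant(co$pci, co$traits, n_perm = 300, seed = 12)
  linking <- classify_linking(rel, net)
  tpn <- assemble_network(rel, linking, net, traits = traits8,
                          pathway_db = co$pathway_db)
  pw_nodes <- unique(c(unlist(rel), unlist(linking)))
  expect_equal(igraph::vcount(tpn$graph),
               length(traits8) + length(pw_nodes))
  # relevance edges run trait -> relevant node only
  el <- igraph::as_edgelist(tpn$graph)
  ety <- igraph::E(tpn$graph)$type
  for (k in which(ety == "relevance")) {
    tr <- intersect(el[k, ], traits8)
    pw <- setdiff(el[k, ], traits8)
    expect_length(tr, 1)
    expect_true(pw %in% rel[[tr]])
  }
  # coexpression edges only between included nodes present in the net
  for (k in which(ety == "coexpression"))
    expect_true(all(el[k, ] %in% pw_nodes))
})

test_that("refinement drops weakly attached nodes by degree then trait
           distance", {
  mk <- function(edges, pw_nodes, traits) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = c(traits, pw_nodes),
                            type = c(rep("trait", length(traits)),
                                     rep("pathway", length(pw_nodes)))))
    structure(list(graph = g, relevant = list(), linking = list(),
                   traits = traits, refined = FALSE),
              class = "trait_pathway_network")
  }
  # X--A, Y--B, A--B: A at distances (1, 2), degree 2 -> kept; same for B
  tpn <- mk(data.frame(from = c("X", "Y", "A"), to = c("A", "B", "B")),
            c("A", "B"), c("X", "Y"))
  ref <- refine_network(tpn)
  expect_setequal(igraph::V(ref$graph)$name, c("X", "Y", "A", "B"))
  # isolated pathway node and degree-1 pendant are removed
  tpn2 <- mk(data.frame(from = c("X", "Y", "A", "A"),
                        to = c("A", "A", "B", "C")),
             c("A", "B", "C", "Iso"), c("X", "Y"))
  ref2 <- refine_network(tpn2)
  expect_false(any(c("Iso", "B", "C") %in% igraph::V(ref2$graph)$name))
  # a pathway reachable from only one trait fails the two-distance rule
  tpn3 <- mk(data.frame(from = c("X", "X", "A"), to = c("A", "B", "B")),
             c("A", "B"), c("X", "Y"))
  ref3 <- refine_network(tpn3)
  expect_false(any(c("A", "B") %in% igraph::V(ref3$graph)$name))
  expect_true(all(c("X", "Y") %in% igraph::V(ref3$graph)$name))
})

test_that("refinement is monotone-destructive and respects the distance
           budget", {
  co <- tiny_cohort(seed = 1)
  tpn <- trait_pathway_network(co$exprs, co$traits, co$pathway_db,
                               co$gene_network, n_perm = 200,
                               refine = FALSE, seed = 3)
  ref <- refine_network(tpn)
  expect_true(all(igraph::V(ref$graph)$name %in%
                  igraph::V(tpn$graph)$name))
  g <- ref$graph
  pw <- igraph::V(g)$name[igraph::V(g)$type == "pathway"]
  if (length(pw)) {
    expect_true(all(igraph::degree(g)[pw] >= 2))
    d <- igraph::distances(
      g, v = pw, to = igraph::V(g)$name[igraph::V(g)$type == "trait"])
    two <- apply(d, 1, function(x) sum(sort(x)[1:2]))
    expect_true(all(two <= 6))
  }
  # iterative refinement reaches a fixed point contained in the single pass
  it <- refine_network(tpn, iterate = TRUE)
  expect_true(all(igraph::V(it$graph)$name %in% igraph::V(ref$graph)$name))
})

test_that("downstream results are invariant to monotone PCI rescaling", {
  co <- tiny_cohort(seed = 2)
  warp <- co$pci
  warp[] <- warp^3 + 0.1 * warp   # strictly increasing, per-value
  attributes(warp) <- attributes(co$pci)
  net_a <- build_network(co$pci, co$pathway_db$links, threshold = 0.55)
  net_b <- build_network(warp, co$pathway_db$links, threshold = 0.55)
  expect_identical(net_a$edges[, c("from", "to")],
                   net_b$edges[, c("from", "to")])
  expect_equal(net_a$edges$r, net_b$edges$r, tolerance = 1e-12)
  rel_a <- trait_relevant(co$pci, co$traits, r_threshold = 0.55)
  rel_b <- trait_relevant(warp, co$traits, r_threshold = 0.55)
  expect_identical(unclass(rel_a)[], unclass(rel_b)[])
})
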