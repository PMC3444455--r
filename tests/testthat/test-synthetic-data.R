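test_that("pathway database generation honors size, density and seed", {
  db <- generate_pathway_db(20, c(4, 8), 300, link_density = 0.1, seed = 1)
  expect_s3_class(db, "pathway_db")
  expect_length(db$pathways, 20)
  expect_true(all(lengths(db$pathways) >= 4))
  expect_true(all(unlist(db$pathways) %in% db$genes))
  # links are irreflexive and canonically ordered
  expect_true(all(db$links$from < db$links$to))
  # determinism
  db2 <- generate_pathway_db(20, c(4, 8), 300, link_density = 0.1, seed = 1)
  expect_identical(db, db2)
  # boundary: zero density leaves the curated set empty
  db0 <- generate_pathway_db(10, c(4, 8), 200, link_density = 0, seed = 2)
  expect_identical(nrow(db0$links), 0L)
  # parameter errors
  expect_error(generate_pathway_db(1, c(4, 8), 100), "n_pathways")
  expect_error(generate_pathway_db(5, c(1, 8), 100), "size_range")
  expect_error(generate_pathway_db(5, c(4, 8), 100, link_density = 2),
               "link_density")
  expect_error(generate_pathway_db(50, c(10, 10), 100), "disjoint")
})

test_that("gene network respects pathway structure, symmetry and bounds", {
  db <- generate_pathway_db(8, c(4, 6), 120, link_density = 0.1,
                            overlap = 0, seed = 3)
  # within_prob = 1: every within-pathway pair realized, k(k-1)/2 per
  # pathway (cores are disjoint at overlap = 0)
  net <- generate_gene_network(db, within_prob = 1, cross_prob = 0, seed = 4)
  n_within <- sum(lengths(db$pathways) * (lengths(db$pathways) - 1) / 2)
  expect_equal(Matrix::nnzero(net) / 2, n_within)
  expect_identical(as.matrix(net), t(as.matrix(net)))
  expect_true(all(net@x > 0 & net@x <= 1))
  expect_identical(unname(Matrix::diag(net)), rep(0, nrow(net)))
  # cross_prob = 0: all edges connect same-pathway genes
  m <- as(as(net, "generalMatrix"), "TsparseMatrix")
  pw_of <- lapply(db$pathways, identity)
  for (k in which(m@i < m@j)) {
    g1 <- rownames(net)[m@i[k] + 1]; g2 <- rownames(net)[m@j[k] + 1]
    expect_true(any(vapply(pw_of, function(p) g1 %in% p && g2 %in% p, TRUE)))
  }
})

test_that("expression generator plants detectable co-activity", {
  # many animals so sample correlations concentrate
  des <- cohort_design(replicates = 125, tissues = "islet")
  db <- generate_pathway_db(6, c(5, 8), 100, seed = 5)
  gt <- ground_truth(db, des, n_active = 2, tissues = "islet",
                     noise_sd = 0.2, activity_sd = 1, seed = 6)
  ex <- generate_expression(db, des, gt, seed = 7)
  expect_identical(dim(ex$islet), c(100L, 1000L))
  planted <- db$pathways[[gt$active_pathways[[1]][1]]]
  cors <- cor(t(ex$islet[planted, ]))
  expect_gt(mean(cors[upper.tri(cors)]), 0.5)
  # a pathway free of planted activity stays uncorrelated
  free <- setdiff(names(db$pathways),
                  unlist(gt$active_pathways, use.names = FALSE))[1]
  cors0 <- cor(t(ex$islet[db$pathways[[free]], ]))
  expect_lt(max(abs(cors0[upper.tri(cors0)])), 0.2)
  # determinism
  ex2 <- generate_expression(db, des, gt, seed = 7)
  expect_identical(ex, ex2)
})

test_that("null cohorts carry no planted correlation structure", {
  co <- tiny_cohort(seed = 11, n_active = 0)
  expect_identical(nrow(co$ground_truth$trait_effects), 0L)
  m <- co$exprs[[1]]
  cors <- cor(t(m[1:40, ]))
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.05)
})

test_that("traits follow planted PCI drivers", {
  co <- tiny_cohort(seed = 1)
  expect_identical(dim(co$traits), c(40L, 8L))
  expect_identical(rownames(co$traits), co$design$animal)
  eff <- co$ground_truth$trait_effects
  # zero-noise single-driver trait is a monotone function of its PCI row
  gt0 <- co$ground_truth
  gt0$trait_noise_sd <- 1e-12
  tr0 <- generate_traits(co$design, co$pci, gt0, seed = 9)
  k <- 1L
  node <- paste(eff$pathway[k], eff$tissue[k], sep = "|")
  expect_equal(abs(cor(tr0[, eff$trait[k]], co$pci[node, ],
                       method = "spearman")), 1)
  # all effects zero: traits are pure noise, uncorrelated with any PCI
  gt_null <- co$ground_truth
  gt_null$trait_effects <- gt_null$trait_effects[0, ]
  trn <- generate_traits(co$design, co$pci, gt_null, seed = 10)
  expect_lt(abs(cor(trn[, 1], co$pci[node, ])), 0.5)
  # consistency error for unknown driver rows
  gt_bad <- co$ground_truth
  gt_bad$trait_effects$pathway[1] <- "pw99"
  expect_error(generate_traits(co$design, co$pci, gt_bad), "absent")
})

test_that("fixtures round-trip through their interchange formats", {
  co <- tiny_cohort(seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, dir)
  expect_identical(length(readLines(paths[["gmt"]])),
                   length(co$pathway_db$pathways))
  back <- read_fixture(dir)
  expect_identical(back$pathway_db$pathways, co$pathway_db$pathways)
  expect_identical(back$pathway_db$links, co$pathway_db$links)
  expect_identical(back$pathway_db$categories, co$pathway_db$categories)
  expect_equal(as.matrix(back$gene_network), as.matrix(co$gene_network))
  expect_equal(back$exprs, co$exprs, tolerance = 1e-12)
  expect_equal(back$traits, co$traits, tolerance = 1e-12)
  expect_identical(back$design$animal, co$design$animal)
  expect_identical(design_tissues(back$design), design_tissues(co$design))
  gt <- back$ground_truth
  expect_identical(gt$active_pathways, co$ground_truth$active_pathways)
  expect_equal(gt$noise_sd, co$ground_truth$noise_sd)
  expect_identical(gt$trait_effects$pathway,
                   co$ground_truth$trait_effects$pathway)
  # PCI recomputed from the round-tripped inputs matches
  pci2 <- pci_matrix(back$exprs, back$pathway_db, back$gene_network)
  expect_equal(unclass(pci2)[, ], unclass(co$pci)[, ], tolerance = 1e-9)
})
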