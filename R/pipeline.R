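#' Construct a cross-tissue trait-pathway network
#'
#' End-to-end driver: scores every pathway in every tissue and animal with
#' the PCI ([pci_matrix()]), calibrates the co-expression threshold by
#' gene-label permutation ([permutation_null()], [threshold_for_p()]),
#' builds the curation-gated pathway coordination network
#' ([build_network()]), identifies trait-relevant pathways
#' ([trait_relevant()]), classifies direct/path2/path3 trait-linking
#' pathways ([classify_linking()]), and assembles (and by default refines)
#' the merged trait-pathway network.
#'
#' Passing `animal_subset` (e.g. the five animals of one group) yields a
#' group-specific network: z-scoring, the permutation null and all
#' correlations are then computed within the subset, which drives the
#' calibrated threshold up (around `|r| > 0.7` at p < 0.005 for n = 5
#' versus `|r| > 0.4` for n = 40 in the emulated study).
#'
#' @param exprs named list tissue -> expression matrix (genes x animals,
#'   log-ratio values).
#' @param traits numeric matrix animals x traits.
#' @param pathway_db a [pathway_db()].
#' @param gene_network symmetric gene-gene link-probability matrix.
#' @param p_cut empirical p-value threshold for both the co-expression and
#'   the trait-relevance calls (default 0.005).
#' @param n_perm permutation rounds for both nulls (default 1000).
#' @param animal_subset optional character vector of animal ids.
#' @param r_threshold optional fixed co-expression `|r|` threshold
#'   (skips the expression permutation null).
#' @param trait_r_threshold optional fixed trait-relevance `|r|` threshold.
#' @param refine apply [refine_network()] (default TRUE).
#' @param max_trait_distance passed to [refine_network()].
#' @param include_diagonal,normalization passed to [pci_matrix()].
#' @param seed RNG seed covering both permutation nulls.
#' @return A `trait_pathway_network` whose fields include the assembled
#'   `graph`, `relevant`, `linking`, plus `pci`, `pathway_network`,
#'   `null`, `r_threshold`, `p_cut`, `n_perm`.
#' @examples
#' co <- synthesize_cohort(n_pathways = 12, n_genes = 150,
#'                         size_range = c(4, 8), seed = 1)
#' tpn <- trait_pathway_network(co$exprs, co$traits, co$pathway_db,
#'                              co$gene_network, n_perm = 50, seed = 1)
#' print(tpn)
#' @export
trait_pathway_network <- function(exprs, traits, pathway_db, gene_network,
                                  p_cut = 0.005, n_perm = 1000L,
                                  animal_subset = NULL, r_threshold = NULL,
                                  trait_r_threshold = NULL, refine = TRUE,
                                  max_trait_distance = 6,
                                  include_diagonal = TRUE,
                                  normalization = c("size", "pairs"),
                                  seed = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(p_cut > 0, p_cut < 1)
  if (!is.null(animal_subset)) {
    exprs <- lapply(exprs, function(m) m[, animal_subset, drop = FALSE])
    traits <- traits[intersect(rownames(traits), animal_subset), ,
                     drop = FALSE]
  }
  with_seed(seed, {
    pci <- pci_matrix(exprs, pathway_db, gene_network,
                      include_diagonal = include_diagonal,
                      normalization = normalization)
    null <- NULL
    if (is.null(r_threshold)) {
      null <- permutation_null(exprs, pathway_db, gene_network,
                               n_perm = n_perm,
                               include_diagonal = include_diagonal,
                               normalization = normalization)
      r_threshold <- threshold_for_p(null, p_cut)
    }
    net <- build_network(pci, pathway_db$links, threshold = r_threshold,
                         null = null)
    relevant <- trait_relevant(pci, traits, p_cut = p_cut, n_perm = n_perm,
                               r_threshold = trait_r_threshold)
    linking <- classify_linking(relevant, net)
    tpn <- assemble_network(relevant, linking, net,
                            traits = colnames(traits),
                            pathway_db = pathway_db)
    if (refine)
      tpn <- refine_network(tpn, max_trait_distance = max_trait_distance)
    tpn$pci <- pci
    tpn$pathway_network <- net
    tpn$null <- null
    tpn$r_threshold <- r_threshold
    tpn$p_cut <- p_cut
    tpn$n_perm <- n_perm
    tpn
  })
}

#' @export
print.trait_pathway_network <- function(x, ...) {
  g <- x$graph
  n_tr <- sum(V(g)$type == "trait")
  n_pw <- sum(V(g)$type == "pathway")
  cat("trait_pathway_network",
      if (isTRUE(x$refined)) "(refined)" else "(unrefined)", "\n")
  cat(sprintf("  %d trait nodes, %d (pathway, tissue) nodes, %d edges\n",
              n_tr, n_pw, ecount(g)))
  if (!is.null(x$r_threshold))
    cat(sprintf("  co-expression threshold |r| >= %.3f (p < %g)\n",
                x$r_threshold, x$p_cut %||% NA))
  cat(sprintf("  linking pathways: %d direct, %d path2, %d path3\n",
              length(x$linking$direct), length(x$linking$path2),
              length(x$linking$path3)))
  invisible(x)
}

#' @export
summary.trait_pathway_network <- function(object, ...) {
  g <- object$graph
  pw <- V(g)$type == "pathway"
  per_tissue <- table(V(g)$tissue[pw])
  deg <- degree(g)[pw]
  rel_counts <- lengths(object$relevant)
  out <- list(
    n_trait_nodes = sum(V(g)$type == "trait"),
    n_pathway_nodes = sum(pw),
    n_edges = ecount(g),
    n_coexpression = if (ecount(g))
      sum(E(g)$type == "coexpression") else 0L,
    n_relevance = if (ecount(g)) sum(E(g)$type == "relevance") else 0L,
    pathway_nodes_per_tissue = per_tissue,
    relevant_per_trait = rel_counts,
    linking_counts = lengths(object$linking),
    top_degree = utils::head(sort(deg, decreasing = TRUE), 10))
  class(out) <- "summary.trait_pathway_network"
  out
}

#' @export
print.summary.trait_pathway_network <- function(x, ...) {
  cat(sprintf("Nodes: %d traits + %d (pathway, tissue); edges: %d (%d coexpression, %d relevance)\n",
              x$n_trait_nodes, x$n_pathway_nodes, x$n_edges,
              x$n_coexpression, x$n_relevance))
  cat("Pathway nodes per tissue:\n"); print(x$pathway_nodes_per_tissue)
  cat("Relevant pathways per trait:\n"); print(x$relevant_per_trait)
  cat("Linking classes:\n"); print(x$linking_counts)
  cat("Top degrees:\n"); print(x$top_degree)
  invisible(x)
}

#' Plot a trait-pathway network
#'
#' Traits are drawn as squares, (pathway, tissue) nodes as circles colored
#' by tissue; relevance edges are dashed.
#'
#' @param x a `trait_pathway_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.trait_pathway_network <- function(x, ...) {
  g <- x$graph
  is_trait <- V(g)$type == "trait"
  tissues <- sort(unique(stats::na.omit(V(g)$tissue)))
  pal <- grDevices::hcl.colors(max(3L, length(tissues)), "Dark 3")
  col <- ifelse(is_trait, "grey20",
                pal[match(V(g)$tissue, tissues)])
  shape <- ifelse(is_trait, "square", "circle")
  lty <- if (ecount(g)) ifelse(E(g)$type == "relevance", 2L, 1L) else 1L
  plot(g, vertex.shape = shape, vertex.color = col,
       vertex.size = ifelse(is_trait, 9, 5),
       vertex.label = ifelse(is_trait, V(g)$name, NA),
       vertex.label.color = "black", edge.lty = lty, ...)
  invisible(x)
}

#' Group-specific trait-pathway analyses
#'
#' Runs [trait_relevant()] (and optionally the full network build) within
#' each animal group of a cohort design, re-normalizing expression inside
#' the group so each network is self-contained.
#'
#' @inheritParams trait_pathway_network
#' @param design a [cohort_design()] identifying the groups.
#' @param r_threshold fixed co-expression threshold used for every group
#'   network (default 0.7, the calibrated group-level threshold of the
#'   emulated study); set to `NULL` to recalibrate per group by
#'   permutation.
#' @return Named list group -> list with `relevant` and (if
#'   `build_networks`) `network`.
#' @param build_networks also build each group's coordination network.
#' @export
group_analysis <- function(exprs, traits, pathway_db, gene_network, design,
                           p_cut = 0.005, n_perm = 1000L,
                           r_threshold = 0.7, trait_r_threshold = NULL,
                           build_networks = FALSE, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- unique(design$group)
  with_seed(seed, {
    out <- stats::setNames(vector("list", length(groups)), groups)
    for (g in groups) {
      animals <- design$animal[design$group == g]
      ex <- lapply(exprs, function(m) m[, animals, drop = FALSE])
      pci <- pci_matrix(ex, pathway_db, gene_network)
      thr <- r_threshold
      null <- NULL
      if (is.null(thr)) {
        null <- permutation_null(ex, pathway_db, gene_network,
                                 n_perm = n_perm)
        thr <- threshold_for_p(null, p_cut)
      }
      rel <- trait_relevant(pci, traits[animals, , drop = FALSE],
                            p_cut = p_cut, n_perm = n_perm,
                            r_threshold = trait_r_threshold)
      res <- list(relevant = rel)
      if (build_networks)
        res$network <- build_network(pci, pathway_db$links,
                                     threshold = thr, null = null)
      out[[g]] <- res
    }
    out
  })
}
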