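#' Log-binned degree histogram
#'
#' Natural-log-transforms the degrees of all nodes with degree >= 1 and
#' allocates them into `n_bins` evenly spaced bins between the minimum and
#' maximum log-degree.  Bins are half-open `[lo, hi)` with the last bin
#' closed, so counts are conserved.  Intended to be plotted as ln(count)
#' against the bin center (zero-count bins omitted), the representation in
#' which a power-law regime appears linear.
#'
#' @param net a network container or igraph.
#' @param n_bins number of bins (default 10).
#' @return Data frame of class `degree_histogram` with columns `center`
#'   (bin center on the ln-degree scale), `count`, and `ln_count` (`NA`
#'   for empty bins).
#' @export
degree_histogram <- function(net, n_bins = 10L) {
  g <- as_cp_graph(net)
  deg <- degree(g)
  deg <- deg[deg >= 1]
  if (!length(deg)) stop("no node has degree >= 1")
  ld <- log(deg)
  lo <- min(ld); hi <- max(ld)
  if (lo == hi) {
    out <- data.frame(center = lo, count = length(ld),
                      ln_count = log(length(ld)))
    class(out) <- c("degree_histogram", "data.frame")
    return(out)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(ld, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  out <- data.frame(center = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                    count = counts,
                    ln_count = ifelse(counts > 0, log(counts), NA_real_))
  class(out) <- c("degree_histogram", "data.frame")
  out
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Unnormalized betweenness of every node in an undirected, unweighted
#' graph: the number of shortest paths between all other node pairs
#' passing through the node, counting each unordered pair once, excluding
#' the endpoints, and splitting geodesic ties fractionally.  Computed with
#' Brandes' algorithm as implemented in igraph.
#'
#' @param net a network container or igraph.
#' @return Named numeric vector of betweenness scores, sorted decreasing.
#' @export
betweenness_centrality <- function(net) {
  g <- as_cp_graph(net)
  b <- betweenness(g, directed = FALSE, weights = NA)
  sort(b, decreasing = TRUE)
}

# MCODE vertex weights: for each vertex, take the subgraph induced by its
# closed neighborhood, find its highest k-core, and weight the vertex by
# (core number) x (density of that core).
.mcode_weights <- function(g) {
  n <- vcount(g)
  w <- numeric(n)
  adj <- adjacent_vertices(g, V(g))
  for (v in seq_len(n)) {
    nb <- c(v, as.integer(adj[[v]]))
    if (length(nb) < 2) next
    sub <- induced_subgraph(g, nb)
    core <- coreness(sub)
    kmax <- max(core)
    core_sub <- induced_subgraph(sub, which(core == kmax))
    w[v] <- kmax * edge_density(core_sub)
  }
  names(w) <- V(g)$name
  w
}

#' Densely connected subregions (MCODE)
#'
#' Reimplementation of the MCODE seed-and-grow procedure: vertices are
#' weighted by their core-clustering coefficient (highest k-core number of
#' the closed-neighborhood subgraph times that core's density); complexes
#' grow outward from the highest-weight unvisited seed, including
#' neighbors whose weight is at least `(1 - vwp)` times the seed weight;
#' optional post-processing *fluffs* complexes with dense-neighborhood
#' boundary vertices and *haircuts* singly-connected members (repeatedly,
#' so every reported member has within-cluster degree >= 2).  Clusters are
#' ranked by score = density x size.
#'
#' @param net a network container or igraph (treated as simple and
#'   undirected).
#' @param vwp vertex weight percentage in `[0, 1]` (default 0.2, the
#'   plug-in's published default).
#' @param haircut remove singly-connected cluster members (default TRUE).
#' @param fluff expand clusters with neighbors whose closed-neighborhood
#'   density exceeds `fluff_density` (default FALSE).
#' @param fluff_density density cutoff for fluffing (default 0.5).
#' @return List of clusters, each a list with `nodes`, `n_nodes`,
#'   `n_edges`, `density`, `score`, ordered by decreasing score.
#' @export
dense_subregions <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                             fluff_density = 0.5) {
  g <- as_cp_graph(net)
  g <- simplify(as_undirected(g, mode = "collapse"))
  n <- vcount(g)
  if (n == 0) return(list())
  w <- .mcode_weights(g)
  visited <- rep(FALSE, n)
  adj <- adjacent_vertices(g, V(g))
  clusters <- list()
  for (seed in order(w, decreasing = TRUE)) {
    if (visited[seed] || w[seed] == 0) next
    cutoff <- (1 - vwp) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!visited[u] && w[u] >= cutoff) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (length(members) < 2) next
    if (fluff) {
      boundary <- setdiff(unique(unlist(lapply(members, function(v)
        as.integer(adj[[v]])))), members)
      for (u in boundary) {
        nb <- c(u, as.integer(adj[[u]]))
        if (edge_density(induced_subgraph(g, nb)) > fluff_density)
          members <- c(members, u)
      }
    }
    if (haircut) {
      repeat {
        sub <- induced_subgraph(g, members)
        low <- degree(sub) < 2
        if (!any(low)) break
        members <- members[!low]
        if (length(members) < 3) { members <- integer(); break }
      }
    }
    if (length(members) < 2) next
    sub <- induced_subgraph(g, members)
    dens <- edge_density(sub)
    clusters[[length(clusters) + 1L]] <- list(
      nodes = sort(V(g)$name[members]),
      n_nodes = length(members), n_edges = ecount(sub),
      density = dens, score = dens * length(members))
  }
  clusters[order(vapply(clusters, `[[`, 0, "score"), decreasing = TRUE)]
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability for the table `[[a, b], [c, d]]`:
#' one-sided (`greater` = over-representation of `a`, `less` =
#' under-representation), or two-sided by the point-probability rule.
#' An all-zero table returns p = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param side `"greater"`, `"less"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' fisher_2x2(3, 1, 1, 3, "greater")  # 17/70
#' @export
fisher_2x2 <- function(a, b, c, d, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1)
  fisher.test(matrix(c(a, c, b, d), 2L), alternative = side)$p.value
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: `q_i = min_{j: p_j >= p_i} (m * p_j / rank_j)`,
#' capped at 1 and order-preserving.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) p.adjust(pvals, method = "BH")

#' Category representation in the trait-pathway network
#'
#' For every (pathway category, tissue) cluster, tests whether (pathway,
#' tissue) nodes of that category and tissue are over- or under-represented
#' among the network's pathway nodes relative to a universe of candidate
#' nodes, with Fisher's exact test.  Both one-sided p-values are reported.
#'
#' @param tpn a `trait_pathway_network` (or `pathway_network`).
#' @param pathway_db a [pathway_db()] supplying category labels.
#' @param tissues tissue labels spanning the universe; defaults to the
#'   tissues present among the network's nodes.
#' @param universe optional character vector of `"pathway|tissue"` node
#'   names to use as the universe; defaults to all pathways x `tissues`.
#' @return Data frame (`category`, `tissue`, `in_network`, `in_universe`,
#'   `over_p`, `under_p`) sorted by `over_p`.
#' @export
category_representation <- function(tpn, pathway_db, tissues = NULL,
                                    universe = NULL) {
  stopifnot(inherits(pathway_db, "pathway_db"))
  g <- as_cp_graph(tpn)
  if ("type" %in% vertex_attr_names(g)) {
    net_nodes <- V(g)$name[V(g)$type == "pathway"]
  } else net_nodes <- V(g)$name
  net_info <- split_nodes(net_nodes)
  tissues <- tissues %||% sort(unique(net_info$tissue))
  if (is.null(universe))
    universe <- as.vector(outer(names(pathway_db$pathways), tissues,
                                node_name))
  uni <- split_nodes(universe)
  bad <- setdiff(uni$pathway, names(pathway_db$categories))
  if (length(bad)) stop("universe references pathways with unknown ",
                        "category: ", paste(utils::head(bad, 5),
                                            collapse = ", "))
  uni$category <- unname(pathway_db$categories[uni$pathway])
  uni$in_net <- uni$node %in% net_nodes
  combos <- expand.grid(category = sort(unique(uni$category)),
                        tissue = tissues, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(k) {
    in_ct <- uni$category == combos$category[k] &
      uni$tissue == combos$tissue[k]
    a <- sum(in_ct & uni$in_net)
    b <- sum(!in_ct & uni$in_net)
    c_ <- sum(in_ct & !uni$in_net)
    d <- sum(!in_ct & !uni$in_net)
    data.frame(category = combos$category[k], tissue = combos$tissue[k],
               in_network = a, in_universe = sum(in_ct),
               over_p = fisher_2x2(a, b, c_, d, "greater"),
               under_p = fisher_2x2(a, b, c_, d, "less"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[order(res$over_p), ]
}

#' Interaction enhancement relative to curated opportunities
#'
#' Tests, per (pathway, tissue) node, whether the expression data realized
#' significantly more of the node's candidate interactions (curated pairs
#' plus cross-tissue self pairs) than expected from the network-wide
#' realization rate: Fisher's exact test on
#' `[[k_v, O_v - k_v], [K - k_v, (O - O_v) - (K - k_v)]]` with `k_v` the
#' node degree, `O_v` its candidate opportunities, and `K`, `O` the network
#' totals; one-sided (greater), BH-adjusted.  Nodes with no opportunities
#' are skipped.
#'
#' @param net a [build_network()] result (its stored candidate set defines
#'   the opportunities).
#' @return Data frame (`node`, `tissue`, `pathway`, `degree`,
#'   `opportunities`, `p`, `fdr`) sorted by `p`.
#' @export
interaction_enhancement <- function(net) {
  stopifnot(inherits(net, "pathway_network"))
  nodes <- V(net$graph)$name
  k <- degree(net$graph)[nodes]
  opp <- table(factor(c(net$candidates$from, net$candidates$to),
                      levels = nodes))
  O_v <- as.integer(opp)
  K <- nrow(net$edges)
  O <- nrow(net$candidates)
  keep <- O_v > 0
  res <- data.frame(node = nodes[keep], stringsAsFactors = FALSE)
  info <- split_nodes(res$node)
  res$tissue <- info$tissue
  res$pathway <- info$pathway
  res$degree <- as.integer(k[keep])
  res$opportunities <- O_v[keep]
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    kv <- res$degree[i]; ov <- res$opportunities[i]
    fisher_2x2(kv, ov - kv, K - kv, (O - ov) - (K - kv), "greater")
  }, 0)
  res$fdr <- bh_fdr(res$p)
  res[order(res$p), ]
}
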