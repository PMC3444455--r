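#' Trait-relevant pathways
#'
#' A (pathway, tissue) node is relevant to a trait when the absolute
#' Spearman correlation between its PCI row and the trait values across
#' animals is significant against an empirical null built by permuting the
#' animal labels of the trait vector (`n_perm` rounds, pooled over all
#' nodes), at `p_cut`.  Alternatively a fixed correlation threshold can be
#' supplied.  Missing trait values are dropped pairwise; a trait constant
#' across animals (or with fewer than 3 observations) yields an empty
#' relevant set with a warning.
#'
#' @param pci a [pci_matrix()].
#' @param traits numeric matrix animals x traits (missing values allowed);
#'   row names must match PCI animal columns.
#' @param p_cut empirical p-value cutoff (default 0.005).
#' @param n_perm trait-permutation rounds for the null (default 1000).
#' @param r_threshold optional fixed `|r|` threshold replacing the
#'   permutation null.
#' @param seed optional RNG seed.
#' @return Named list trait -> character vector of relevant node names,
#'   with attribute `details`: a data frame (`trait`, `node`, `r`, `p`)
#'   for all significant pairs.
#' @export
trait_relevant <- function(pci, traits, p_cut = 0.005, n_perm = 1000L,
                           r_threshold = NULL, seed = NULL) {
  stopifnot(is.matrix(pci), is.matrix(traits) || is.data.frame(traits))
  traits <- as.matrix(traits)
  animals <- intersect(colnames(pci), rownames(traits))
  if (length(animals) < 3)
    stop("need at least 3 animals with both PCI and trait values")
  pci <- pci[, animals, drop = FALSE]
  traits <- traits[animals, , drop = FALSE]
  out <- vector("list", ncol(traits))
  names(out) <- colnames(traits)
  details <- list()
  with_seed(seed, {
    for (tr in colnames(traits)) {
      y <- traits[, tr]
      ok <- !is.na(y)
      if (sum(ok) < 3 || sd(y[ok]) == 0) {
        warning("trait '", tr, "' is constant or has <3 observations; ",
                "empty relevant set")
        out[[tr]] <- character()
        next
      }
      Z <- .rank_standardize(pci[, ok, drop = FALSE])
      ry <- rank(y[ok], ties.method = "average")
      ry <- (ry - mean(ry))
      ry <- ry / sqrt(sum(ry^2))
      r_obs <- as.vector(Z %*% ry)
      if (!is.null(r_threshold)) {
        sig <- abs(r_obs) >= r_threshold
        p <- rep(NA_real_, length(r_obs))
      } else {
        perms <- replicate(n_perm, sample(ry))
        null_r <- abs(Z %*% perms)           # nodes x n_perm
        nv <- sort(as.vector(null_r))
        M <- length(nv)
        n_ge <- M - findInterval(abs(r_obs), nv, left.open = TRUE)
        p <- (1 + n_ge) / (1 + M)
        sig <- p < p_cut
      }
      out[[tr]] <- rownames(pci)[sig]
      if (any(sig))
        details[[tr]] <- data.frame(trait = tr, node = rownames(pci)[sig],
                                    r = r_obs[sig], p = p[sig],
                                    stringsAsFactors = FALSE)
    }
  })
  details <- if (length(details)) do.call(rbind, c(details,
                                                   make.row.names = FALSE))
  else data.frame(trait = character(), node = character(),
                  r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  structure(out, details = details)
}

# trait sets per node: named list node -> character vector of traits
.node_traits <- function(relevant, nodes) {
  tv <- stats::setNames(vector("list", length(nodes)), nodes)
  for (tr in names(relevant))
    for (v in relevant[[tr]]) tv[[v]] <- c(tv[[v]], tr)
  tv
}

#' Classify trait-linking pathways
#'
#' A (pathway, tissue) node links two traits when it satisfies at least one
#' of three rules: **direct** -- relevant to two or more traits;
#' **path2** -- relevant to at least one trait and adjacent (in the pathway
#' coordination network) to a node relevant to some trait it is not itself
#' relevant to; **path3** -- adjacent to nodes whose combined relevance
#' covers two or more distinct traits (the node itself need not be relevant
#' to any).  A node receives every class it satisfies.
#'
#' @param relevant named list trait -> relevant node names (from
#'   [trait_relevant()]).
#' @param net a [build_network()] result (or an igraph).
#' @return List with character-vector elements `direct`, `path2`, `path3`.
#' @export
classify_linking <- function(relevant, net) {
  g <- as_cp_graph(net)
  nodes <- sort(unique(c(V(g)$name, unlist(relevant, use.names = FALSE))))
  tv <- .node_traits(relevant, nodes)
  in_graph <- nodes %in% V(g)$name
  nbrs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes[in_graph])
    nbrs[[v]] <- names(neighbors(g, v))
  direct <- nodes[vapply(tv, function(s) length(s) >= 2, TRUE)]
  path2 <- character(); path3 <- character()
  for (v in nodes) {
    nbr_traits <- unique(unlist(tv[nbrs[[v]]], use.names = FALSE))
    if (length(tv[[v]]) >= 1 &&
        length(setdiff(nbr_traits, tv[[v]])) >= 1)
      path2 <- c(path2, v)
    if (length(nbr_traits) >= 2)
      path3 <- c(path3, v)
  }
  list(direct = direct, path2 = path2, path3 = path3)
}

#' Assemble the merged trait-pathway network
#'
#' Joins trait nodes and the trait-relevant plus trait-linking (pathway,
#' tissue) nodes into one graph: co-expression edges are the coordination
#' network's edges restricted to the included pathway nodes, and a
#' relevance edge connects each trait to each of its relevant pathways.
#'
#' @inheritParams classify_linking
#' @param linking result of [classify_linking()].
#' @param traits character vector of trait names (defaults to
#'   `names(relevant)`).
#' @param pathway_db optional [pathway_db()] used to attach pathway
#'   category labels to nodes.
#' @return Object of class `trait_pathway_network`: `graph` (igraph with
#'   vertex attributes `type`, `pathway`, `tissue`, `category`, `linking`),
#'   `relevant`, `linking`, `traits`, `refined = FALSE`.
#' @export
assemble_network <- function(relevant, linking, net,
                             traits = names(relevant), pathway_db = NULL) {
  g0 <- as_cp_graph(net)
  pw_nodes <- sort(unique(c(unlist(relevant, use.names = FALSE),
                            unlist(linking, use.names = FALSE))))
  coexp <- induced_subgraph(g0, intersect(V(g0)$name, pw_nodes))
  rel_list <- Filter(Negate(is.null), lapply(names(relevant), function(tr) {
    if (!length(relevant[[tr]])) return(NULL)
    data.frame(from = tr, to = relevant[[tr]], stringsAsFactors = FALSE)
  }))
  rel_edges <- if (length(rel_list)) do.call(rbind, rel_list) else NULL
  edges <- data.frame(from = character(), to = character(),
                      type = character(), stringsAsFactors = FALSE)
  el <- as_edgelist(coexp)
  if (nrow(el))
    edges <- rbind(edges, data.frame(from = el[, 1], to = el[, 2],
                                     type = "coexpression",
                                     stringsAsFactors = FALSE))
  if (!is.null(rel_edges) && nrow(rel_edges))
    edges <- rbind(edges, data.frame(rel_edges, type = "relevance",
                                     stringsAsFactors = FALSE))
  info <- split_nodes(pw_nodes)
  linking_label <- vapply(pw_nodes, function(v) {
    cls <- names(linking)[vapply(linking, function(s) v %in% s, TRUE)]
    if (length(cls)) paste(cls, collapse = ",") else "relevant-only"
  }, "")
  vert <- data.frame(
    name = c(traits, pw_nodes),
    type = c(rep("trait", length(traits)), rep("pathway", length(pw_nodes))),
    pathway = c(rep(NA_character_, length(traits)), info$pathway),
    tissue = c(rep(NA_character_, length(traits)), info$tissue),
    linking = c(rep(NA_character_, length(traits)), linking_label),
    stringsAsFactors = FALSE)
  vert$category <- NA_character_
  if (!is.null(pathway_db)) {
    hit <- !is.na(vert$pathway) & vert$pathway %in% names(pathway_db$categories)
    vert$category[hit] <- unname(pathway_db$categories[vert$pathway[hit]])
  }
  g <- graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  structure(list(graph = g, relevant = relevant, linking = linking,
                 traits = traits, refined = FALSE),
            class = "trait_pathway_network")
}

#' Refine a trait-pathway network
#'
#' Single-pass pruning that focuses the network on interactive,
#' trait-proximal pathways: first every pathway node of total degree 0 or 1
#' is removed; then, on the remaining graph, each pathway node whose
#' unweighted shortest-path distances to its two nearest trait nodes sum to
#' more than `max_trait_distance` is removed (an unreachable trait counts
#' as infinite, so nodes reachable from fewer than two traits are always
#' dropped).  Trait nodes are never removed.  With `iterate = TRUE` the two
#' filters are reapplied until a fixed point.
#'
#' @param tpn a [assemble_network()] result.
#' @param max_trait_distance cutoff on the sum of the two nearest trait
#'   distances (default 6).
#' @param iterate repeat until no node is removed (default FALSE).
#' @return The refined `trait_pathway_network` (`refined = TRUE`); the node
#'   set is always a subset of the input's.
#' @export
refine_network <- function(tpn, max_trait_distance = 6, iterate = FALSE) {
  stopifnot(inherits(tpn, "trait_pathway_network"))
  g <- tpn$graph
  repeat {
    removed <- 0L
    is_pw <- V(g)$type == "pathway"
    drop1 <- V(g)$name[is_pw & degree(g) <= 1]
    if (length(drop1)) {
      g <- delete_vertices(g, drop1)
      removed <- removed + length(drop1)
    }
    is_pw <- V(g)$type == "pathway"
    trait_v <- V(g)$name[V(g)$type == "trait"]
    pw_v <- V(g)$name[is_pw]
    if (length(pw_v) && length(trait_v)) {
      d <- distances(g, v = pw_v, to = trait_v)
      two_sum <- apply(d, 1L, function(x) sum(sort(x)[1:2]))
      two_sum[is.na(two_sum)] <- Inf  # fewer than 2 traits in the graph
      drop2 <- pw_v[two_sum > max_trait_distance]
    } else drop2 <- pw_v
    if (length(drop2)) {
      g <- delete_vertices(g, drop2)
      removed <- removed + length(drop2)
    }
    if (!iterate || removed == 0L) break
  }
  tpn$graph <- g
  tpn$refined <- TRUE
  tpn
}

# Extract the underlying igraph from any network container used here.
as_cp_graph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  if (inherits(x, c("pathway_network", "trait_pathway_network")))
    return(x$graph)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a graph")
}
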