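#' Add margin totals to a trait x tissue linking-count table
#'
#' Prepends a `Total` column (row sums over tissues) and appends a
#' `"Total each tissue"` row (column sums, with the grand total in the
#' `Total` column), the layout used to summarize where trait-linking
#' pathways sit across tissues.
#'
#' @param counts numeric matrix or data frame, traits x tissues.
#' @return Data frame with the `Total` column and total row added.
#' @export
linking_distribution_table <- function(counts) {
  counts <- as.matrix(counts)
  out <- cbind(Total = rowSums(counts), counts)
  out <- rbind(out, "Total each tissue" = colSums(out))
  as.data.frame(out)
}

#' Distribution of trait-linking pathways across tissues
#'
#' Counts, for every trait and tissue, the linking pathway nodes of that
#' tissue attached to the trait: a linking node counts for trait X when it
#' is itself relevant to X or is adjacent (via a co-expression edge) to a
#' node relevant to X -- the ways a node can participate in a linking rule
#' for X.  Only nodes still present in the (typically refined) network are
#' counted.
#'
#' @param tpn a `trait_pathway_network`.
#' @return Data frame in the layout of [linking_distribution_table()].
#' @export
trait_tissue_distribution <- function(tpn) {
  stopifnot(inherits(tpn, "trait_pathway_network"))
  g <- tpn$graph
  present <- V(g)$name
  link_nodes <- intersect(
    sort(unique(unlist(tpn$linking, use.names = FALSE))), present)
  tissues <- sort(unique(V(g)$tissue[V(g)$type == "pathway"]))
  traits <- tpn$traits
  counts <- matrix(0L, nrow = length(traits), ncol = length(tissues),
                   dimnames = list(traits, tissues))
  tv <- .node_traits(lapply(tpn$relevant, intersect, present), present)
  for (v in link_nodes) {
    nb <- names(neighbors(g, v))
    nb <- nb[nb %in% present & !(nb %in% traits)]
    covered <- unique(c(tv[[v]], unlist(tv[nb], use.names = FALSE)))
    covered <- intersect(covered, traits)
    tt <- V(g)$tissue[match(v, V(g)$name)]
    if (length(covered))
      counts[covered, tt] <- counts[covered, tt] + 1L
  }
  linking_distribution_table(counts)
}

#' Add the mean row to a trait x group relevant-pathway count table
#'
#' Appends a `Mean` row holding the arithmetic mean of the trait rows per
#' group column, rounded to one decimal.
#'
#' @param counts numeric matrix or data frame, traits x animal groups.
#' @return Data frame with the `Mean` row appended.
#' @export
group_count_table <- function(counts) {
  counts <- as.matrix(counts)
  out <- rbind(counts, Mean = round(colMeans(counts), 1))
  as.data.frame(out)
}

#' Per-group trait-relevant pathway counts
#'
#' Tabulates, for each animal group's network, how many pathways are
#' relevant to each trait, with the per-group mean appended.
#'
#' @param group_relevant named list: group label -> [trait_relevant()]
#'   result (list trait -> node names).
#' @return Data frame traits x groups in the layout of
#'   [group_count_table()].
#' @export
group_relevance_counts <- function(group_relevant) {
  stopifnot(is.list(group_relevant), length(group_relevant) >= 1)
  traits <- names(group_relevant[[1]])
  counts <- vapply(group_relevant, function(rel)
    lengths(rel)[traits], integer(length(traits)))
  rownames(counts) <- traits
  group_count_table(counts)
}

#' Per-trait relevant and linking pathway report
#'
#' Long-format table of every (trait, pathway, tissue) attachment in the
#' network, with the node's linking classes.
#'
#' @param tpn a `trait_pathway_network`.
#' @return Data frame (`trait`, `node`, `pathway`, `tissue`, `linking`).
#' @export
trait_pathway_table <- function(tpn) {
  stopifnot(inherits(tpn, "trait_pathway_network"))
  present <- V(tpn$graph)$name
  rows <- lapply(names(tpn$relevant), function(tr) {
    nodes <- intersect(tpn$relevant[[tr]], present)
    if (!length(nodes)) return(NULL)
    info <- split_nodes(nodes)
    data.frame(trait = tr, node = nodes, pathway = info$pathway,
               tissue = info$tissue,
               linking = V(tpn$graph)$linking[match(nodes, present)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trait = character(), node = character(),
                      pathway = character(), tissue = character(),
                      linking = character(), stringsAsFactors = FALSE)
  out[order(out$trait, out$node), ]
}
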