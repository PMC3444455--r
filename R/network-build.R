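#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), the
#' correlation index used throughout the pathway co-expression machinery.
#' A constant vector leaves the coefficient undefined; it is returned as 0
#' with attribute `undefined = TRUE` so downstream thresholding treats the
#' pair as uncorrelated.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @return Correlation in `[-1, 1]`, with attribute `undefined`.
#' @examples
#' spearman_cor(1:5, c(5, 4, 3, 2, 1))  # -1
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(0, undefined = TRUE))
  structure(unname(cor(x, y, method = "spearman")), undefined = FALSE)
}

# Rank rows of a matrix and standardize each to mean 0, unit sum of
# squares, so pairwise Spearman correlations are plain inner products.
# Constant rows become all-zero (Spearman treated as 0).
.rank_standardize <- function(m) {
  r <- t(apply(m, 1L, rank, ties.method = "average"))
  if (ncol(m) == 1L) r <- t(r)  # apply() drops dims for single column
  r <- r - rowMeans(r)
  ss <- sqrt(rowSums(r^2))
  ss[ss == 0] <- Inf
  r / ss
}

# Candidate node pairs of the coordination network: curated pathway pairs
# across any tissue combination (including the same tissue), plus the same
# pathway across two different tissues.  `nodes` is a data.frame from
# split_nodes(); returns a list(i, j, type) of row indices into `nodes`.
candidate_pairs <- function(nodes, links) {
  rows_by_pw <- split(seq_len(nrow(nodes)), nodes$pathway)
  ii <- integer(); jj <- integer(); type <- character()
  if (nrow(links)) {
    known <- links$from %in% names(rows_by_pw) &
      links$to %in% names(rows_by_pw)
    if (any(!known)) {
      bad <- unique(c(links$from[!known], links$to[!known]))
      bad <- setdiff(bad, names(rows_by_pw))
      warning("curated links reference pathways without PCI rows: ",
              paste(utils::head(bad, 5), collapse = ", "))
    }
    links <- links[known, , drop = FALSE]
    for (k in seq_len(nrow(links))) {
      a <- rows_by_pw[[links$from[k]]]
      b <- rows_by_pw[[links$to[k]]]
      grid <- expand.grid(i = a, j = b)
      ii <- c(ii, grid$i); jj <- c(jj, grid$j)
      type <- c(type, rep("curated", nrow(grid)))
    }
  }
  for (rs in rows_by_pw) {
    if (length(rs) >= 2) {
      pr <- combn(rs, 2L)
      ii <- c(ii, pr[1L, ]); jj <- c(jj, pr[2L, ])
      type <- c(type, rep("self", ncol(pr)))
    }
  }
  list(i = ii, j = jj, type = type)
}

#' Permutation null distribution of pathway-pair correlations
#'
#' Estimates the null distribution of absolute Spearman correlations
#' between candidate (pathway, tissue) node pairs by randomly permuting
#' gene-row labels within each tissue's expression matrix, recomputing all
#' PCIs and all candidate pairwise correlations each round, and pooling the
#' absolute values.  Permuting gene labels detaches pathway membership from
#' the expression values while preserving each animal's value multiset.
#' Empirical p-values use the add-one rule
#' `p(r) = (1 + #\{null >= |r|\}) / (1 + #null)`.
#'
#' @inheritParams pci_matrix
#' @param n_perm number of permutation rounds (>= 1); 1000 is a practical
#'   default, 10000 gives publication-grade resolution.
#' @param animal_subset optional character vector of animal ids; z-scoring
#'   is redone within the subset so group-specific networks are
#'   self-contained.
#' @param seed optional RNG seed.
#' @return Object of class `perm_null`: sorted absolute correlations
#'   (`values`), `n_perm`, `n_pairs`, `seed`.
#' @export
permutation_null <- function(exprs, pathway_db, network, n_perm = 1000L,
                             animal_subset = NULL, seed = NULL,
                             include_diagonal = TRUE,
                             normalization = c("size", "pairs")) {
  normalization <- match.arg(normalization)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(animal_subset))
    exprs <- lapply(exprs, function(m) m[, animal_subset, drop = FALSE])
  tissues <- names(exprs)
  genes <- rownames(exprs[[1]])
  scored <- lapply(pathway_db$pathways, function(m) intersect(m, genes))
  scored <- scored[lengths(scored) > 0]
  pw_ids <- sort(names(scored))
  scored <- scored[pw_ids]
  sizes <- lengths(scored)
  adj <- lapply(scored, pathway_adjacency, network = network,
                diagonal = if (include_diagonal) 1 else 0)
  divisor <- if (normalization == "size") sizes else
    sizes * (sizes - 1) / 2 + if (include_diagonal) sizes else 0
  gene_index <- stats::setNames(seq_along(genes), genes)
  members0 <- lapply(scored, function(m) unname(gene_index[m]) - 1L)
  h_list <- lapply(exprs, function(m)
    sigmoid_transform(normalize_expression(m)))

  tis_sorted <- sort(tissues)
  nodes <- split_nodes(as.vector(t(outer(pw_ids, tis_sorted, node_name))))
  cand <- candidate_pairs(nodes, pathway_db$links)
  n_pairs <- length(cand$i)
  if (n_pairs == 0) stop("no candidate pathway pairs (empty curated link ",
                         "set and single-tissue input)")
  G <- length(genes)
  n_nodes <- nrow(nodes)
  row_of <- stats::setNames(seq_len(n_nodes), nodes$node)

  with_seed(seed, {
    out <- numeric(n_perm * n_pairs)
    pci_perm <- matrix(NA_real_, n_nodes, ncol(exprs[[1]]))
    for (b in seq_len(n_perm)) {
      for (tt in tis_sorted) {
        perm <- sample.int(G)
        mem_p <- lapply(members0, function(ix) perm[ix + 1L] - 1L)
        pci_perm[row_of[node_name(pw_ids, tt)], ] <-
          .pci_core(h_list[[tt]], mem_p, adj, as.numeric(divisor))
      }
      Z <- .rank_standardize(pci_perm)
      out[((b - 1) * n_pairs + 1):(b * n_pairs)] <-
        abs(rowSums(Z[cand$i, , drop = FALSE] * Z[cand$j, , drop = FALSE]))
    }
    structure(list(values = sort(out), n_perm = n_perm, n_pairs = n_pairs,
                   seed = seed),
              class = "perm_null")
  })
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "perm_null: %d values (%d rounds x %d candidate pairs), |r| median %.3f\n",
    length(x$values), x$n_perm, x$n_pairs, stats::median(x$values)))
  invisible(x)
}

#' Empirical p-value of a correlation against a permutation null
#'
#' @param null a [permutation_null()] result.
#' @param r numeric vector of (signed) correlations.
#' @return `(1 + #\{null >= |r|\}) / (1 + #null)`, elementwise.
#' @export
null_pvalue <- function(null, r) {
  stopifnot(inherits(null, "perm_null"))
  v <- null$values
  M <- length(v)
  # findInterval(x, v, left.open = TRUE) = #{v < x} on a sorted vector
  n_ge <- M - findInterval(abs(r), v, left.open = TRUE)
  (1 + n_ge) / (1 + M)
}

#' Correlation threshold for an empirical p-value cutoff
#'
#' Returns the smallest absolute correlation whose empirical p-value (per
#' [null_pvalue()]) falls below `p_cut`, so that every correlation at or
#' above the threshold is significant at `p_cut`.  Ties in the null (e.g.
#' the atom at `|r| = 1` for very small animal subsets) are handled
#' exactly: if not even the null maximum is significant, the threshold
#' lands just above it, and with few animals this can leave no attainable
#' correlation significant -- an honest statement that the permutation
#' resolution does not support `p_cut` at that sample size.  If the null
#' is too small to reach `p_cut` at all (`p_cut <= 1 / (1 + #null)`), the
#' threshold is `+Inf` with a warning.
#'
#' @param null a [permutation_null()] result.
#' @param p_cut p-value cutoff in (0, 1); 0.005 in the default analysis.
#' @return A single threshold on `|r|`.
#' @export
threshold_for_p <- function(null, p_cut = 0.005) {
  stopifnot(inherits(null, "perm_null"), p_cut > 0, p_cut <= 1)
  v <- null$values
  M <- length(v)
  m1 <- M + 1
  if (p_cut <= 1 / m1) {
    warning("p_cut below the resolution of the null (1/",
            m1, "); threshold is +Inf")
    return(Inf)
  }
  u <- unique(v)  # ascending; p(u) = (1 + #{v >= u}) / m1, tie-exact
  n_ge <- M - findInterval(u, v, left.open = TRUE)
  ok <- (1 + n_ge) / m1 < p_cut
  if (any(ok)) return(u[which(ok)[1]])
  v[M] + 1e-15  # only values strictly above the null maximum qualify
}

#' Build the pathway coordination network
#'
#' Candidate edges are (a) curated pathway pairs, taken across every tissue
#' combination -- two pathways in the same tissue, or each in a different
#' tissue -- and (b) the same pathway in two different tissues (self
#' pairs, always candidates).  An edge is retained when the absolute
#' Spearman correlation of the two PCI rows reaches `threshold`.  Curated
#' gating is absolute: no other pair is ever connected.
#'
#' @param pci a [pci_matrix()].
#' @param curated_links data frame of curated pathway pairs (columns
#'   `from`, `to`), e.g. `pathway_db$links`; unknown pathways are skipped
#'   with a warning.
#' @param animal_subset optional character vector of animal columns to use
#'   (e.g. one of the eight groups).
#' @param threshold correlation threshold in `[0, 1]` (from
#'   [threshold_for_p()], or the fixed values 0.4 / 0.7 for the global /
#'   group networks of the emulated study).
#' @param null optional [permutation_null()]; if given, each edge gets an
#'   empirical p-value attribute.
#' @return Object of class `pathway_network`: `graph` (igraph over all
#'   (pathway, tissue) nodes), `edges` (data frame `from`, `to`, `r`,
#'   `type`, optional `p`), `candidates` (data frame of all candidate
#'   pairs), `threshold`.
#' @export
build_network <- function(pci, curated_links, animal_subset = NULL,
                          threshold, null = NULL) {
  stopifnot(is.matrix(pci), threshold >= 0)
  m <- pci
  if (!is.null(animal_subset)) {
    stopifnot(length(animal_subset) >= 3)
    m <- m[, animal_subset, drop = FALSE]
  }
  nodes <- split_nodes(rownames(m))
  links <- normalize_links(curated_links)
  cand <- candidate_pairs(nodes, links)
  Z <- .rank_standardize(m)
  r <- rowSums(Z[cand$i, , drop = FALSE] * Z[cand$j, , drop = FALSE])
  keep <- abs(r) >= threshold
  edges <- data.frame(from = nodes$node[cand$i][keep],
                      to = nodes$node[cand$j][keep],
                      r = r[keep], type = cand$type[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(null)) edges$p <- null_pvalue(null, edges$r)
  g <- graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes$node, pathway = nodes$pathway,
                          tissue = nodes$tissue, stringsAsFactors = FALSE))
  if (nrow(edges)) {
    E(g)$r <- edges$r
    E(g)$type <- edges$type
  }
  structure(list(graph = g, edges = edges,
                 candidates = data.frame(from = nodes$node[cand$i],
                                         to = nodes$node[cand$j],
                                         type = cand$type,
                                         stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf(paste0("pathway_network: %d (pathway, tissue) nodes, %d ",
                     "edges of %d candidate pairs (|r| >= %.3f)\n"),
              vcount(x$graph), nrow(x$edges), nrow(x$candidates),
              x$threshold))
  invisible(x)
}
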