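#' Z-score expression per gene
#'
#' Normalizes each gene (row) to zero mean and unit variance across the
#' animals of one tissue, using the sample (n-1) standard deviation.
#' Zero-variance genes carry no ranking information and are set to all-zero
#' z-scores with a warning.
#'
#' @param expr numeric matrix, genes x animals (log-ratio values), >= 2
#'   columns.
#' @return Numeric matrix of z-scores, same dimnames.
#' @examples
#' normalize_expression(rbind(g1 = c(1, 2, 3)))  # (-1, 0, 1)
#' @export
normalize_expression <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression matrix")
  mu <- rowMeans(expr)
  s <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1))
  flat <- s <= .Machine$double.eps
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s); z-scores set to 0")
    s[flat] <- 1
  }
  z <- (expr - mu) / s
  z[flat, ] <- 0
  z
}

#' Centered sigmoid transform
#'
#' Maps a z-score to `1 / (1 + exp(-z)) - 0.5`, a strictly increasing odd
#' function with range (-0.5, 0.5).  Centering preserves the sign
#' (up/down-regulation) of the z-score while damping the influence of
#' extreme expression values on the PCI.
#'
#' @param z numeric vector/matrix of finite values.
#' @return Transformed values, same shape.
#' @export
sigmoid_transform <- function(z) plogis(z) - 0.5

# Dense adjacency submatrix for one pathway's member genes: stored link
# probabilities off the diagonal, `diagonal` on it.  Genes absent from the
# network get only their diagonal entry.
pathway_adjacency <- function(members, network, diagonal = 1) {
  N <- length(members)
  A <- matrix(0, N, N, dimnames = list(members, members))
  present <- intersect(members, rownames(network))
  if (length(present) >= 2)
    A[present, present] <- as.matrix(network[present, present, drop = FALSE])
  diag(A) <- diagonal
  A
}

#' Pathway Connectivity Index for one animal
#'
#' Computes
#' `PCI = (1/N) * sum_{i <= j} sgn(h_i + h_j) * sqrt(|h_i|) * a_ij * sqrt(|h_j|)`
#' over all unordered member-gene pairs of a pathway, where `h` are
#' centered-sigmoid-transformed z-scores, `a_ij` is the functional-linkage
#' probability (with `a_ii = 1`, so each diagonal term reduces to `h_i`),
#' `sgn(0) = 0`, and `N` is the number of scored member genes.  The sign
#' term encodes the joint up/down-regulation of the pair, the square-root
#' weighting symmetrizes the two magnitudes, and the size normalization
#' makes PCIs comparable across pathways.  Genes with stronger or more
#' numerous links (hubs) contribute more.
#'
#' @param h named numeric vector of transformed values for one animal
#'   (all genes of the tissue).
#' @param members character vector of pathway member gene ids; members
#'   without expression values are dropped and do not count toward `N`.
#' @param network symmetric gene-gene link-probability matrix (sparse or
#'   dense); absent pairs mean 0.
#' @param include_diagonal include the `a_ii = 1` self terms (default TRUE).
#' @param normalization `"size"` divides by `N`; `"pairs"` divides by the
#'   number of summed pairs.
#' @return A single PCI value, or `NA` (with a warning) if no member has
#'   expression data.
#' @examples
#' h <- c(a = 0.2, b = -0.1)
#' A <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("a","b"), c("a","b")))
#' compute_pci(h, c("a", "b"), A)  # (0.2 - 0.1 + 0.5*sqrt(0.02)) / 2
#' @export
compute_pci <- function(h, members, network, include_diagonal = TRUE,
                        normalization = c("size", "pairs")) {
  normalization <- match.arg(normalization)
  members <- intersect(members, names(h))
  N <- length(members)
  if (N == 0) {
    warning("pathway has no members with expression data")
    return(NA_real_)
  }
  A <- pathway_adjacency(members, network,
                         diagonal = if (include_diagonal) 1 else 0)
  hm <- h[members]
  S <- sign(outer(hm, hm, "+")) * outer(sqrt(abs(hm)), sqrt(abs(hm))) * A
  tot <- (sum(S) + sum(diag(S))) / 2
  div <- if (normalization == "size") N else
    N * (N - 1) / 2 + if (include_diagonal) N else 0
  tot / div
}

#' PCI matrix across pathways, tissues and animals
#'
#' Applies per-tissue z-scoring, the centered sigmoid transform, and
#' [compute_pci()] animal-wise to every pathway, producing one row per
#' (pathway, tissue) node.  Rows are ordered lexicographically by pathway
#' id then tissue and named `"pathway|tissue"`.
#'
#' @param exprs named list tissue -> numeric matrix (genes x animals); all
#'   tissues must cover the same animal set (columns are aligned to the
#'   first tissue's order).
#' @param pathway_db a [pathway_db()].
#' @param network symmetric gene-gene link-probability matrix.
#' @inheritParams compute_pci
#' @return Numeric matrix of class `pci_matrix` ((pathway, tissue) nodes x
#'   animals) with attributes `pathway`, `tissue` and `size` (scored genes
#'   per row).
#' @export
pci_matrix <- function(exprs, pathway_db, network, include_diagonal = TRUE,
                       normalization = c("size", "pairs")) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(exprs), length(exprs) >= 1, !is.null(names(exprs)),
            inherits(pathway_db, "pathway_db"))
  tissues <- names(exprs)
  animals <- colnames(exprs[[1]])
  for (tt in tissues) {
    if (!setequal(colnames(exprs[[tt]]), animals))
      stop("animal sets differ across tissues (tissue ", tt, ")")
    exprs[[tt]] <- exprs[[tt]][, animals, drop = FALSE]
  }
  # scored members per pathway (genes present in the expression matrices;
  # the gene set is shared across tissues by construction)
  genes <- rownames(exprs[[1]])
  scored <- lapply(pathway_db$pathways, function(m) intersect(m, genes))
  empty <- lengths(scored) == 0
  if (any(empty)) {
    warning("skipping pathway(s) with no expression data: ",
            paste(names(scored)[empty], collapse = ", "))
    scored <- scored[!empty]
  }
  if (!length(scored)) stop("no pathway has members with expression data")
  pw_ids <- sort(names(scored))
  scored <- scored[pw_ids]
  sizes <- lengths(scored)
  adj <- lapply(scored, pathway_adjacency, network = network,
                diagonal = if (include_diagonal) 1 else 0)
  divisor <- if (normalization == "size") sizes else
    sizes * (sizes - 1) / 2 + if (include_diagonal) sizes else 0
  gene_index <- stats::setNames(seq_along(genes), genes)
  members0 <- lapply(scored, function(m) unname(gene_index[m]) - 1L)

  per_tissue <- vector("list", length(tissues))
  names(per_tissue) <- tissues
  for (tt in tissues) {
    stopifnot(identical(rownames(exprs[[tt]]), genes))
    h <- sigmoid_transform(normalize_expression(exprs[[tt]]))
    per_tissue[[tt]] <- .pci_core(h, members0, adj, as.numeric(divisor))
  }
  # interleave into (pathway, tissue) lexicographic row order
  tis_sorted <- sort(tissues)
  rows <- as.vector(t(outer(pw_ids, tis_sorted, paste, sep = "|")))
  out <- matrix(NA_real_, nrow = length(rows), ncol = length(animals),
                dimnames = list(rows, animals))
  for (tt in tis_sorted)
    out[paste(pw_ids, tt, sep = "|"), ] <- per_tissue[[tt]]
  structure(out,
            pathway = rep(pw_ids, each = length(tis_sorted)),
            tissue = rep(tis_sorted, times = length(pw_ids)),
            size = stats::setNames(rep(unname(sizes), each = length(tis_sorted)),
                                   rows),
            class = c("pci_matrix", "matrix", "array"))
}

# node name helpers -----------------------------------------------------

node_name <- function(pathway, tissue) paste(pathway, tissue, sep = "|")

#' Split `"pathway|tissue"` node names
#' @param nodes character vector of node names.
#' @return Data frame with columns `node`, `pathway`, `tissue`.
#' @export
split_nodes <- function(nodes) {
  parts <- strsplit(nodes, "|", fixed = TRUE)
  data.frame(node = nodes,
             pathway = vapply(parts, `[`, "", 1L),
             tissue = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}
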