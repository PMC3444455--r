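#' Read a GMT gene-set file
#'
#' @param file path to a tab-separated GMT file (pathway id, description,
#'   member genes).
#' @return Named list pathway id -> character vector of gene ids.
#' @export
read_gmt <- function(file) fgsea::gmtPathways(file)

#' Write pathway memberships as GMT
#'
#' @param pathways named list pathway id -> gene ids.
#' @param file output path.
#' @param descriptions optional named character of descriptions (defaults
#'   to the pathway ids).
#' @export
write_gmt <- function(pathways, file, descriptions = NULL) {
  descriptions <- descriptions %||%
    stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(p)
    paste(c(p, descriptions[[p]], pathways[[p]]), collapse = "\t"), "")
  writeLines(lines, file)
}

#' @rdname io_tables
#' @export
write_pathway_links <- function(links, file)
  write.table(links, file, sep = "\t", quote = FALSE, row.names = FALSE)

#' @rdname io_tables
#' @export
read_pathway_links <- function(file)
  normalize_links(read.delim(file, stringsAsFactors = FALSE))

#' Tabular readers and writers
#'
#' Plain TSV interchange for the pipeline's inputs and outputs: curated
#' pathway links (two columns), the gene functional network (three-column
#' edge list with link probability), per-tissue expression matrices (gene
#' rows, animal columns), the animal x trait table, and the PCI matrix
#' (rows named `"pathway|tissue"`).
#'
#' @param links,file,genes,mat,pci,traits see individual functions.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
write_gene_network <- function(net, file) {
  m <- as(as(net, "generalMatrix"), "TsparseMatrix")
  keep <- m@i < m@j  # upper triangle once
  df <- data.frame(gene1 = rownames(net)[m@i[keep] + 1L],
                   gene2 = colnames(net)[m@j[keep] + 1L],
                   probability = m@x[keep], stringsAsFactors = FALSE)
  df <- df[order(df$gene1, df$gene2), ]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io_tables
#' @export
read_gene_network <- function(file, genes = NULL) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 3)
  genes <- genes %||% sort(unique(c(df[[1]], df[[2]])))
  if (any(df[[3]] <= 0 | df[[3]] > 1))
    stop("link probabilities must lie in (0, 1]")
  i <- match(df[[1]], genes); j <- match(df[[2]], genes)
  if (anyNA(i) || anyNA(j)) stop("edge list references unknown genes")
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(df[[3]], 2),
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes))
}

#' @rdname io_tables
#' @export
write_expression <- function(mat, file) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io_tables
#' @export
read_expression <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io_tables
#' @export
write_traits <- function(traits, file) {
  df <- data.frame(animal = rownames(traits), traits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io_tables
#' @export
read_traits <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io_tables
#' @export
write_pci <- function(pci, file) {
  df <- data.frame(node = rownames(pci), size = attr(pci, "size"),
                   pci, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io_tables
#' @export
read_pci <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$node
  info <- split_nodes(df$node)
  structure(m, pathway = info$pathway, tissue = info$tissue,
            size = stats::setNames(df$size, df$node),
            class = c("pci_matrix", "matrix", "array"))
}

#' Write a synthetic cohort fixture to disk
#'
#' Emits every pipeline input in its interchange format: pathway GMT,
#' curated-link TSV, gene-network edge list, per-tissue expression TSVs,
#' trait TSV, cohort design TSV, and the planted ground truth as YAML.
#'
#' @param cohort a [synthesize_cohort()] result.
#' @param dir writable output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gmt = file.path(dir, "pathways.gmt"),
             links = file.path(dir, "curated_links.tsv"),
             network = file.path(dir, "gene_network.tsv"),
             traits = file.path(dir, "traits.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "ground_truth.yaml"),
             categories = file.path(dir, "categories.tsv"))
  write_gmt(cohort$pathway_db$pathways, paths[["gmt"]])
  write_pathway_links(cohort$pathway_db$links, paths[["links"]])
  write_gene_network(cohort$gene_network, paths[["network"]])
  write_traits(cohort$traits, paths[["traits"]])
  write.table(cbind(as.data.frame(cohort$design),
                    tissues = paste(design_tissues(cohort$design),
                                    collapse = ",")),
              paths[["design"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(pathway = names(cohort$pathway_db$categories),
                         category = unname(cohort$pathway_db$categories)),
              paths[["categories"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- cohort$ground_truth
  yaml::write_yaml(list(
    active_pathways = lapply(gt$active_pathways, as.list),
    trait_effects = lapply(seq_len(nrow(gt$trait_effects)), function(k)
      as.list(gt$trait_effects[k, ])),
    traits = as.list(gt$traits),
    noise_sd = gt$noise_sd, activity_sd = gt$activity_sd,
    trait_noise_sd = gt$trait_noise_sd), paths[["truth"]])
  for (tt in names(cohort$exprs)) {
    p <- file.path(dir, paste0("expression_", tt, ".tsv"))
    write_expression(cohort$exprs[[tt]], p)
    paths[[paste0("expression_", tt)]] <- p
  }
  invisible(paths)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return List with `design`, `pathway_db`, `gene_network`, `exprs`,
#'   `traits`, `ground_truth` (no PCI; recompute with [pci_matrix()]).
#' @export
read_fixture <- function(dir) {
  pathways <- read_gmt(file.path(dir, "pathways.gmt"))
  cats <- read.delim(file.path(dir, "categories.tsv"),
                     stringsAsFactors = FALSE)
  categories <- stats::setNames(cats$category, cats$pathway)
  links <- read_pathway_links(file.path(dir, "curated_links.tsv"))
  des <- read.delim(file.path(dir, "design.tsv"), stringsAsFactors = FALSE)
  tissues <- strsplit(des$tissues[1], ",", fixed = TRUE)[[1]]
  design <- des[, setdiff(names(des), "tissues")]
  attr(design, "tissues") <- tissues
  class(design) <- c("cohort_design", "data.frame")
  y <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  te <- if (length(y$trait_effects))
    do.call(rbind, lapply(y$trait_effects, as.data.frame))
  else data.frame(trait = character(), pathway = character(),
                  tissue = character(), effect = numeric())
  gt <- structure(list(
    active_pathways = lapply(y$active_pathways, unlist),
    trait_effects = te, traits = unlist(y$traits),
    noise_sd = y$noise_sd, activity_sd = y$activity_sd,
    trait_noise_sd = y$trait_noise_sd), class = "ground_truth")
  exprs <- stats::setNames(lapply(tissues, function(tt)
    read_expression(file.path(dir, paste0("expression_", tt, ".tsv")))),
    tissues)
  genes <- rownames(exprs[[1]])
  db <- pathway_db(pathways, categories, links, genes = genes)
  net <- read_gene_network(file.path(dir, "gene_network.tsv"), genes = genes)
  list(design = design, pathway_db = db, gene_network = net,
       exprs = exprs, traits = read_traits(file.path(dir, "traits.tsv")),
       ground_truth = gt)
}

#' Export a network as SIF or GraphML
#'
#' SIF lines read `nodeA <edgetype> nodeB` (tab-separated) with pathway
#' nodes named `"pathway|tissue"` and trait node names verbatim; isolated
#' nodes are emitted as single-column lines, per SIF convention.  GraphML
#' (via igraph) carries the node attributes (type, tissue, pathway,
#' category, linking class).
#'
#' @param net a `trait_pathway_network`, `pathway_network` or igraph.
#' @param file output path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `file`.
#' @export
export_network <- function(net, file, format = c("sif", "graphml")) {
  format <- match.arg(format)
  g <- as_cp_graph(net)
  if (format == "graphml") {
    # GraphML attribute handling rejects NA logicals/characters
    for (a in vertex_attr_names(g)) {
      v <- vertex_attr(g, a)
      if (is.character(v) || is.logical(v)) {
        v[is.na(v)] <- ""
        g <- set_vertex_attr(g, a, value = as.character(v))
      }
    }
    write_graph(g, file, format = "graphml")
  } else {
    el <- as_edgelist(g)
    type <- if ("type" %in% edge_attr_names(g)) E(g)$type
    else rep("interacts", nrow(el))
    lines <- if (nrow(el))
      paste(el[, 1], type, el[, 2], sep = "\t") else character()
    isolated <- V(g)$name[degree(g) == 0]
    writeLines(c(lines, isolated), file)
  }
  invisible(file)
}

#' Import a GraphML network
#'
#' @param file path to a GraphML file written by [export_network()].
#' @return An igraph graph.
#' @export
import_network <- function(file) read_graph(file, format = "graphml")
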