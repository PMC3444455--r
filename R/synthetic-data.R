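#' Multi-tissue cohort design
#'
#' Describes a factorial animal cohort: strains x obesity status x ages x
#' replicates, with every animal profiled in every tissue.  The default
#' reproduces the 2 x 2 x 2 x 5 design (40 animals, 8 groups) of the
#' obesity-induced diabetes mouse model this package emulates.
#'
#' @param strains,obesity,ages character vectors of factor levels
#'   (two each by default).
#' @param replicates positive integer, animals per group.
#' @param tissues character vector of tissue labels.
#' @return A data frame of class `cohort_design` with one row per animal
#'   (columns `animal`, `strain`, `obesity`, `age`, `replicate`, `group`)
#'   and attribute `tissues`.
#' @examples
#' d <- cohort_design()
#' nrow(d)            # 40 animals
#' length(unique(d$group))  # 8 groups
#' @export
cohort_design <- function(strains = c("B6", "BTBR"),
                          obesity = c("lean", "ob"),
                          ages = c("4wk", "10wk"),
                          replicates = 5L,
                          tissues = c("adipose", "gastrocnemius",
                                      "hypothalamus", "islet", "liver",
                                      "soleus")) {
  stopifnot(length(strains) >= 1, length(obesity) >= 1, length(ages) >= 1,
            replicates >= 1, length(tissues) >= 1)
  grid <- expand.grid(replicate = seq_len(replicates), age = ages,
                      obesity = obesity, strain = strains,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "obesity", "age", "replicate")]
  grid$group <- paste(grid$strain, grid$obesity, grid$age, sep = "-")
  grid$animal <- paste0(grid$group, "-r", grid$replicate)
  grid <- grid[order(grid$group, grid$replicate), ]
  rownames(grid) <- NULL
  out <- grid[, c("animal", "strain", "obesity", "age", "replicate", "group")]
  attr(out, "tissues") <- as.character(tissues)
  class(out) <- c("cohort_design", "data.frame")
  out
}

#' Tissues of a cohort design
#' @param design a `cohort_design`.
#' @return Character vector of tissue labels.
#' @export
design_tissues <- function(design) attr(design, "tissues")

#' Pathway database container
#'
#' Bundles pathway membership, pathway category labels and the curated
#' pathway-pathway link set (the analogue of KEGG pathway annotation).
#'
#' @param pathways named list, pathway id -> character vector of gene ids.
#' @param categories named character, pathway id -> category label.
#' @param links data frame with columns `from`, `to` (pathway ids); stored
#'   symmetric-irreflexive with `from < to`.
#' @param genes character vector, the full gene universe (defaults to the
#'   union of all members).
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(pathways, categories = NULL, links = NULL,
                       genes = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)),
            !anyDuplicated(names(pathways)))
  genes <- genes %||% sort(unique(unlist(pathways, use.names = FALSE)))
  bad <- setdiff(unlist(pathways, use.names = FALSE), genes)
  if (length(bad))
    stop("pathway members absent from the gene universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(categories)) {
    categories <- rep("Unassigned", length(pathways))
    names(categories) <- names(pathways)
  }
  stopifnot(all(names(pathways) %in% names(categories)))
  if (is.null(links)) {
    links <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    links <- normalize_links(links, names(pathways))
  }
  structure(list(pathways = pathways,
                 categories = categories[names(pathways)],
                 links = links, genes = genes),
            class = "pathway_db")
}

# Canonical, deduplicated, irreflexive link table with from < to.
normalize_links <- function(links, pathway_ids = NULL) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  stopifnot(ncol(links) >= 2)
  from <- as.character(links[[1]]); to <- as.character(links[[2]])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  lo <- pmin(from, to); hi <- pmax(from, to)
  out <- unique(data.frame(from = lo, to = hi, stringsAsFactors = FALSE))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways over %d genes, %d curated links\n",
              length(x$pathways), length(x$genes), nrow(x$links)))
  cat("  sizes: ", paste(range(lengths(x$pathways)), collapse = "-"),
      " genes; categories: ",
      paste(sort(unique(x$categories)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.pathway_categories <- c("Metabolism", "Genetic information processing",
                         "Environmental information processing",
                         "Cellular processes", "Human diseases")

#' Generate a synthetic pathway database
#'
#' Pathways receive disjoint core gene memberships (drawn from a common gene
#' universe) plus a configurable fraction of overlapping members; curated
#' pathway-pathway links are sampled uniformly with the requested density,
#' and each pathway is assigned one of five category labels.
#'
#' @param n_pathways number of pathways (>= 2).
#' @param size_range length-2 integer vector, inclusive range of core sizes;
#'   must lie within `[2, n_genes]`.
#' @param n_genes size of the gene universe.
#' @param link_density probability in `[0, 1]` that an unordered pathway
#'   pair is curated-linked.
#' @param overlap fraction of additional shared members per pathway (drawn
#'   from the whole gene universe), default 0.1.
#' @param seed optional RNG seed for reproducibility.
#' @return A [pathway_db()].
#' @examples
#' db <- generate_pathway_db(20, c(5, 10), 300, link_density = 0.1, seed = 1)
#' length(db$pathways)
#' @export
generate_pathway_db <- function(n_pathways = 60L, size_range = c(5L, 25L),
                                n_genes = 1200L, link_density = 0.05,
                                overlap = 0.1, seed = NULL) {
  if (n_pathways < 2) stop("n_pathways must be >= 2")
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] > n_genes || size_range[1] > size_range[2])
    stop("size_range must lie within [2, n_genes]")
  if (link_density < 0 || link_density > 1)
    stop("link_density must be in [0, 1]")
  if (overlap < 0) stop("overlap must be >= 0")
  with_seed(seed, {
    ids <- sprintf(paste0("pw%0", nchar(n_pathways), "d"),
                   seq_len(n_pathways))
    genes <- sprintf(paste0("g%0", nchar(n_genes), "d"), seq_len(n_genes))
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    if (sum(sizes) > n_genes)
      stop("disjoint pathway cores require more genes than n_genes; ",
           "reduce n_pathways or size_range, or raise n_genes")
    pool <- sample(genes)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    pathways <- vector("list", n_pathways)
    names(pathways) <- ids
    for (k in seq_len(n_pathways)) {
      core <- pool[starts[k]:stops[k]]
      n_extra <- round(overlap * sizes[k])
      extra <- if (n_extra > 0)
        sample(setdiff(genes, core), n_extra) else character()
      pathways[[k]] <- sort(c(core, extra))
    }
    categories <- sample(.pathway_categories, n_pathways, replace = TRUE)
    names(categories) <- ids
    pairs <- t(combn(ids, 2L))
    keep <- runif(nrow(pairs)) < link_density
    links <- data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                        stringsAsFactors = FALSE)
    pathway_db(pathways, categories, links, genes)
  })
}

#' Generate a synthetic gene functional-interaction network
#'
#' Emulates a probabilistic functional-linkage network: each gene pair in
#' the same pathway is linked with probability `within_prob`, every other
#' pair with probability `cross_prob`.  Link weights (interaction
#' probabilities in `(0, 1]`) are drawn higher for within-pathway edges,
#' reflecting that annotated functional partners carry stronger linkage
#' evidence.  No self-edges are stored; the PCI module supplies the unit
#' diagonal.
#'
#' @param pathway_db a [pathway_db()].
#' @param within_prob,cross_prob edge probabilities in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A symmetric sparse `Matrix` (genes x genes) of link
#'   probabilities; absent pairs mean probability 0.
#' @export
generate_gene_network <- function(pathway_db, within_prob = 0.5,
                                  cross_prob = 0.01, seed = NULL) {
  stopifnot(inherits(pathway_db, "pathway_db"))
  if (within_prob < 0 || within_prob > 1 || cross_prob < 0 || cross_prob > 1)
    stop("edge probabilities must lie in [0, 1]")
  genes <- pathway_db$genes
  G <- length(genes)
  idx <- stats::setNames(seq_len(G), genes)
  with_seed(seed, {
    # within-pathway candidate pairs (deduplicated across overlapping sets)
    wp <- lapply(pathway_db$pathways, function(m) {
      i <- sort(idx[m])
      if (length(i) < 2) return(NULL)
      t(combn(i, 2L))
    })
    wp <- unique(do.call(rbind, wp))
    key_w <- (wp[, 1L] - 1) * G + wp[, 2L]
    keep <- runif(nrow(wp)) < within_prob
    wi <- wp[keep, , drop = FALSE]
    w_within <- runif(nrow(wi), min = 0.5, max = 1)
    # cross pairs: sample linear indices of the upper triangle, drop the
    # ones that are within-pathway pairs
    n_pairs <- G * (G - 1) / 2
    n_cross <- rbinom(1L, n_pairs - nrow(wp), cross_prob)
    ci <- matrix(integer(), 0L, 2L)
    if (n_cross > 0) {
      draw <- sample(n_pairs, min(n_pairs, ceiling(n_cross * 1.2 + 10)))
      # linear index k (1-based, column-major upper triangle) -> (i, j)
      j <- ceiling((1 + sqrt(1 + 8 * draw)) / 2)
      i <- draw - (j - 1) * (j - 2) / 2
      key <- (i - 1) * G + j
      ok <- !(key %in% key_w)
      ci <- cbind(i[ok], j[ok])[seq_len(min(n_cross, sum(ok))), ,
                                drop = FALSE]
    }
    w_cross <- runif(nrow(ci), min = .Machine$double.eps, max = 0.5)
    ii <- c(wi[, 1L], ci[, 1L]); jj <- c(wi[, 2L], ci[, 2L])
    ww <- c(w_within, w_cross)
    Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                         dims = c(G, G), dimnames = list(genes, genes))
  })
}

#' Planted ground truth for a synthetic cohort
#'
#' Records which pathways are co-active (per animal group), which traits are
#' driven by which (pathway, tissue) activities, and the noise scales.  Used
#' by [generate_expression()] and [generate_traits()], and by recovery tests
#' as the reference answer.
#'
#' @param pathway_db a [pathway_db()].
#' @param design a [cohort_design()].
#' @param n_active number of planted co-active pathways (0 gives a pure
#'   null cohort).
#' @param traits character vector of trait names (default: the eight
#'   metabolic traits of the emulated study).
#' @param tissues tissues in which activity is planted (default: all).
#' @param effect_size trait effect per planted pathway, in PCI
#'   standard-deviation units.
#' @param noise_sd per-gene expression noise SD (log10-ratio scale).
#' @param activity_sd SD of the planted group-level activity shifts.
#' @param trait_noise_sd SD of the additive trait noise.
#' @param seed optional RNG seed.
#' @return An object of class `ground_truth` with fields `active_pathways`
#'   (group -> pathway ids), `trait_effects` (data frame `trait`, `pathway`,
#'   `tissue`, `effect`), `noise_sd`, `activity_sd`, `trait_noise_sd`,
#'   `traits`.
#' @export
ground_truth <- function(pathway_db, design, n_active = 8L,
                         traits = c("glucose", "insulin", "islets", "weight",
                                    "TG", "adiponectin", "PAI1", "resistin"),
                         tissues = design_tissues(design),
                         effect_size = 1, noise_sd = 0.2,
                         activity_sd = 5 * noise_sd,
                         trait_noise_sd = 0.2, seed = NULL) {
  stopifnot(inherits(pathway_db, "pathway_db"),
            inherits(design, "cohort_design"),
            n_active >= 0, n_active <= length(pathway_db$pathways),
            noise_sd > 0)
  groups <- unique(design$group)
  with_seed(seed, {
    active <- sort(sample(names(pathway_db$pathways), n_active))
    active_pathways <- stats::setNames(
      rep(list(active), length(groups)), groups)
    if (n_active > 0 && length(traits) > 0) {
      pw <- active[1 + (seq_along(traits) - 1) %% n_active]
      ts <- tissues[1 + (seq_along(traits) - 1) %% length(tissues)]
      trait_effects <- data.frame(trait = traits, pathway = pw, tissue = ts,
                                  effect = effect_size,
                                  stringsAsFactors = FALSE)
    } else {
      trait_effects <- data.frame(trait = character(), pathway = character(),
                                  tissue = character(), effect = numeric(),
                                  stringsAsFactors = FALSE)
    }
    structure(list(active_pathways = active_pathways,
                   trait_effects = trait_effects,
                   traits = traits, noise_sd = noise_sd,
                   activity_sd = activity_sd,
                   trait_noise_sd = trait_noise_sd),
              class = "ground_truth")
  })
}

validate_ground_truth <- function(gt, pathway_db) {
  ref <- unique(c(unlist(gt$active_pathways, use.names = FALSE),
                  gt$trait_effects$pathway))
  bad <- setdiff(ref, names(pathway_db$pathways))
  if (length(bad))
    stop("ground truth references unknown pathways: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Generate synthetic log-ratio expression matrices
#'
#' Baseline values are i.i.d. Normal(0, `noise_sd`) per gene and animal
#' (log10-ratio scale).  For every planted (group, pathway, tissue) triple a
#' single latent activity shift ~ Normal(0, `activity_sd`) is drawn and
#' added to all member genes of that pathway in all animals of that group,
#' so member expression -- and hence pathway PCI -- co-varies across
#' animals.
#'
#' @param pathway_db a [pathway_db()].
#' @param design a [cohort_design()].
#' @param ground_truth a [ground_truth()].
#' @param tissues tissues to generate (default: the design's).
#' @param seed optional RNG seed.
#' @return Named list tissue -> numeric matrix (genes x animals).
#' @export
generate_expression <- function(pathway_db, design, ground_truth,
                                tissues = design_tissues(design),
                                seed = NULL) {
  stopifnot(inherits(pathway_db, "pathway_db"),
            inherits(design, "cohort_design"),
            inherits(ground_truth, "ground_truth"))
  validate_ground_truth(ground_truth, pathway_db)
  genes <- pathway_db$genes
  animals <- design$animal
  groups <- unique(design$group)
  with_seed(seed, {
    out <- vector("list", length(tissues))
    names(out) <- tissues
    for (tt in tissues) {
      m <- matrix(rnorm(length(genes) * length(animals),
                        sd = ground_truth$noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes, animals))
      for (g in groups) {
        cols <- design$animal[design$group == g]
        for (p in sort(ground_truth$active_pathways[[g]])) {
          shift <- rnorm(1L, sd = ground_truth$activity_sd)
          rows <- pathway_db$pathways[[p]]
          m[rows, cols] <- m[rows, cols] + shift
        }
      }
      out[[tt]] <- m
    }
    out
  })
}

#' Generate quantitative traits from planted pathway activities
#'
#' Each trait is a linear combination of the (z-scored) PCI rows of its
#' planted (pathway, tissue) drivers plus Gaussian noise; traits without
#' planted drivers are pure noise.  Spearman-based detection downstream is
#' invariant to any monotone link, so the linear form is without loss of
#' generality for testing.
#'
#' @param design a [cohort_design()].
#' @param pci_truth a numeric matrix with rows named `"pathway|tissue"`
#'   and animal columns (typically the output of [pci_matrix()]); must
#'   contain every planted driver row.
#' @param ground_truth a [ground_truth()].
#' @param seed optional RNG seed.
#' @return Numeric matrix animals x traits.
#' @export
generate_traits <- function(design, pci_truth, ground_truth, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(ground_truth, "ground_truth"),
            is.matrix(pci_truth))
  animals <- design$animal
  stopifnot(all(animals %in% colnames(pci_truth)))
  eff <- ground_truth$trait_effects
  need <- paste(eff$pathway, eff$tissue, sep = "|")
  missing_rows <- setdiff(need, rownames(pci_truth))
  if (length(missing_rows))
    stop("trait effects reference PCI rows absent from pci_truth: ",
         paste(missing_rows, collapse = ", "))
  traits <- ground_truth$traits
  with_seed(seed, {
    out <- matrix(0, nrow = length(animals), ncol = length(traits),
                  dimnames = list(animals, traits))
    for (tr in traits) {
      rows <- eff[eff$trait == tr, , drop = FALSE]
      y <- rnorm(length(animals), sd = ground_truth$trait_noise_sd)
      if (nrow(rows)) {
        for (k in seq_len(nrow(rows))) {
          v <- pci_truth[paste(rows$pathway[k], rows$tissue[k], sep = "|"),
                         animals]
          s <- sd(v)
          if (s > 0) v <- (v - mean(v)) / s
          y <- y + rows$effect[k] * v
        }
      }
      out[, tr] <- y
    }
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' One-call generator producing every input of the pipeline with planted,
#' recoverable structure: a pathway database, a gene functional network,
#' per-tissue expression, the PCI matrix, and traits driven by planted
#' pathway activities.  Pathway pairs that are planted co-active are
#' guaranteed to be curated-linked, so their coordination is detectable by
#' the curation-gated network.  The default scale (60 pathways, 1200 genes,
#' 3 tissues, 40 animals) keeps full-pipeline runs fast; pass
#' `n_pathways = 187` and six tissues for the full emulated scale.
#'
#' @param n_pathways,n_genes,size_range,link_density,overlap passed to
#'   [generate_pathway_db()].
#' @param tissues tissue labels (default 3 of the six profiled tissues).
#' @param design a [cohort_design()]; defaults to 2 strains x 2 obesity x
#'   2 ages x 5 replicates over `tissues`.
#' @param within_prob,cross_prob passed to [generate_gene_network()].
#' @param n_active,effect_size,noise_sd,activity_sd,trait_noise_sd,traits
#'   passed to [ground_truth()]; `n_active = 0` yields a null cohort.
#' @param seed RNG seed for the whole cohort.
#' @return List with elements `design`, `pathway_db`, `gene_network`,
#'   `exprs` (tissue -> genes x animals matrix), `pci` (a [pci_matrix()]),
#'   `traits` (animals x traits), `ground_truth`.
#' @examples
#' co <- synthesize_cohort(n_pathways = 12, n_genes = 150,
#'                         size_range = c(4, 8), seed = 1)
#' dim(co$pci)
#' @export
synthesize_cohort <- function(n_pathways = 60L, n_genes = 1200L,
                              size_range = c(5L, 25L),
                              tissues = c("adipose", "islet", "liver"),
                              design = cohort_design(tissues = tissues),
                              link_density = 0.05, overlap = 0.1,
                              within_prob = 0.5, cross_prob = 0.01,
                              n_active = 8L, effect_size = 1,
                              noise_sd = 0.2, activity_sd = 5 * noise_sd,
                              trait_noise_sd = 0.2,
                              traits = c("glucose", "insulin", "islets",
                                         "weight", "TG", "adiponectin",
                                         "PAI1", "resistin"),
                              seed = NULL) {
  with_seed(seed, {
    db <- generate_pathway_db(n_pathways, size_range, n_genes,
                              link_density, overlap)
    gt <- ground_truth(db, design, n_active = n_active, traits = traits,
                       tissues = design_tissues(design),
                       effect_size = effect_size, noise_sd = noise_sd,
                       activity_sd = activity_sd,
                       trait_noise_sd = trait_noise_sd)
    # planted co-active pathways must be detectable: make consecutive
    # planted pairs curated-linked
    active <- sort(unique(unlist(gt$active_pathways, use.names = FALSE)))
    if (length(active) >= 2) {
      extra <- data.frame(from = active[-length(active)], to = active[-1L],
                          stringsAsFactors = FALSE)
      db$links <- normalize_links(rbind(db$links, extra))
    }
    net <- generate_gene_network(db, within_prob, cross_prob)
    exprs <- generate_expression(db, design, gt)
    pci <- pci_matrix(exprs, db, net)
    tr <- generate_traits(design, pci, gt)
    list(design = design, pathway_db = db, gene_network = net,
         exprs = exprs, pci = pci, traits = tr, ground_truth = gt)
  })
}
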