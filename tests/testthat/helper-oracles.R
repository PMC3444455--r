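# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately take the slow, literal route.

# PCI by explicit double loop over ordered pairs i <= j.
naive_pci <- function(h, members, A, include_diagonal = TRUE,
                      normalization = "size") {
  members <- intersect(members, names(h))
  N <- length(members)
  tot <- 0
  n_terms <- 0
  for (ii in seq_len(N)) {
    for (jj in ii:N) {
      if (ii == jj && !include_diagonal) next
      a <- if (ii == jj) 1 else A[members[ii], members[jj]]
      n_terms <- n_terms + 1
      hi <- h[[members[ii]]]; hj <- h[[members[jj]]]
      s <- hi + hj
      sgn <- if (s > 0) 1 else if (s < 0) -1 else 0
      tot <- tot + sgn * sqrt(abs(hi)) * a * sqrt(abs(hj))
    }
  }
  div <- if (normalization == "size") N else n_terms
  tot / div
}

# Spearman via hand-computed mid-ranks and the Pearson formula.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Betweenness via Floyd-Warshall distances plus layer-by-layer geodesic
# counting: node v scores sum over unordered pairs (s, t), s,t != v, of
# sigma_st(v) / sigma_st.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n); diag(d) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el)))
    d[el[k, 1], el[k, 2]] <- d[el[k, 2], el[k, 1]] <- 1
  for (m in seq_len(n))
    for (s in seq_len(n))
      for (t in seq_len(n))
        if (d[s, m] + d[m, t] < d[s, t]) d[s, t] <- d[s, m] + d[m, t]
  # sigma_st = sum of sigma_s,pred over predecessors of t (neighbors one
  # step closer to s); filling by increasing distance makes this exact
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (dist in seq_len(maxd)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (d[s, t] != dist) next
      if (dist == 1) { sigma[s, t] <- 1; next }
      nb <- which(d[t, ] == 1)
      sigma[s, t] <- sum(sigma[s, nb[d[s, nb] == dist - 1]])
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  stats::setNames(b, igraph::V(g)$name)
}

# Trait-linking classes by exhaustive enumeration of (node, trait pair,
# neighbor, neighbor) tuples, straight from the three verbal rules.
brute_linking <- function(relevant, g) {
  nodes <- sort(unique(c(igraph::V(g)$name,
                         unlist(relevant, use.names = FALSE))))
  traits <- names(relevant)
  rel_to <- function(v, tr) v %in% relevant[[tr]]
  nbr <- function(v) {
    if (!(v %in% igraph::V(g)$name)) return(character())
    names(igraph::neighbors(g, v))
  }
  direct <- character(); path2 <- character(); path3 <- character()
  for (v in nodes) {
    for (xi in seq_along(traits)) {
      for (yi in seq_along(traits)) {
        if (xi == yi) next
        X <- traits[xi]; Y <- traits[yi]
        if (rel_to(v, X) && rel_to(v, Y)) direct <- c(direct, v)
        if (rel_to(v, X) && !rel_to(v, Y) &&
            any(vapply(nbr(v), rel_to, TRUE, tr = Y)))
          path2 <- c(path2, v)
        if (xi < yi &&
            any(vapply(nbr(v), rel_to, TRUE, tr = X)) &&
            any(vapply(nbr(v), rel_to, TRUE, tr = Y)))
          path3 <- c(path3, v)
      }
    }
  }
  list(direct = sort(unique(direct)), path2 = sort(unique(path2)),
       path3 = sort(unique(path3)))
}

# Small planted cohort shared by several tests (memoized per seed).
.tiny_cache <- new.env(parent = emptyenv())
tiny_cohort <- function(seed = 1, n_active = 4L) {
  key <- paste0("s", seed, "a", n_active)
  if (is.null(.tiny_cache[[key]]))
    .tiny_cache[[key]] <- synthesize_cohort(
      n_pathways = 12L, n_genes = 150L, size_range = c(4L, 8L),
      tissues = c("adipose", "islet", "liver"),
      n_active = n_active, seed = seed)
  .tiny_cache[[key]]
}

# Random small trait/pathway relevance structure + coordination graph.
random_linking_case <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(4:9, 1)
  nodes <- paste0("pw", seq_len(n_nodes), "|t1")
  traits <- paste0("trait", seq_len(sample(2:4, 1)))
  relevant <- lapply(stats::setNames(traits, traits), function(tr)
    sample(nodes, rbinom(1, n_nodes, 0.3)))
  m <- matrix(runif(n_nodes^2) < 0.35, n_nodes)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  el <- which(m, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]]),
    directed = FALSE, vertices = data.frame(name = nodes))
  list(relevant = relevant, graph = g)
}
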