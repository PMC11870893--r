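# Independent oracles and small random fixtures. Everything here is written
# against the definitions, not against the package internals: exhaustive
# enumeration with raw row scans, dense eigendecompositions, direct linear
# solves, and Monte-Carlo permutation estimates.

# Random transaction database: each prescription gets 1 disease and 1-4
# materials drawn uniformly.
random_db <- function(n_transactions, n_diseases, n_materials, seed) {
  set.seed(seed)
  dis_labels <- sprintf("d%02d", seq_len(n_diseases))
  mat_labels <- sprintf("m%02d", seq_len(n_materials))
  diseases <- lapply(seq_len(n_transactions),
                     function(i) sample(dis_labels, 1))
  materials <- lapply(seq_len(n_transactions),
                      function(i) sample(mat_labels,
                                         sample(seq_len(min(4, n_materials)), 1)))
  transaction_db(sprintf("t%03d", seq_len(n_transactions)),
                 diseases, materials)
}

# Exhaustive frequent-itemset enumeration (sizes 1 and 2) by raw row scans.
oracle_itemsets <- function(db, min_support) {
  n <- length(db$ids)
  has <- function(item) vapply(seq_len(n), function(i)
    item %in% db$diseases[[i]] || item %in% db$materials[[i]], TRUE)
  items <- c(db$disease_catalog, db$material_catalog)
  out <- list()
  for (it in items) {
    cnt <- sum(has(it))
    if (cnt / n >= min_support)
      out[[length(out) + 1]] <- list(items = it, count = cnt)
  }
  if (length(items) >= 2) {
    pairs <- utils::combn(sort(items), 2)
    for (j in seq_len(ncol(pairs))) {
      cnt <- sum(has(pairs[1, j]) & has(pairs[2, j]))
      if (cnt / n >= min_support)
        out[[length(out) + 1]] <- list(items = pairs[, j], count = cnt)
    }
  }
  out
}

# Exhaustive disease => material rule enumeration with direct counting.
oracle_rules <- function(db, min_support, min_confidence) {
  n <- length(db$ids)
  rows <- list()
  for (d in db$disease_catalog) {
    in_d <- vapply(db$diseases, function(x) d %in% x, TRUE)
    for (m in db$material_catalog) {
      in_m <- vapply(db$materials, function(x) m %in% x, TRUE)
      n_both <- sum(in_d & in_m)
      n_ante <- sum(in_d)
      n_cons <- sum(in_m)
      if (n_both == 0) next
      support <- n_both / n
      confidence <- n_both / n_ante
      if (support >= min_support && confidence >= min_confidence)
        rows[[length(rows) + 1]] <- data.frame(
          disease = d, material = m, n_both = n_both, n_disease = n_ante,
          n_material = n_cons, n_total = n, support = support,
          confidence = confidence,
          lift = confidence / (n_cons / n), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$disease, -out$confidence, -out$lift, out$material), ]
  rownames(out) <- NULL
  out
}

# Principal eigenvector by dense eigendecomposition, L2-normalized and
# non-negative, restricted to the largest connected component.
oracle_eigenvector <- function(g) {
  comps <- igraph::components(g)
  main <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == main))
  A <- as.matrix(igraph::as_adjacency_matrix(sub))
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  out[rownames(A)] <- v / sqrt(sum(v^2))
  out
}

# RWR stationary distribution by direct linear solve, with dangling columns
# redirected to the seed distribution.
oracle_rwr <- function(g, p0, r) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (!is.null(igraph::E(g)$weight)) "weight" else NULL))
  cs <- colSums(A)
  W <- A
  for (j in seq_along(cs)) {
    W[, j] <- if (cs[j] == 0) p0 else A[, j] / cs[j]
  }
  p <- solve(diag(length(p0)) - (1 - r) * W, r * p0)
  stats::setNames(as.numeric(p), igraph::V(g)$name)
}

# Random undirected simple graph that always has at least one edge.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Monte-Carlo estimate of P(overlap >= k) drawing n from a universe of size
# N containing K marked genes.
oracle_overlap_tail <- function(k, K, n, N, n_draws, seed) {
  set.seed(seed)
  hits <- vapply(seq_len(n_draws), function(i)
    sum(sample.int(N, n) <= K) >= k, TRUE)
  mean(hits)
}
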