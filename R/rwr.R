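# Random walk with restart over a typed heterogeneous network
# (protein / compound / disease nodes; ppi / compound-target / target-disease
# edges). The walker follows edges with probability 1 - r and teleports back
# to the seed distribution with probability r; the stationary distribution
# scores every node's proximity to the seeds, and disease nodes are ranked
# by it.

ALLOWED_EDGE_TYPES <- list(
  ppi = c("protein", "protein"),
  compound_target = c("compound", "protein"),
  target_disease = c("protein", "disease"))

#' Construct a heterogeneous compound-target-disease network
#'
#' Nodes carry a type in \{protein, compound, disease\}; undirected weighted
#' edges carry a type in \{ppi, compound_target, target_disease\} and must
#' connect the node types that edge type allows. Weights must be positive.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `from`, `to`, `type` and optional
#'   `weight` (default 1).
#' @return A list of class `het_network` with `nodes`, `edges` and the
#'   underlying [igraph::igraph] as `graph`.
#' @export
het_network <- function(nodes, edges) {
  stopifnot(all(c("id", "type") %in% names(nodes)),
            all(c("from", "to", "type") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop_tmnet("duplicate node ids", "tmnet_validation_error")
  if (!all(nodes$type %in% c("protein", "compound", "disease")))
    stop_tmnet("node types must be protein/compound/disease",
               "tmnet_validation_error")
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$weight <= 0))
    stop_tmnet("edge weights must be > 0", "tmnet_validation_error")
  type_of <- stats::setNames(nodes$type, nodes$id)
  for (i in seq_len(nrow(edges))) {
    et <- edges$type[i]
    allowed <- ALLOWED_EDGE_TYPES[[et]]
    if (is.null(allowed))
      stop_tmnet(sprintf("unknown edge type '%s'", et),
                 "tmnet_validation_error")
    endpoints <- sort(c(type_of[[edges$from[i]]], type_of[[edges$to[i]]]))
    if (!identical(endpoints, sort(allowed)))
      stop_tmnet(sprintf(
        "edge %s--%s: endpoint types (%s) not allowed for '%s'",
        edges$from[i], edges$to[i], paste(endpoints, collapse = ","), et),
        "tmnet_validation_error")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight", "type")], directed = FALSE,
    vertices = nodes[, c("id", "type")])
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "het_network")
}

#' Read a heterogeneous network from node and edge TSV files
#'
#' @param node_path TSV with columns `id`, `type`.
#' @param edge_path TSV with columns `from`, `to`, `type`, optional `weight`.
#' @return A [het_network()].
#' @export
read_het_network <- function(node_path, edge_path) {
  het_network(read_tsv(node_path), read_tsv(edge_path))
}

#' Seed (restart) distribution over network nodes
#'
#' Uniform over the given seed nodes unless explicit weights are supplied;
#' always normalized to sum to 1.
#'
#' @param network A `het_network` or igraph object.
#' @param seeds Character vector of seed node ids.
#' @param weights Optional positive weights, one per seed.
#' @return Named numeric vector over all network nodes, summing to 1.
#' @export
seed_vector <- function(network, seeds, weights = NULL) {
  g <- if (inherits(network, "het_network")) network$graph else network
  ids <- igraph::V(g)$name
  seeds <- as.character(seeds)
  missing <- setdiff(seeds, ids)
  if (length(missing) > 0)
    stop_tmnet(sprintf("seed(s) not in network: %s",
                       paste(utils::head(missing, 5), collapse = ", ")),
               "tmnet_validation_error")
  if (is.null(weights)) weights <- rep(1, length(seeds))
  stopifnot(length(weights) == length(seeds), all(weights > 0))
  p0 <- stats::setNames(numeric(length(ids)), ids)
  p0[seeds] <- weights / sum(weights)
  p0
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) * W p + r * p0` with `W` the column-normalized
#' (weighted) adjacency matrix, until the L1 change between iterates falls
#' below `tol`. Probability mass arriving at a dangling node (no edges) is
#' redirected to the seed distribution, so the score vector remains a
#' probability distribution at every iteration.
#'
#' @param network A `het_network` or igraph object.
#' @param seeds A seed distribution from [seed_vector()] (or a character
#'   vector of seed ids, which is passed through `seed_vector`).
#' @param restart Restart probability r in (0, 1] (default 0.7).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A list of class `rwr_scores`: `scores` (named, sums to 1),
#'   `iterations`, `residual`, `restart`.
#' @export
rwr <- function(network, seeds, restart = 0.7, tol = 1e-10,
                max_iter = 10000) {
  stopifnot(restart > 0, restart <= 1)
  g <- if (inherits(network, "het_network")) network$graph else network
  if (is.character(seeds)) seeds <- seed_vector(g, seeds)
  ids <- igraph::V(g)$name
  stopifnot(length(seeds) == length(ids))
  p0 <- as.numeric(seeds[ids])
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop_tmnet("seed vector must be a probability distribution",
               "tmnet_validation_error")
  adj <- igraph::as_adjacency_matrix(g, attr = if (!is.null(igraph::E(g)$weight))
    "weight" else NULL, sparse = TRUE)
  colsum <- Matrix::colSums(adj)
  dangling <- colsum == 0
  inv <- ifelse(dangling, 0, 1 / colsum)
  W <- adj %*% Matrix::Diagonal(x = inv)
  p <- p0
  for (it in seq_len(max_iter)) {
    walked <- as.numeric(W %*% p) + sum(p[dangling]) * p0
    p_new <- (1 - restart) * walked + restart * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (resid < tol)
      return(structure(list(scores = stats::setNames(p, ids),
                            iterations = it, residual = resid,
                            restart = restart),
                       class = "rwr_scores"))
  }
  stop_tmnet(sprintf("RWR did not converge in %d iterations (residual %.3g)",
                     max_iter, resid), "tmnet_convergence_error")
}

#' Rank disease nodes by RWR score
#'
#' Keeps only disease-type nodes, sorted by descending stationary score;
#' exact ties are broken lexicographically and flagged.
#'
#' @param scores An `rwr_scores` object.
#' @param network The `het_network` the scores were computed on.
#' @return data.frame with columns `disease`, `score`, `rank`, `tied`.
#' @export
rank_diseases <- function(scores, network) {
  stopifnot(inherits(network, "het_network"))
  dis <- network$nodes$id[network$nodes$type == "disease"]
  if (length(dis) == 0) {
    warning("no disease nodes in network")
    return(data.frame(disease = character(), score = numeric(),
                      rank = integer(), tied = logical()))
  }
  s <- scores$scores[dis]
  ord <- order(-s, dis)
  out <- data.frame(disease = dis[ord], score = as.numeric(s[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  out
}
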