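# Multi-source PPI assembly and dual-centrality hub extraction. Sources are
# plain edge lists; the merged network is simple and undirected (directed
# records are symmetrized, self-loops dropped, unordered duplicates
# collapsed with their provenance tags concatenated).

#' Merge tagged PPI edge lists into one simple undirected network
#'
#' Accepts file paths (TSV with columns `node_a`, `node_b`, optional
#' `source`) or data.frames with those columns. Order of sources does not
#' affect the result. Self-loops are dropped with a message; duplicate
#' unordered pairs across sources are collapsed, retaining all source tags
#' as a `sources` edge attribute (`;`-joined, sorted).
#'
#' @param edge_lists List of paths and/or data.frames.
#' @return An undirected simple [igraph::igraph] with edge attribute
#'   `sources`.
#' @export
merge_ppi_sources <- function(edge_lists) {
  if (!is.list(edge_lists) || inherits(edge_lists, "data.frame"))
    edge_lists <- list(edge_lists)
  parts <- lapply(seq_along(edge_lists), function(i) {
    el <- edge_lists[[i]]
    if (is.character(el) && length(el) == 1) {
      tag <- sub("\\.[^.]*$", "", basename(el))
      df <- read_tsv(el)
    } else {
      tag <- paste0("source", i)
      df <- as.data.frame(el, stringsAsFactors = FALSE)
    }
    if (!all(c("node_a", "node_b") %in% names(df)))
      stop_tmnet(sprintf("edge list %d: need columns node_a, node_b", i),
                 "tmnet_format_error")
    bad <- which(is.na(df$node_a) | is.na(df$node_b) |
                   !nzchar(df$node_a) | !nzchar(df$node_b))
    if (length(bad) > 0)
      stop_tmnet(sprintf("edge list %d, line %d: malformed record",
                         i, bad[1] + 1L),
                 "tmnet_parse_error")
    data.frame(node_a = as.character(df$node_a),
               node_b = as.character(df$node_b),
               source = if ("source" %in% names(df))
                 as.character(df$source) else tag,
               stringsAsFactors = FALSE)
  })
  all_edges <- do.call(rbind, parts)
  loops <- all_edges$node_a == all_edges$node_b
  if (any(loops)) {
    message(sprintf("merge_ppi_sources: dropped %d self-loop(s)", sum(loops)))
    all_edges <- all_edges[!loops, , drop = FALSE]
  }
  # canonical unordered orientation, then collapse duplicates
  a <- pmin(all_edges$node_a, all_edges$node_b)
  b <- pmax(all_edges$node_a, all_edges$node_b)
  key <- paste(a, b, sep = "\r")
  src <- vapply(split(all_edges$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), "")
  first <- !duplicated(key)
  edges <- data.frame(from = a[first], to = b[first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  edges$sources <- src[paste(edges$from, edges$to, sep = "\r")]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Degree and eigenvector centrality
#'
#' Degree is the raw incident-edge count (not normalized). Eigenvector
#' centrality is computed by power iteration on the adjacency matrix of the
#' largest connected component, L2-normalized; nodes outside that component
#' score 0. Iteration stops when successive normalized vectors differ by
#' less than `tol` in L2 norm.
#'
#' @param g An undirected igraph network with at least one edge.
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Maximum power iterations (default 10000).
#' @return A data.frame of class `centrality_report` with columns `node`,
#'   `degree`, `eigenvector`.
#' @export
centrality <- function(g, tol = 1e-10, max_iter = 10000) {
  if (igraph::ecount(g) == 0)
    stop_tmnet("network has no edges", "tmnet_empty_input")
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  main <- which.max(comps$csize)
  in_main <- comps$membership == main
  sub <- igraph::induced_subgraph(g, which(in_main))
  adj <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  ev_main <- power_iteration(adj, tol = tol, max_iter = max_iter)
  ev <- stats::setNames(numeric(length(deg)), names(deg))
  ev[rownames(adj)] <- ev_main
  res <- data.frame(node = names(deg), degree = as.integer(deg),
                    eigenvector = as.numeric(ev),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("centrality_report", class(res))
  res
}

# Principal-eigenvector power iteration on a (sparse) symmetric nonnegative
# matrix; returns the L2-normalized Perron vector, entrywise >= 0. Iterates
# on (A + I): same principal eigenvector on a connected graph, but strictly
# positive spectrum, so bipartite components (eigenvalues +/- lambda) cannot
# make the iteration oscillate.
power_iteration <- function(adj, tol = 1e-10, max_iter = 10000) {
  n <- nrow(adj)
  if (n == 1) return(stats::setNames(1, rownames(adj)))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(adj %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0)
      stop_tmnet("power iteration hit the zero vector", "tmnet_convergence_error")
    w <- w / nw
    if (sqrt(sum((w - v)^2)) < tol) {
      return(stats::setNames(abs(w), rownames(adj)))
    }
    v <- w
  }
  stop_tmnet(sprintf(
    "eigenvector centrality did not converge in %d iterations (residual %.3g)",
    max_iter, sqrt(sum((w - v)^2))), "tmnet_convergence_error")
}

#' Top-percentile centrality thresholds
#'
#' For each fraction f, the threshold is the minimum score attained within
#' the top `ceiling(f * n)` nodes ranked descending; any node at or above
#' the threshold is in the top set (ties keep all tied nodes).
#'
#' @param report A `centrality_report` from [centrality()].
#' @param fractions Numeric fractions (default `c(0.01, 0.05, 0.10)`).
#' @return A data.frame with columns `measure`, `fraction`, `threshold`,
#'   `n_top`.
#' @export
percentile_thresholds <- function(report, fractions = c(0.01, 0.05, 0.10)) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  n <- nrow(report)
  one <- function(scores, measure) {
    sorted <- sort(scores, decreasing = TRUE)
    do.call(rbind, lapply(fractions, function(f) {
      k <- ceiling(f * n)
      thr <- sorted[k]
      data.frame(measure = measure, fraction = f, threshold = thr,
                 n_top = sum(scores >= thr), stringsAsFactors = FALSE)
    }))
  }
  res <- rbind(one(report$degree, "degree"),
               one(report$eigenvector, "eigenvector"))
  rownames(res) <- NULL
  res
}

#' Extract hub targets: top percentile of both centrality measures
#'
#' Hubs are the query targets that fall inside the top-`fraction` sets of
#' both degree and eigenvector centrality (ties at the threshold included).
#' Query ids absent from the network are reported and skipped.
#'
#' @param report A `centrality_report`.
#' @param query_targets Character vector of node ids of interest.
#' @param fraction Top fraction for both measures (default 0.01).
#' @return A list of class `hub_set`: `hubs` (character), `query_targets`
#'   (those present in the network), `fraction`, `thresholds`.
#' @export
extract_hubs <- function(report, query_targets, fraction = 0.01) {
  query_targets <- unique(as.character(query_targets))
  unknown <- setdiff(query_targets, report$node)
  if (length(unknown) > 0) {
    message(sprintf("extract_hubs: %d query id(s) not in network, skipped",
                    length(unknown)))
    query_targets <- setdiff(query_targets, unknown)
  }
  thr <- percentile_thresholds(report, fraction)
  deg_thr <- thr$threshold[thr$measure == "degree"]
  ev_thr <- thr$threshold[thr$measure == "eigenvector"]
  top_deg <- report$node[report$degree >= deg_thr]
  top_ev <- report$node[report$eigenvector >= ev_thr]
  hubs <- sort(intersect(query_targets, intersect(top_deg, top_ev)))
  structure(list(hubs = hubs, query_targets = query_targets,
                 fraction = fraction, thresholds = thr),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d hub(s) of %d query target(s) at top %.0f%%\n",
              length(x$hubs), length(x$query_targets), 100 * x$fraction))
  invisible(x)
}
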