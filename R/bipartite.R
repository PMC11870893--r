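# Disease-material bipartite network built from mined rules, plus the radar
# summary tables (confidence, lift, standardized values) used to compare
# materials within one disease.

#' Build the disease-material bipartite rule network
#'
#' One node per distinct disease or material label, one edge per rule,
#' carrying the rule's lift as `weight` and its confidence as `confidence`.
#' Node attribute `kind` is `"disease"` or `"material"`; `degree` is the
#' incident edge count (so node size in a plot reflects how broadly an item
#' participates in rules).
#'
#' @param rules An `association_rules` data.frame (non-empty).
#' @return An undirected [igraph::igraph] with `type` set for bipartite
#'   layouts (`TRUE` = material).
#' @export
build_rule_network <- function(rules) {
  stopifnot(nrow(rules) > 0)
  diseases <- unique(rules$disease)
  materials <- unique(rules$material)
  verts <- data.frame(
    name = c(diseases, materials),
    kind = rep(c("disease", "material"),
               c(length(diseases), length(materials))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = rules$disease, to = rules$material,
                      weight = rules$lift, confidence = rules$confidence,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::V(g)$type <- igraph::V(g)$kind == "material"
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Radar table for one disease
#'
#' The per-material view behind a radar chart: confidence and lift of every
#' rule for the disease, plus standardized columns for comparison on a
#' common scale. Standardization is within-table: z-scores by default
#' (mean 0, sd 1 across the disease's materials), or min-max scaling to
#' [0, 1]. A zero-variance column standardizes to 0 under either scheme.
#'
#' @param rules An `association_rules` data.frame.
#' @param disease Disease label to summarize.
#' @param scheme `"zscore"` (default) or `"minmax"`.
#' @return A data.frame (`material`, `confidence`, `lift`,
#'   `standardized_confidence`, `standardized_lift`) sorted by descending
#'   confidence, with the scheme recorded in attribute `standardization`.
#' @export
radar_table <- function(rules, disease, scheme = c("zscore", "minmax")) {
  scheme <- match.arg(scheme)
  rows <- rules[rules$disease == disease, , drop = FALSE]
  if (nrow(rows) == 0)
    stop_tmnet(sprintf("no rules for disease '%s'", disease),
               "tmnet_not_found")
  standardize <- function(x) {
    if (length(x) < 2) return(rep(0, length(x)))
    if (scheme == "zscore") {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    } else {
      rng <- range(x)
      if (diff(rng) == 0) rep(0, length(x))
      else (x - rng[1]) / diff(rng)
    }
  }
  out <- data.frame(material = rows$material,
                    confidence = rows$confidence,
                    lift = rows$lift,
                    standardized_confidence = standardize(rows$confidence),
                    standardized_lift = standardize(rows$lift),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$material), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "standardization") <- scheme
  attr(out, "disease") <- disease
  out
}

#' Export a network to GraphML and TSV
#'
#' Writes `<stem>.graphml` plus `<stem>_nodes.tsv` / `<stem>_edges.tsv`.
#'
#' @param g An igraph object.
#' @param stem Output path stem (no extension).
#' @return The three paths, invisibly.
#' @export
export_network <- function(g, stem) {
  graphml <- paste0(stem, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  write_tsv(nodes, paste0(stem, "_nodes.tsv"))
  write_tsv(edges, paste0(stem, "_edges.tsv"))
  invisible(c(graphml, paste0(stem, "_nodes.tsv"), paste0(stem, "_edges.tsv")))
}
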