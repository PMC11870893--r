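# Hypergeometric over-representation analysis of a query gene list against
# GMT gene-set libraries, with Benjamini-Hochberg adjustment. The universe
# defaults to the union of all library members and is configurable to an
# explicit background list.

#' Read a gene-set library from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#' Duplicate members within a set are collapsed; empty sets are skipped with
#' a warning; a duplicated set name is an error.
#'
#' @param path Path to the GMT file.
#' @return A list of class `gene_set_library`: `sets` (named list of
#'   character vectors) and `universe` (union of all members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop_tmnet(sprintf("file not found: %s", path), "tmnet_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 2
  if (any(short))
    stop_tmnet(sprintf("GMT line %d: fewer than 2 fields", which(short)[1]),
               "tmnet_format_error")
  names_ <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names_))
    stop_tmnet(sprintf("duplicate gene-set name '%s'",
                       names_[duplicated(names_)][1]),
               "tmnet_format_error")
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names_
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("skipping %d empty gene set(s): %s", sum(empty),
                    paste(utils::head(names_[empty], 5), collapse = ", ")))
    sets <- sets[!empty]
  }
  gene_set_library(sets)
}

#' Construct a gene-set library from a named list
#'
#' @param sets Named list of character vectors (unique, non-empty names).
#' @param universe Optional explicit background; default is the union of
#'   all set members.
#' @return A `gene_set_library`.
#' @export
gene_set_library <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)), all(lengths(sets) > 0))
  sets <- lapply(sets, unique)
  structure(list(sets = sets,
                 universe = universe %||%
                   unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_library")
}

#' Write a gene-set library to GMT
#'
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$sets), function(nm)
    paste(c(nm, "na", library$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set of size K in a universe of size N, the p-value is the upper
#' tail P(overlap >= k) when drawing the n mapped query genes without
#' replacement. P-values are adjusted across all terms by
#' Benjamini-Hochberg; results are sorted by adjusted then raw p.
#'
#' @param query Character vector of query gene ids.
#' @param library A `gene_set_library`.
#' @return A data.frame of class `enrichment_result` with columns `term`,
#'   `k` (overlap), `K` (set size), `n` (mapped query size), `N` (universe),
#'   `p_value`, `adjusted_p`.
#' @export
ora <- function(query, library) {
  stopifnot(inherits(library, "gene_set_library"))
  query <- unique(as.character(query))
  if (length(query) == 0)
    stop_tmnet("empty query", "tmnet_empty_input")
  universe <- library$universe
  unmapped <- setdiff(query, universe)
  if (length(unmapped) > 0)
    message(sprintf("ora: %d query id(s) outside the universe ignored",
                    length(unmapped)))
  query <- intersect(query, universe)
  if (length(query) == 0)
    stop_tmnet("no query genes map to the universe", "tmnet_empty_input")
  N <- length(universe)
  n <- length(query)
  K <- vapply(library$sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(library$sets, function(s) length(intersect(s, query)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = names(library$sets), k = k, K = K,
                    n = n, N = N, p_value = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$adjusted_p, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Keep significantly enriched terms
#'
#' @param results An `enrichment_result` data.frame.
#' @param alpha Adjusted-p cutoff, inclusive (default 0.05).
#' @return The rows with `adjusted_p <= alpha`.
#' @export
filter_significant <- function(results, alpha = 0.05) {
  out <- results[results$adjusted_p <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
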