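# Reading, validating, filtering and matrix-encoding multicomponent
# prescription records. A prescription is a basket: a set of disease labels
# plus a set of medicinal-material labels; the two namespaces are disjoint.

#' Construct a transaction database of prescriptions
#'
#' A `transaction_db` holds one record per prescription: an id, a non-empty
#' set of disease labels and a non-empty set of medicinal-material labels,
#' together with ordered catalogs of all disease and material labels. Labels
#' are whitespace-normalized; duplicates within a prescription are collapsed.
#' Disease and material namespaces must be disjoint.
#'
#' @param ids Character vector of prescription ids.
#' @param diseases List of character vectors, one per prescription.
#' @param materials List of character vectors, one per prescription.
#' @return An object of class `transaction_db` with elements `ids`,
#'   `diseases`, `materials`, `disease_catalog`, `material_catalog`.
#' @export
transaction_db <- function(ids, diseases, materials) {
  stopifnot(length(ids) == length(diseases),
            length(ids) == length(materials))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop_tmnet("duplicate prescription ids", "tmnet_validation_error")
  diseases <- lapply(diseases, function(x) unique(normalize_label(x)))
  materials <- lapply(materials, function(x) unique(normalize_label(x)))
  n_dis <- lengths(diseases)
  n_mat <- lengths(materials)
  if (any(n_dis == 0))
    stop_tmnet(sprintf("prescription '%s' has an empty disease set",
                       ids[which(n_dis == 0)[1]]),
               "tmnet_validation_error")
  if (any(n_mat == 0))
    stop_tmnet(sprintf("prescription '%s' has an empty material set",
                       ids[which(n_mat == 0)[1]]),
               "tmnet_validation_error")
  disease_catalog <- unique(unlist(diseases, use.names = FALSE))
  material_catalog <- unique(unlist(materials, use.names = FALSE))
  clash <- intersect(disease_catalog, material_catalog)
  if (length(clash) > 0)
    stop_tmnet(sprintf(
      "label(s) appear as both disease and material: %s",
      paste(utils::head(clash, 5), collapse = ", ")),
      "tmnet_namespace_error")
  structure(list(ids = ids, diseases = diseases, materials = materials,
                 disease_catalog = disease_catalog,
                 material_catalog = material_catalog),
            class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf(
    "<transaction_db> %d prescriptions, %d diseases, %d materials\n",
    length(x$ids), length(x$disease_catalog), length(x$material_catalog)))
  invisible(x)
}

#' Read prescription records from a TSV file
#'
#' Expects a UTF-8 tab-separated file with header columns `prescription_id`,
#' `diseases` and `materials`; multi-valued cells are delimited by `";"`
#' (configurable). Labels are whitespace-normalized and duplicates within a
#' cell collapsed.
#'
#' @param path Path to the TSV file.
#' @param sep Cell delimiter for multi-valued fields (default `";"`).
#' @return A [transaction_db()].
#' @export
read_prescriptions <- function(path, sep = ";") {
  if (!file.exists(path))
    stop_tmnet(sprintf("file not found: %s", path), "tmnet_format_error")
  df <- read_tsv(path)
  required <- c("prescription_id", "diseases", "materials")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_tmnet(sprintf("missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "tmnet_format_error")
  split_cell <- function(x) {
    parts <- normalize_label(strsplit(x, sep, fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  }
  diseases <- lapply(as.character(df$diseases), split_cell)
  materials <- lapply(as.character(df$materials), split_cell)
  empty_d <- which(lengths(diseases) == 0)
  if (length(empty_d) > 0)
    stop_tmnet(sprintf("row %d ('%s'): empty disease cell", empty_d[1],
                       df$prescription_id[empty_d[1]]),
               "tmnet_validation_error")
  empty_m <- which(lengths(materials) == 0)
  if (length(empty_m) > 0)
    stop_tmnet(sprintf("row %d ('%s'): empty material cell", empty_m[1],
                       df$prescription_id[empty_m[1]]),
               "tmnet_validation_error")
  transaction_db(df$prescription_id, diseases, materials)
}

#' Write a transaction database to TSV
#'
#' Inverse of [read_prescriptions()]: one row per prescription with
#' `";"`-joined multi-valued cells.
#'
#' @param db A `transaction_db`.
#' @param path Output path.
#' @param sep Cell delimiter (default `";"`).
#' @return The path, invisibly.
#' @export
write_prescriptions <- function(db, path, sep = ";") {
  df <- data.frame(
    prescription_id = db$ids,
    diseases = vapply(db$diseases, paste, "", collapse = sep),
    materials = vapply(db$materials, paste, "", collapse = sep),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Drop rarely prescribed diseases
#'
#' Removes every disease that occurs in fewer than `min_prescriptions`
#' prescriptions, both from the prescriptions and from the catalog;
#' prescriptions left with no disease are dropped. Idempotent at a fixed
#' threshold. Removals are reported via [message()].
#'
#' @param db A `transaction_db`.
#' @param min_prescriptions Minimum number of prescriptions a disease must
#'   occur in to be kept (default 3).
#' @return The filtered `transaction_db`.
#' @export
filter_diseases <- function(db, min_prescriptions = 3) {
  stopifnot(min_prescriptions >= 1)
  counts <- table(unlist(db$diseases, use.names = FALSE))
  keep <- names(counts)[counts >= min_prescriptions]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped) > 0)
    message(sprintf("filter_diseases: removed %d disease(s) below %d prescriptions",
                    length(dropped), min_prescriptions))
  diseases <- lapply(db$diseases, function(x) x[x %in% keep])
  nonempty <- lengths(diseases) > 0
  if (!any(nonempty))
    stop_tmnet("filtering removed all prescriptions", "tmnet_empty_result")
  if (!all(nonempty))
    message(sprintf("filter_diseases: dropped %d prescription(s) left without a disease",
                    sum(!nonempty)))
  transaction_db(db$ids[nonempty], diseases[nonempty],
                 db$materials[nonempty])
}

#' Encode a transaction database as a binary presence/absence matrix
#'
#' Rows are prescriptions; columns are the concatenated disease and material
#' catalogs. Entry `(i, j)` is 1 iff item `j` occurs in prescription `i`.
#' Decoding the matrix with [decode_matrix()] reproduces the database.
#'
#' @param db A `transaction_db`.
#' @return An integer 0/1 matrix of class `binary_matrix` with row names the
#'   prescription ids, column names the item labels, and an `item_kind`
#'   attribute (`"disease"`/`"material"` per column).
#' @export
encode_matrix <- function(db) {
  items <- c(db$disease_catalog, db$material_catalog)
  kind <- rep(c("disease", "material"),
              c(length(db$disease_catalog), length(db$material_catalog)))
  m <- matrix(0L, nrow = length(db$ids), ncol = length(items),
              dimnames = list(db$ids, items))
  for (i in seq_along(db$ids)) {
    m[i, c(db$diseases[[i]], db$materials[[i]])] <- 1L
  }
  structure(m, item_kind = stats::setNames(kind, items),
            class = c("binary_matrix", class(m)))
}

#' Decode a binary matrix back into a transaction database
#'
#' @param m A `binary_matrix` from [encode_matrix()].
#' @return A `transaction_db`; `decode_matrix(encode_matrix(db))` equals `db`.
#' @export
decode_matrix <- function(m) {
  kind <- attr(m, "item_kind")
  items <- colnames(m)
  dis_items <- items[kind == "disease"]
  mat_items <- items[kind == "material"]
  diseases <- unname(apply(m[, dis_items, drop = FALSE], 1,
                           function(r) dis_items[r == 1L], simplify = FALSE))
  materials <- unname(apply(m[, mat_items, drop = FALSE], 1,
                            function(r) mat_items[r == 1L], simplify = FALSE))
  transaction_db(rownames(m), diseases, materials)
}

#' Summarize a transaction database
#'
#' Per-disease prescription counts (descending) plus overall totals, the
#' usual first look at a prescription corpus.
#'
#' @param db A `transaction_db`.
#' @return A list with `totals` (named vector: prescriptions, diseases,
#'   materials) and `disease_frequency` (data.frame `disease`, `n`, sorted
#'   by descending count then label).
#' @export
summarize_db <- function(db) {
  counts <- table(unlist(db$diseases, use.names = FALSE))
  freq <- data.frame(disease = names(counts), n = as.integer(counts),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$n, freq$disease), , drop = FALSE]
  rownames(freq) <- NULL
  list(totals = c(prescriptions = length(db$ids),
                  diseases = length(db$disease_catalog),
                  materials = length(db$material_catalog)),
       disease_frequency = freq)
}
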