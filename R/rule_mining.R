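# Level-wise apriori frequent-itemset search and disease => material rule
# generation. Transactions are sets (presence/absence); dosage is never
# modeled. Rules are restricted to a single-disease antecedent and a
# single-material consequent, the form the prescription corpus supports.

#' Mining configuration
#'
#' Thresholds and rule shape for [apriori()] and [generate_rules()].
#' `min_support` is a fraction of all transactions (default 0.003, i.e.
#' 0.3%); `min_confidence` a fraction of antecedent transactions (default
#' 0.10). Itemsets are searched up to `max_rule_length` items (default 2:
#' one disease plus one material).
#'
#' @param min_support Minimum itemset support, in (0, 1].
#' @param min_confidence Minimum rule confidence, in (0, 1].
#' @param max_rule_length Maximum itemset size (default 2).
#' @return A `mining_config` list.
#' @export
mining_config <- function(min_support = 0.003, min_confidence = 0.10,
                          max_rule_length = 2) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1,
            max_rule_length >= 1)
  structure(list(min_support = min_support,
                 min_confidence = min_confidence,
                 max_rule_length = max_rule_length),
            class = "mining_config")
}

#' Apriori frequent-itemset search
#'
#' Level-wise search in the classic style: frequent 1-itemsets from column
#' counts, then candidate k-itemsets joined from frequent (k-1)-itemsets and
#' pruned by downward closure (any candidate with an infrequent subset is
#' discarded before counting). Returns exactly the itemsets of size up to
#' `config$max_rule_length` with support >= `config$min_support`.
#'
#' @param m A `binary_matrix` from [encode_matrix()].
#' @param config A [mining_config()].
#' @return A data.frame of class `frequent_itemsets` with list-column
#'   `items`, and columns `size`, `count`, `support`.
#' @export
apriori <- function(m, config = mining_config()) {
  if (nrow(m) == 0)
    stop_tmnet("empty transaction matrix", "tmnet_empty_input")
  n <- nrow(m)
  counts1 <- colSums(m)
  freq_items <- colnames(m)[counts1 / n >= config$min_support]
  out <- list(data.frame(
    items = I(as.list(freq_items)),
    size = rep(1L, length(freq_items)),
    count = as.integer(counts1[freq_items]),
    stringsAsFactors = FALSE))
  # level-wise extension; at k = 2 the join of frequent singletons is every
  # pair of frequent items, so closure pruning is implicit and the counting
  # pass is a single cross-product over the frequent-item submatrix
  level_items <- lapply(freq_items, identity)
  k <- 2L
  while (k <= config$max_rule_length && length(level_items) >= 2) {
    if (k == 2L) {
      items2 <- sort(freq_items)
      cp <- crossprod(m[, items2, drop = FALSE])
      ut <- which(upper.tri(cp) & cp / n >= config$min_support,
                  arr.ind = TRUE)
      kept <- lapply(seq_len(nrow(ut)), function(j)
        c(items2[ut[j, 1L]], items2[ut[j, 2L]]))
      counts <- as.integer(cp[ut])
    } else {
      cands <- candidate_join(level_items, k)
      if (length(cands) == 0) break
      kept <- list()
      counts <- integer(0)
      for (cand in cands) {
        cnt <- sum(rowSums(m[, cand, drop = FALSE]) == k)
        if (cnt / n >= config$min_support) {
          kept[[length(kept) + 1L]] <- cand
          counts <- c(counts, cnt)
        }
      }
    }
    if (length(kept) > 0)
      out[[k]] <- data.frame(items = I(kept), size = k,
                             count = as.integer(counts),
                             stringsAsFactors = FALSE)
    level_items <- kept
    k <- k + 1L
  }
  res <- do.call(rbind, out)
  res$support <- res$count / n
  attr(res, "n_transactions") <- n
  class(res) <- c("frequent_itemsets", class(res))
  res
}

# Join sorted frequent (k-1)-itemsets sharing a (k-2)-prefix; prune any
# candidate with an infrequent (k-1)-subset.
candidate_join <- function(level_items, k) {
  level_items <- lapply(level_items, sort)
  keys <- vapply(level_items, paste, "", collapse = "\r")
  cands <- list()
  if (k == 2L) {
    items <- sort(unlist(level_items))
    if (length(items) < 2) return(list())
    idx <- utils::combn(length(items), 2)
    return(lapply(seq_len(ncol(idx)),
                  function(j) items[idx[, j]]))
  }
  prefixes <- vapply(level_items, function(x)
    paste(x[-(k - 1L)], collapse = "\r"), "")
  for (pref in unique(prefixes)) {
    grp <- level_items[prefixes == pref]
    if (length(grp) < 2) next
    lasts <- sort(vapply(grp, function(x) x[k - 1L], ""))
    idx <- utils::combn(length(lasts), 2)
    for (j in seq_len(ncol(idx))) {
      cand <- sort(c(grp[[1]][-(k - 1L)], lasts[idx[, j]]))
      subs <- vapply(seq_len(k), function(i)
        paste(cand[-i], collapse = "\r"), "")
      if (all(subs %in% keys))
        cands[[length(cands) + 1L]] <- cand
    }
  }
  cands
}

#' Rule metrics: support, confidence, lift
#'
#' For a rule X => Y counted over N transactions: support = n_both / N,
#' confidence = n_both / n_ante, lift = confidence / (n_cons / N). Lift 1
#' means the antecedent and consequent are statistically independent; above
#' 1, positive association.
#'
#' @param n_both Transactions containing both X and Y.
#' @param n_ante Transactions containing X.
#' @param n_cons Transactions containing Y.
#' @param n_total Total transactions N.
#' @return A data.frame with columns `support`, `confidence`, `lift`
#'   (vectorized over the count arguments).
#' @export
compute_metrics <- function(n_both, n_ante, n_cons, n_total) {
  if (any(n_ante == 0) || any(n_cons == 0))
    stop_tmnet("metrics undefined for items never observed (zero marginal count)",
               "tmnet_undefined_metric")
  stopifnot(all(n_both <= pmin(n_ante, n_cons)),
            all(n_ante <= n_total), all(n_cons <= n_total))
  confidence <- n_both / n_ante
  data.frame(support = n_both / n_total,
             confidence = confidence,
             lift = confidence / (n_cons / n_total))
}

#' Generate disease => material association rules
#'
#' One rule per frequent \{disease, material\} 2-itemset with confidence at
#' least `config$min_confidence`, with counts and the three metrics. Sorted
#' by disease, then descending confidence, descending lift, material label.
#'
#' @param itemsets `frequent_itemsets` from [apriori()] on the same matrix.
#' @param m The `binary_matrix` the itemsets were mined from.
#' @param config A [mining_config()].
#' @return A data.frame of class `association_rules` with columns `disease`,
#'   `material`, `n_both`, `n_disease`, `n_material`, `n_total`, `support`,
#'   `confidence`, `lift`.
#' @export
generate_rules <- function(itemsets, m, config = mining_config()) {
  kind <- attr(m, "item_kind")
  n <- nrow(m)
  counts1 <- colSums(m)
  pairs <- itemsets[itemsets$size == 2L, , drop = FALSE]
  first <- vapply(pairs$items, `[`, "", 1L)
  second <- vapply(pairs$items, `[`, "", 2L)
  mixed <- which(kind[first] != kind[second])
  if (length(mixed) > 0) {
    d <- ifelse(kind[first[mixed]] == "disease", first[mixed], second[mixed])
    mat <- ifelse(kind[first[mixed]] == "disease", second[mixed], first[mixed])
    res <- data.frame(
      disease = d, material = mat,
      n_both = pairs$count[mixed],
      n_disease = as.integer(counts1[d]),
      n_material = as.integer(counts1[mat]),
      n_total = n, stringsAsFactors = FALSE)
  }
  if (length(mixed) == 0 || nrow(pairs) == 0) {
    res <- data.frame(disease = character(), material = character(),
                      n_both = integer(), n_disease = integer(),
                      n_material = integer(), n_total = integer(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE)
    class(res) <- c("association_rules", class(res))
    return(res)
  }
  res <- cbind(res, compute_metrics(res$n_both, res$n_disease,
                                    res$n_material, res$n_total))
  res <- res[res$confidence >= config$min_confidence, , drop = FALSE]
  res <- res[order(res$disease, -res$confidence, -res$lift, res$material), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("association_rules", class(res))
  res
}

#' Filter rules by support and confidence thresholds
#'
#' Keeps rules whose support and confidence both meet or exceed the
#' configured thresholds (inclusive comparison); input order is preserved.
#'
#' @param rules An `association_rules` data.frame.
#' @param config A [mining_config()].
#' @return The surviving rules.
#' @export
filter_rules <- function(rules, config = mining_config()) {
  keep <- rules$support >= config$min_support &
    rules$confidence >= config$min_confidence
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine association rules from a transaction database
#'
#' Convenience wrapper: encode, run [apriori()], [generate_rules()] and
#' [filter_rules()].
#'
#' @param db A `transaction_db` (or a pre-encoded `binary_matrix`).
#' @param config A [mining_config()].
#' @return An `association_rules` data.frame.
#' @export
mine_rules <- function(db, config = mining_config()) {
  m <- if (inherits(db, "binary_matrix")) db else encode_matrix(db)
  filter_rules(generate_rules(apriori(m, config), m, config), config)
}

#' Render rules the way summary tables print them
#'
#' Support and confidence as percentages at 2 decimals (half-up), lift at 2
#' decimals; internal values stay full precision.
#'
#' @param rules An `association_rules` data.frame.
#' @return A data.frame with `support_pct`, `confidence_pct`, `lift`
#'   rendered at 2 dp alongside the counts.
#' @export
format_rules <- function(rules) {
  data.frame(disease = rules$disease, material = rules$material,
             n_both = rules$n_both, n_disease = rules$n_disease,
             n_material = rules$n_material, n_total = rules$n_total,
             support_pct = round_half_up(100 * rules$support, 2),
             confidence_pct = round_half_up(100 * rules$confidence, 2),
             lift = round_half_up(rules$lift, 2),
             stringsAsFactors = FALSE)
}
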