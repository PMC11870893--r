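# Synthetic generators for every input the pipeline consumes: prescription
# databases with planted disease-material rules, count reconstruction from
# printed (support, confidence, lift) triples, scale-free PPI graphs with
# planted super-hubs, heterogeneous compound-target-disease networks with a
# known disease ordering, and gene-set libraries with a planted enriched
# set. Every generator is a pure function of its arguments plus the seed:
# the same call reproduces byte-identical data. Labels are opaque tokens,
# not real vocabularies.

#' Reconstruct integer counts from printed rule metrics
#'
#' Inverts the support/confidence/lift equations for a rule printed at
#' 2 decimals over `n_total` transactions, rounding half-up sequentially:
#' `n_both` from support, then `n_ante` from confidence, then `n_cons` from
#' confidence/lift. The three metrics are recomputed from the integer
#' counts and compared with the inputs at 2 decimals; a deviation beyond
#' 0.005 (percentage points, or lift units) means no integer count triple
#' reproduces the printed row and is an error.
#'
#' @param n_total Total transactions N.
#' @param support_pct Printed support, in percent.
#' @param confidence_pct Printed confidence, in percent.
#' @param lift Printed lift.
#' @return A list: `n_both`, `n_ante`, `n_cons`, and `report` (data.frame
#'   of recomputed metrics and absolute deviations from the inputs).
#' @export
reconstruct_counts <- function(n_total, support_pct, confidence_pct, lift) {
  stopifnot(n_total >= 1, support_pct > 0, confidence_pct > 0, lift > 0)
  n_both <- round_half_up(support_pct / 100 * n_total)
  n_ante <- round_half_up(n_both / (confidence_pct / 100))
  n_cons <- round_half_up((confidence_pct / lift) / 100 * n_total)
  if (n_both > min(n_ante, n_cons) || n_ante > n_total || n_cons > n_total ||
      n_both < 1)
    stop_tmnet(sprintf(
      "infeasible reconstruction: counts (%d, %d, %d) violate count ordering",
      n_both, n_ante, n_cons), "tmnet_infeasible_reconstruction")
  rec <- compute_metrics(n_both, n_ante, n_cons, n_total)
  report <- data.frame(
    metric = c("support_pct", "confidence_pct", "lift"),
    input = c(support_pct, confidence_pct, lift),
    recomputed = c(round_half_up(100 * rec$support, 2),
                   round_half_up(100 * rec$confidence, 2),
                   round_half_up(rec$lift, 2)))
  report$deviation <- abs(report$recomputed - report$input)
  if (any(report$deviation > 0.005))
    stop_tmnet(sprintf(
      "infeasible reconstruction: recomputed %s = %.2f vs input %.2f",
      report$metric[which.max(report$deviation)],
      report$recomputed[which.max(report$deviation)],
      report$input[which.max(report$deviation)]),
      "tmnet_infeasible_reconstruction")
  list(n_both = n_both, n_ante = n_ante, n_cons = n_cons, report = report)
}

#' Configuration for the synthetic prescription generator
#'
#' Defaults emulate the scale of a curated traditional-medicine corpus:
#' 505 prescriptions over 106 diseases and 567 medicinal materials, one
#' disease per prescription, with sparse background material noise.
#'
#' @param n_transactions Number of prescriptions (default 505).
#' @param n_diseases Disease catalog size (default 106).
#' @param n_materials Material catalog size (default 567).
#' @param planted_rules Optional data.frame with columns `disease`,
#'   `material`, `n_both`, `n_ante`, `n_cons`: exact co-occurrence counts to
#'   realize.
#' @param noise_rate Per (transaction, background-material) inclusion
#'   probability (default 0.01).
#' @param seed RNG seed (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_transactions = 505, n_diseases = 106,
                             n_materials = 567, planted_rules = NULL,
                             noise_rate = 0.01, seed = 1) {
  stopifnot(n_transactions >= 1, n_diseases >= 1, n_materials >= 1,
            noise_rate >= 0, noise_rate <= 1)
  if (!is.null(planted_rules))
    stopifnot(all(c("disease", "material", "n_both", "n_ante", "n_cons")
                  %in% names(planted_rules)))
  structure(list(n_transactions = n_transactions, n_diseases = n_diseases,
                 n_materials = n_materials, planted_rules = planted_rules,
                 noise_rate = noise_rate, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic prescription database with planted rules
#'
#' Realizes each planted (disease, material) rule exactly: `n_both`
#' transactions contain both items, `n_ante - n_both` the disease without
#' the material, `n_cons - n_both` the material without the disease (placed
#' in filler transactions that carry non-planted diseases, so planted
#' antecedent counts stay exact). Remaining transactions receive filler
#' diseases and background materials; background noise touches only
#' non-planted materials. One disease per transaction. Deterministic under
#' the config seed.
#'
#' @param config A [generator_config()].
#' @return A `transaction_db`; the planted rules are attached as attribute
#'   `ground_truth`.
#' @export
synth_prescriptions <- function(config = generator_config()) {
  pr <- config$planted_rules
  N <- config$n_transactions
  if (!is.null(pr)) {
    pr$disease <- as.character(pr$disease)
    pr$material <- as.character(pr$material)
    # per-disease antecedent counts must agree across that disease's rules
    for (d in unique(pr$disease)) {
      if (length(unique(pr$n_ante[pr$disease == d])) > 1)
        stop_tmnet(sprintf(
          "planted rules for disease '%s' disagree on n_ante", d),
          "tmnet_infeasibility")
    }
    for (m in unique(pr$material)) {
      if (length(unique(pr$n_cons[pr$material == m])) > 1)
        stop_tmnet(sprintf(
          "planted rules for material '%s' disagree on n_cons", m),
          "tmnet_infeasibility")
    }
    if (any(pr$n_both > pmin(pr$n_ante, pr$n_cons)) || any(pr$n_both < 0))
      stop_tmnet("planted counts violate n_both <= min(n_ante, n_cons)",
                 "tmnet_infeasibility")
  }
  planted_d <- unique(pr$disease)
  planted_m <- unique(pr$material)
  ante_of <- if (is.null(pr)) integer(0) else
    vapply(planted_d, function(d) pr$n_ante[pr$disease == d][1], 0)
  n_block <- sum(ante_of)
  n_filler <- N - n_block
  if (n_filler < 0)
    stop_tmnet(sprintf(
      "planted antecedent counts need %d transactions but N = %d",
      n_block, N), "tmnet_infeasibility")
  # material occurrences outside any planted disease block
  extra_of <- if (is.null(pr)) integer(0) else vapply(planted_m, function(m) {
    rows <- pr[pr$material == m, , drop = FALSE]
    e <- rows$n_cons[1] - sum(rows$n_both)
    if (e < 0)
      stop_tmnet(sprintf(
        "material '%s': planted co-occurrences exceed its total count n_cons",
        m), "tmnet_infeasibility")
    e
  }, 0)
  if (length(extra_of) > 0 && max(extra_of) > n_filler)
    stop_tmnet(sprintf(
      "material extras (max %d) exceed the %d available filler transactions",
      max(extra_of), n_filler), "tmnet_infeasibility")
  if (length(planted_d) > config$n_diseases ||
      length(planted_m) > config$n_materials)
    stop_tmnet("planted labels exceed catalog sizes", "tmnet_infeasibility")
  # planted labels take catalog slots; the pools fill the remainder
  disease_pool <- sprintf("disease_%03d",
                          seq_len(config$n_diseases - length(planted_d)))
  material_pool <- sprintf("material_%03d",
                           seq_len(config$n_materials - length(planted_m)))
  if (n_filler > 0 && length(disease_pool) == 0)
    stop_tmnet("filler transactions need at least one non-planted disease",
               "tmnet_infeasibility")
  if (length(material_pool) == 0)
    stop_tmnet("need at least one non-planted material for fillers",
               "tmnet_infeasibility")
  diseases <- vector("list", N)
  materials <- rep(list(character(0)), N)
  offset <- 0L
  for (d in planted_d) {
    idx <- offset + seq_len(ante_of[[d]])
    diseases[idx] <- list(d)
    rows <- pr[pr$disease == d, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      hit <- offset + seq_len(rows$n_both[j])
      for (i in hit)
        materials[[i]] <- c(materials[[i]], rows$material[j])
    }
    offset <- offset + ante_of[[d]]
  }
  if (n_filler > 0) {
    filler_idx <- offset + seq_len(n_filler)
    diseases[filler_idx] <- as.list(
      rep_len(disease_pool, n_filler))
    for (m in planted_m) {
      e <- extra_of[[m]]
      if (e > 0)
        for (i in filler_idx[seq_len(e)])
          materials[[i]] <- c(materials[[i]], m)
    }
  }
  with_seed(config$seed, {
    # background noise over non-planted materials only
    if (config$noise_rate > 0) {
      for (i in seq_len(N)) {
        n_extra <- stats::rbinom(1, length(material_pool), config$noise_rate)
        if (n_extra > 0)
          materials[[i]] <- c(materials[[i]],
                              sample(material_pool, n_extra))
      }
    }
    # every prescription needs at least one material; cycle the pool so no
    # background material pairs repeatedly with one filler disease
    empty <- which(lengths(materials) == 0)
    if (length(empty) > 0)
      materials[empty] <- as.list(rep_len(material_pool, length(empty)))
    # catalog coverage: park any still-unused pool material in a random
    # prescription so the material catalog has its configured size
    unused <- setdiff(material_pool, unique(unlist(materials)))
    if (length(unused) > 0) {
      host <- sample(N, length(unused), replace = TRUE)
      for (j in seq_along(unused))
        materials[[host[j]]] <- c(materials[[host[j]]], unused[j])
    }
  })
  db <- transaction_db(sprintf("rx_%04d", seq_len(N)), diseases, materials)
  attr(db, "ground_truth") <- pr
  db
}

#' Generate a scale-free PPI network with planted super-hubs
#'
#' Preferential-attachment (Barabasi-Albert) graph over
#' `n_nodes - n_super_hubs` protein nodes, then each planted super-hub is
#' wired to a fixed fraction of them so it lands in the top percentile of
#' both degree and eigenvector centrality. Node names are `P...`; hubs are
#' `HUB...`. Deterministic under `seed`.
#'
#' @param n_nodes Total node count including hubs (default 2000).
#' @param m Edges attached per new node (default 3).
#' @param n_super_hubs Number of planted hubs (default 0).
#' @param hub_fraction Fraction of ordinary nodes each hub wires to
#'   (default 0.2).
#' @param seed RNG seed (default 1).
#' @return An igraph network; planted hub ids in the graph attribute
#'   `ground_truth`.
#' @export
synth_ppi <- function(n_nodes = 2000, m = 3, n_super_hubs = 0,
                      hub_fraction = 0.2, seed = 1) {
  stopifnot(n_nodes > m, m >= 1, n_super_hubs >= 0,
            n_super_hubs < n_nodes)
  n_base <- n_nodes - n_super_hubs
  g <- with_seed(seed, {
    base <- igraph::sample_pa(n_base, power = 1, m = m, directed = FALSE,
                              algorithm = "psumtree")
    igraph::V(base)$name <- sprintf("P%05d", seq_len(n_base))
    if (n_super_hubs > 0) {
      hubs <- sprintf("HUB%02d", seq_len(n_super_hubs))
      base <- igraph::add_vertices(base, n_super_hubs, name = hubs)
      k <- max(1L, floor(hub_fraction * n_base))
      new_edges <- unlist(lapply(hubs, function(h)
        rbind(h, sample(sprintf("P%05d", seq_len(n_base)), k))))
      base <- igraph::add_edges(base, new_edges)
    }
    igraph::simplify(base)
  })
  igraph::graph_attr(g, "ground_truth") <- if (n_super_hubs > 0)
    sprintf("HUB%02d", seq_len(n_super_hubs)) else character(0)
  g
}

#' Generate a heterogeneous compound-target-disease network
#'
#' Wires `n_compounds` compound nodes to random protein targets of a PPI
#' network, and `n_diseases` disease nodes to nested subsets of the
#' compound-target set: disease 1 connects to every target, disease 2 to a
#' subset, and so on down a strict gradient. Because the subsets are
#' nested, proximity to the compound targets decreases strictly down the
#' list, giving a ground-truth disease ordering for propagation tests.
#'
#' @param ppi An igraph protein network (e.g. from [synth_ppi()]).
#' @param n_compounds Number of compound nodes (default 10).
#' @param n_diseases Number of disease nodes (default 8).
#' @param targets_per_compound Targets wired to each compound (default 5).
#' @param seed RNG seed (default 1).
#' @return A list: `network` (a [het_network()]), `seed_targets` (the union
#'   of compound targets), `disease_order` (ids best-first).
#' @export
synth_heterogeneous <- function(ppi, n_compounds = 10, n_diseases = 8,
                                targets_per_compound = 5, seed = 1) {
  proteins <- igraph::V(ppi)$name
  stopifnot(targets_per_compound <= length(proteins), n_diseases >= 1)
  with_seed(seed, {
    compounds <- sprintf("C%03d", seq_len(n_compounds))
    ct <- do.call(rbind, lapply(compounds, function(cp)
      data.frame(from = cp,
                 to = sample(proteins, targets_per_compound),
                 type = "compound_target", stringsAsFactors = FALSE)))
    seed_targets <- sort(unique(ct$to))
    diseases <- sprintf("D%02d", seq_len(n_diseases))
    # nested target subsets: strictly decreasing wiring down the list
    sizes <- pmax(1L, round_half_up(
      length(seed_targets) * rev(seq_len(n_diseases)) / n_diseases))
    td <- do.call(rbind, lapply(seq_len(n_diseases), function(i)
      data.frame(from = seed_targets[seq_len(sizes[i])],
                 to = diseases[i],
                 type = "target_disease", stringsAsFactors = FALSE)))
    ppi_edges <- igraph::as_data_frame(ppi, what = "edges")
    edges <- rbind(
      data.frame(from = ppi_edges$from, to = ppi_edges$to, type = "ppi",
                 stringsAsFactors = FALSE),
      ct, td)
    nodes <- data.frame(
      id = c(proteins, compounds, diseases),
      type = rep(c("protein", "compound", "disease"),
                 c(length(proteins), length(compounds), length(diseases))),
      stringsAsFactors = FALSE)
    list(network = het_network(nodes, edges),
         seed_targets = seed_targets,
         disease_order = diseases)
  })
}

#' Generate a gene-set library with one planted enriched set
#'
#' Random sets over an opaque gene universe, plus a query list constructed
#' to overlap the first ("planted") set by a stated number of genes; the
#' rest of the query is drawn from outside that set.
#'
#' @param universe_size Genes in the universe (default 200).
#' @param n_sets Number of gene sets (default 20).
#' @param set_size Genes per set (default 20).
#' @param query_size Query list length (default 20).
#' @param planted_overlap Query genes inside the planted set (default 15).
#' @param seed RNG seed (default 1).
#' @return A list: `library` (a `gene_set_library`), `query`, and
#'   `planted_term` (the name of the enriched set).
#' @export
synth_gmt <- function(universe_size = 200, n_sets = 20, set_size = 20,
                      query_size = 20, planted_overlap = 15, seed = 1) {
  stopifnot(planted_overlap <= min(set_size, query_size),
            set_size <= universe_size,
            query_size - planted_overlap <= universe_size - set_size)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(universe_size))
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
    names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
    planted <- sets[[1]]
    query <- c(sample(planted, planted_overlap),
               sample(setdiff(genes, planted), query_size - planted_overlap))
    list(library = gene_set_library(sets, universe = genes),
         query = sort(query), planted_term = names(sets)[1])
  })
}

#' Published disease-material rule metrics
#'
#' The bundled table of mined association-rule metrics (support, confidence,
#' lift at 2 decimals) for the ten most frequently treated diseases in a
#' curated Ethiopian traditional-medicine prescription corpus of 505
#' prescriptions. Used with [reconstruct_counts()] and
#' [synth_prescriptions()] to rebuild count-exact transaction databases.
#'
#' @return data.frame with columns `disease`, `material`, `support_pct`,
#'   `confidence_pct`, `lift`.
#' @export
published_rule_metrics <- function() {
  read_tsv(system.file("extdata", "disease_material_rules.tsv",
                       package = "tmnet", mustWork = TRUE))
}
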