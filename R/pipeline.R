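# End-to-end pipeline driver: simulate (optional) -> mine -> network ->
# hubs -> rwr -> enrich, with a resolved config persisted next to the
# outputs for provenance. All tabular outputs are TSV with header; networks
# are exported as GraphML + node/edge TSV. Outputs carry no timestamps, so
# a rerun with the same resolved config is byte-identical.

default_run_config <- function() {
  list(
    out_dir = "tmnet_run",
    stages = c("simulate", "mine", "network", "hubs", "rwr", "enrich"),
    seed = 1,
    prescriptions = NULL,          # path; NULL with "simulate" => generated
    ppi_edges = NULL,              # list of paths; NULL => generated
    gmt = NULL,                    # path; NULL => generated
    query_targets = NULL,          # character vector or path
    min_disease_prescriptions = 3,
    min_support = 0.003,
    min_confidence = 0.10,
    hub_fraction = 0.01,
    restart = 0.7,
    rwr_tol = 1e-10,
    alpha = 0.05,
    sim = list(n_transactions = 505, n_diseases = 106, n_materials = 567,
               noise_rate = 0.01, ppi_nodes = 2000, ppi_m = 3,
               ppi_super_hubs = 5, n_compounds = 10, n_diseases_het = 8))
}

#' Run the full prescription-to-network analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (generate synthetic
#' inputs when no paths are given), `mine` (association rules), `network`
#' (disease-material bipartite network and radar tables), `hubs`
#' (multi-source PPI centrality and hub extraction), `rwr` (disease
#' prioritization on the heterogeneous network) and `enrich`
#' (over-representation analysis). Each stage writes its outputs under
#' `config$out_dir`; the resolved configuration is persisted as
#' `resolved_config.yaml`. A stage failure stops the run with the stage
#' named in the error.
#'
#' @param config A named list overriding the defaults (see
#'   `tmnet:::default_run_config()`), or a path to a YAML file of the same
#'   shape.
#' @return The output directory, invisibly; the resolved config as
#'   attribute `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  # validate referenced inputs before touching the output directory, so a
  # bad path fails cleanly with no partial outputs
  for (p in c(cfg$prescriptions, unlist(cfg$ppi_edges), cfg$gmt)) {
    if (is.character(p) && !file.exists(p))
      stop_tmnet(sprintf("input file not found: %s", p),
                 "tmnet_format_error")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  note <- function(...) {
    line <- sprintf(...)
    writeLines(line, log_con)
    message("tmnet: ", line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  want <- function(s) s %in% cfg$stages

  db <- ppi <- het <- gmt_lib <- query <- rules <- NULL

  if (want("simulate") || want("mine")) {
    db <- stage("input", {
      if (!is.null(cfg$prescriptions)) {
        read_prescriptions(cfg$prescriptions)
      } else {
        sim_cfg <- generator_config(
          n_transactions = cfg$sim$n_transactions,
          n_diseases = cfg$sim$n_diseases,
          n_materials = cfg$sim$n_materials,
          planted_rules = cfg$sim$planted_rules,
          noise_rate = cfg$sim$noise_rate, seed = cfg$seed)
        db <- synth_prescriptions(sim_cfg)
        write_prescriptions(db, file.path(cfg$out_dir, "prescriptions.tsv"))
        db
      }
    })
    note("input: %d prescriptions, %d diseases, %d materials",
         length(db$ids), length(db$disease_catalog),
         length(db$material_catalog))
  }

  if (want("mine")) {
    rules <- stage("mine", {
      db_f <- suppressMessages(
        filter_diseases(db, cfg$min_disease_prescriptions))
      mcfg <- mining_config(cfg$min_support, cfg$min_confidence)
      mine_rules(db_f, mcfg)
    })
    write_tsv(format_rules(rules), file.path(cfg$out_dir, "rules.tsv"))
    jsonlite::write_json(format_rules(rules),
                         file.path(cfg$out_dir, "rules.json"),
                         digits = NA)
    s <- summarize_db(db)
    jsonlite::write_json(list(totals = as.list(s$totals),
                              disease_frequency = s$disease_frequency),
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("mine: %d rules above support %.4f / confidence %.2f",
         nrow(rules), cfg$min_support, cfg$min_confidence)
  }

  if (want("network")) {
    stage("network", {
      if (is.null(rules) || nrow(rules) == 0)
        stop("no rules to build the bipartite network from")
      g <- build_rule_network(rules)
      export_network(g, file.path(cfg$out_dir, "bipartite"))
      for (d in unique(rules$disease)) {
        rt <- radar_table(rules, d)
        safe <- gsub("[^A-Za-z0-9_-]+", "_", d)
        write_tsv(rt, file.path(cfg$out_dir,
                                sprintf("radar_%s.tsv", safe)))
      }
      note("network: %d nodes, %d edges",
           igraph::vcount(g), igraph::ecount(g))
    })
  }

  report <- NULL
  if (want("hubs") || want("rwr")) {
    ppi <- stage("ppi", {
      if (!is.null(cfg$ppi_edges)) {
        merge_ppi_sources(as.list(cfg$ppi_edges))
      } else {
        g <- synth_ppi(n_nodes = cfg$sim$ppi_nodes, m = cfg$sim$ppi_m,
                       n_super_hubs = cfg$sim$ppi_super_hubs,
                       seed = cfg$seed)
        export_network(g, file.path(cfg$out_dir, "ppi"))
        g
      }
    })
  }

  if (want("hubs")) {
    stage("hubs", {
      report <- centrality(ppi)
      write_tsv(report, file.path(cfg$out_dir, "centrality.tsv"))
      write_tsv(percentile_thresholds(report),
                file.path(cfg$out_dir, "centrality_thresholds.tsv"))
      query <- resolve_query_targets(cfg, ppi)
      hs <- extract_hubs(report, query, cfg$hub_fraction)
      write_tsv(data.frame(hub = hs$hubs),
                file.path(cfg$out_dir, "hubs.tsv"))
      note("hubs: %d of %d query targets in top %.0f%% of both centralities",
           length(hs$hubs), length(hs$query_targets),
           100 * cfg$hub_fraction)
    })
  }

  if (want("rwr")) {
    stage("rwr", {
      synth <- synth_heterogeneous(ppi, n_compounds = cfg$sim$n_compounds,
                                   n_diseases = cfg$sim$n_diseases_het,
                                   seed = cfg$seed)
      het <- synth$network
      seeds <- seed_vector(het, synth$seed_targets)
      sc <- rwr(het, seeds, restart = cfg$restart, tol = cfg$rwr_tol)
      write_tsv(data.frame(node = names(sc$scores),
                           score = as.numeric(sc$scores)),
                file.path(cfg$out_dir, "rwr_scores.tsv"))
      ranking <- rank_diseases(sc, het)
      write_tsv(ranking, file.path(cfg$out_dir, "rwr_ranking.tsv"))
      note("rwr: converged in %d iterations (restart %.2f), %d diseases ranked",
           sc$iterations, cfg$restart, nrow(ranking))
    })
  }

  if (want("enrich")) {
    stage("enrich", {
      if (!is.null(cfg$gmt)) {
        gmt_lib <- read_gmt(cfg$gmt)
        q <- resolve_query_genes(cfg)
      } else {
        synth <- synth_gmt(seed = cfg$seed)
        gmt_lib <- synth$library
        q <- synth$query
        write_gmt(gmt_lib, file.path(cfg$out_dir, "genesets.gmt"))
      }
      res <- ora(q, gmt_lib)
      write_tsv(res, file.path(cfg$out_dir, "enrichment.tsv"))
      sig <- filter_significant(res, cfg$alpha)
      write_tsv(sig, file.path(cfg$out_dir, "enrichment_significant.tsv"))
      note("enrich: %d of %d terms significant at adjusted p <= %.2f",
           nrow(sig), nrow(res), cfg$alpha)
    })
  }

  invisible(structure(cfg$out_dir, config = cfg))
}

resolve_query_targets <- function(cfg, ppi) {
  if (!is.null(cfg$query_targets)) {
    q <- cfg$query_targets
    if (is.character(q) && length(q) == 1 && file.exists(q))
      q <- readLines(q, warn = FALSE)
    return(q[nzchar(q)])
  }
  # synthetic default: planted hubs plus a deterministic sample of others
  truth <- igraph::graph_attr(ppi, "ground_truth") %||% character(0)
  others <- setdiff(igraph::V(ppi)$name, truth)
  with_seed(cfg$seed, c(truth, sample(others, min(25, length(others)))))
}

resolve_query_genes <- function(cfg) {
  q <- cfg$query_targets
  if (is.null(q))
    stop_tmnet("enrich stage with an explicit GMT needs query_targets",
               "tmnet_validation_error")
  if (is.character(q) && length(q) == 1 && file.exists(q))
    q <- readLines(q, warn = FALSE)
  q[nzchar(q)]
}
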