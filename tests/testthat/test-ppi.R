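# Multi-source merge, centrality measures and hub extraction.

test_that("merge deduplicates unordered pairs, drops self-loops, keeps provenance", {
  s1 <- data.frame(node_a = c("a", "x"), node_b = c("b", "y"))
  s2 <- data.frame(node_a = c("b", "a"), node_b = c("a", "a"))
  g <- suppressMessages(merge_ppi_sources(list(s1, s2)))
  expect_equal(igraph::ecount(g), 2)  # (a,b) collapsed, (a,a) dropped
  expect_equal(igraph::vcount(g), 4)
  ab <- igraph::E(g)$sources[
    apply(igraph::ends(g, igraph::E(g)), 1, function(e)
      setequal(e, c("a", "b")))]
  expect_identical(ab, "source1;source2")
  expect_message(merge_ppi_sources(list(s2)), "self-loop")
})

test_that("merge is order-independent and matches a set-union oracle", {
  set.seed(31)
  mk <- function(n) data.frame(
    node_a = sprintf("n%d", sample(30, n, replace = TRUE)),
    node_b = sprintf("n%d", sample(30, n, replace = TRUE)))
  srcs <- list(mk(40), mk(40), mk(40))
  canon <- function(df) {
    df <- df[df$node_a != df$node_b, ]
    unique(paste(pmin(df$node_a, df$node_b),
                 pmax(df$node_a, df$node_b)))
  }
  want <- unique(unlist(lapply(srcs, canon)))
  g1 <- suppressMessages(merge_ppi_sources(srcs))
  g2 <- suppressMessages(merge_ppi_sources(rev(srcs)))
  expect_equal(igraph::ecount(g1), length(want))
  # permuting sources yields the identical network
  expect_identical(igraph::as_data_frame(g1)[, c("from", "to")],
                   igraph::as_data_frame(g2)[, c("from", "to")])
  # degree sum identity
  expect_equal(sum(igraph::degree(g1)), 2 * igraph::ecount(g1))
})

test_that("merge reads tagged TSV edge files and flags malformed records", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "alpha.tsv")
  write.table(data.frame(node_a = "p1", node_b = "p2"), f1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- merge_ppi_sources(list(f1))
  expect_identical(igraph::E(g)$sources, "alpha")
  f2 <- file.path(dir, "bad.tsv")
  writeLines(c("node_a\tnode_b", "p1\t"), f2)
  expect_error(merge_ppi_sources(list(f2)), class = "tmnet_parse_error")
})

test_that("centrality matches symmetry expectations on star and complete graphs", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- c("hub", sprintf("leaf%d", 1:5))
  rep <- centrality(star)
  expect_identical(rep$degree[rep$node == "hub"], 5L)
  expect_identical(rep$node[which.max(rep$eigenvector)], "hub")
  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- sprintf("v%d", 1:10)
  rep <- centrality(k10)
  expect_equal(rep$eigenvector, rep(rep$eigenvector[1], 10))
  expect_equal(sum(rep$eigenvector^2), 1)  # L2 normalization
})

test_that("power-iteration eigenvector matches a dense eigen-oracle", {
  for (seed in 1:12) {
    g <- random_graph(sample(10:50, 1), 0.15, seed = seed)
    got <- centrality(g)
    want <- oracle_eigenvector(g)
    expect_equal(stats::setNames(got$eigenvector, got$node)[names(want)],
                 want, tolerance = 1e-6)
    expect_identical(got$degree,
                     as.integer(igraph::degree(g)[got$node]))
  }
})

test_that("percentile thresholds follow the ceiling rank with ties included", {
  rep <- data.frame(node = sprintf("n%03d", 1:100), degree = 1:100,
                    eigenvector = (1:100) / sqrt(sum((1:100)^2)))
  class(rep) <- c("centrality_report", class(rep))
  thr <- percentile_thresholds(rep, c(0.01, 0.05, 0.10))
  dthr <- thr[thr$measure == "degree", ]
  expect_equal(dthr$threshold[dthr$fraction == 0.10], 91)
  expect_equal(dthr$threshold[dthr$fraction == 0.01], 100)
  # 20 tied top scores at f = 0.01: the whole tie block is in the top set
  rep2 <- data.frame(node = sprintf("n%03d", 1:100),
                     degree = c(rep(50L, 20), sample(1:40, 80, replace = TRUE)),
                     eigenvector = rep(0.1, 100))
  class(rep2) <- c("centrality_report", class(rep2))
  thr2 <- percentile_thresholds(rep2, 0.01)
  expect_equal(thr2$n_top[thr2$measure == "degree"], 20)
  # random reports match a full-sort oracle
  set.seed(4)
  rep3 <- data.frame(node = sprintf("n%03d", 1:57),
                     degree = sample(200, 57, replace = TRUE),
                     eigenvector = runif(57))
  class(rep3) <- c("centrality_report", class(rep3))
  thr3 <- percentile_thresholds(rep3, c(0.05, 0.10))
  for (f in c(0.05, 0.10)) {
    k <- ceiling(f * 57)
    expect_equal(
      thr3$threshold[thr3$measure == "degree" & thr3$fraction == f],
      as.numeric(sort(rep3$degree, decreasing = TRUE)[k]))
  }
})

test_that("hub extraction intersects both top sets and is monotone in fraction", {
  rep <- data.frame(node = c("both", "deg_only", "ev_only", "neither",
                             sprintf("bg%02d", 1:46)),
                    degree = c(100L, 99L, 1L, 1L, rep(10L, 46)),
                    eigenvector = c(0.9, 0.01, 0.89, 0.01, rep(0.1, 46)))
  class(rep) <- c("centrality_report", class(rep))
  hs <- extract_hubs(rep, c("both", "deg_only", "ev_only", "neither"),
                     fraction = 0.04)
  expect_identical(hs$hubs, "both")
  expect_identical(extract_hubs(rep, character(0))$hubs, character(0))
  expect_message(extract_hubs(rep, c("both", "ghost")), "not in network")
  # monotone: smaller fraction's hubs are a subset of a larger fraction's
  g <- synth_ppi(400, 3, n_super_hubs = 3, seed = 9)
  rep <- centrality(g)
  q <- igraph::V(g)$name[1:50]
  h1 <- extract_hubs(rep, q, 0.01)$hubs
  h2 <- extract_hubs(rep, q, 0.05)$hubs
  expect_true(all(h1 %in% h2))
})

test_that("planted super-hubs are recovered exactly from a 2000-node scale-free graph", {
  g <- synth_ppi(2000, 3, n_super_hubs = 5, seed = 17)
  truth <- igraph::graph_attr(g, "ground_truth")
  rep <- centrality(g)
  # background query ids drawn from late (low-degree) attachment nodes
  query <- c(truth, sprintf("P%05d", seq(1200, 1960, by = 40)))
  hs <- extract_hubs(rep, query, fraction = 0.01)
  expect_identical(hs$hubs, sort(truth))
})
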