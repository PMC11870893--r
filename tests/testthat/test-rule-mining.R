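# Apriori mining and rule metrics against exhaustive-enumeration oracles
# and hand-checked count triples.

test_that("metric equations hold on hand-checked count triples", {
  # universal item: support 1, and a universal consequent forces lift 1
  m <- compute_metrics(5, 5, 20, 20)
  expect_equal(m$confidence, 1)
  expect_equal(m$lift, 1)
  # back-solved triple: confidence 43.75%, lift 4.80
  m <- compute_metrics(7, 16, 46, 505)
  expect_equal(round_half_up(100 * m$confidence, 2), 43.75)
  expect_equal(round_half_up(m$lift, 2), 4.80)
  # back-solved triple: lift 36.07 from (2, 14, 2, 505)
  m <- compute_metrics(2, 14, 2, 505)
  expect_equal(round_half_up(100 * m$confidence, 2), 14.29)
  expect_equal(round_half_up(m$lift, 2), 36.07)
  # undefined for never-observed items
  expect_error(compute_metrics(0, 0, 5, 10),
               class = "tmnet_undefined_metric")
})

test_that("apriori finds universal singletons and errors on empty input", {
  db <- transaction_db(c("a", "b"), list("d1", "d1"), list("m1", "m2"))
  m <- encode_matrix(db)
  fi <- apriori(m, mining_config(min_support = 0.5))
  singles <- fi[fi$size == 1, ]
  expect_equal(singles$support[match("d1", unlist(singles$items))], 1.0)
  expect_error(apriori(m[0, , drop = FALSE]), class = "tmnet_empty_input")
})

test_that("miner output is identical to exhaustive pair enumeration", {
  for (seed in 1:25) {
    db <- random_db(n_transactions = sample(10:60, 1),
                    n_diseases = sample(3:6, 1),
                    n_materials = sample(4:10, 1), seed = seed)
    cfg <- mining_config(min_support = 0.1, min_confidence = 0.1)
    got <- mine_rules(db, cfg)
    want <- oracle_rules(db, cfg$min_support, cfg$min_confidence)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_equal(got$disease, want$disease)
      expect_equal(got$material, want$material)
      expect_equal(got$n_both, want$n_both)
      expect_equal(got$n_disease, want$n_disease)
      expect_equal(got$n_material, want$n_material)
      expect_equal(got$support, want$support)
      expect_equal(got$confidence, want$confidence)
      expect_equal(got$lift, want$lift)
    }
  }
})

test_that("frequent itemsets match exhaustive enumeration and downward closure", {
  for (seed in c(3, 14)) {
    db <- random_db(40, 4, 7, seed = seed)
    m <- encode_matrix(db)
    cfg <- mining_config(min_support = 0.1)
    got <- apriori(m, cfg)
    want <- oracle_itemsets(db, cfg$min_support)
    key <- function(items) paste(sort(items), collapse = "|")
    got_keys <- sort(vapply(got$items, key, ""))
    want_keys <- sort(vapply(want, function(x) key(x$items), ""))
    expect_identical(got_keys, want_keys)
    # downward closure: both members of every frequent pair are frequent
    singles <- unlist(got$items[got$size == 1])
    for (pair in got$items[got$size == 2])
      expect_true(all(pair %in% singles))
  }
})

test_that("independent items give lift near 1 and metric identities hold", {
  # two independent coin-flip items over many transactions
  set.seed(42)
  n <- 4000
  d_in <- runif(n) < 0.5
  m_in <- runif(n) < 0.5
  db <- transaction_db(
    sprintf("t%04d", 1:n),
    ifelse(d_in, "dA", "dB"),
    ifelse(m_in, "mA", "mB"))
  rules <- mine_rules(db, mining_config(0.01, 0.01))
  r <- rules[rules$disease == "dA" & rules$material == "mA", ]
  expect_equal(r$lift, 1, tolerance = 0.05)
  # identities on every emitted rule
  expect_equal(r$lift * (r$n_material / r$n_total), r$confidence)
  expect_true(all(rules$support <= rules$confidence))
  expect_true(all(rules$support <= rules$n_material / rules$n_total))
})

test_that("a consequent present wherever the antecedent is gives confidence 1", {
  db <- transaction_db(sprintf("t%d", 1:10),
                       as.list(rep("d", 10)),
                       lapply(1:10, function(i) "m"))
  rules <- mine_rules(db, mining_config(0.05, 0.05))
  expect_equal(rules$confidence[rules$disease == "d"], 1.0)
})

test_that("filter_rules uses inclusive thresholds and preserves order", {
  cfg <- mining_config(min_support = 0.10, min_confidence = 0.10)
  rules <- data.frame(
    disease = c("d1", "d2", "d3"), material = c("m1", "m2", "m3"),
    n_both = c(1, 1, 1), n_disease = c(10, 10, 10),
    n_material = c(2, 2, 2), n_total = 10,
    support = c(0.10, 0.09, 0.50),
    confidence = c(0.10, 0.50, 0.09), lift = 1)
  kept <- filter_rules(rules, cfg)
  expect_identical(kept$disease, "d1")  # exactly-at-threshold kept, both cuts inclusive
  # survivors equal a brute-force predicate scan on random rule lists
  set.seed(8)
  rnd <- data.frame(disease = sprintf("d%d", 1:50),
                    material = sprintf("m%d", 1:50),
                    n_both = 1, n_disease = 2, n_material = 2, n_total = 10,
                    support = runif(50), confidence = runif(50), lift = 1)
  expect_identical(
    filter_rules(rnd, cfg)$disease,
    rnd$disease[rnd$support >= 0.10 & rnd$confidence >= 0.10])
})

test_that("planted rules are recovered with exact counts and printed metrics", {
  pr <- data.frame(
    disease = c("wound", "wound", "rabies"),
    material = c("matA", "matB", "matC"),
    n_both = c(7, 4, 7), n_ante = c(39, 39, 16), n_cons = c(17, 8, 46))
  db <- synth_prescriptions(generator_config(planted_rules = pr, seed = 2))
  rules <- mine_rules(db)
  got <- rules[rules$disease == "wound" & rules$material == "matA", ]
  expect_identical(got$n_both, 7L)
  expect_identical(got$n_disease, 39L)
  expect_identical(got$n_material, 17L)
  f <- format_rules(got)
  expect_equal(f$support_pct, 1.39)
  expect_equal(f$confidence_pct, 17.95)
  expect_equal(f$lift, 5.33)
  got2 <- rules[rules$disease == "rabies" & rules$material == "matC", ]
  expect_equal(format_rules(got2)$confidence_pct, 43.75)
  expect_equal(format_rules(got2)$lift, 4.80)
})
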