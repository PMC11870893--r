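# Reading, validation, filtering and matrix encoding of prescription
# records.

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("TSV readback preserves records and collapses duplicates", {
  path <- write_fixture(c(
    "prescription_id\tdiseases\tmaterials",
    "rx1\twound\tA; A; B",
    "rx2\tfever\tB;C",
    "rx3\twound; fever\tA"))
  db <- read_prescriptions(path)
  expect_length(db$ids, 3)
  expect_setequal(db$materials[[1]], c("A", "B"))   # duplicate collapsed
  expect_setequal(db$diseases[[3]], c("wound", "fever"))
  expect_setequal(db$disease_catalog, c("wound", "fever"))
  expect_setequal(db$material_catalog, c("A", "B", "C"))
})

test_that("malformed input is rejected with a specific error", {
  missing_col <- write_fixture(c("prescription_id\tdiseases",
                                 "rx1\twound"))
  expect_error(read_prescriptions(missing_col), class = "tmnet_format_error")
  empty_cell <- write_fixture(c("prescription_id\tdiseases\tmaterials",
                                "rx1\twound\tA",
                                "rx2\t\tB"))
  expect_error(read_prescriptions(empty_cell),
               class = "tmnet_validation_error")
  expect_error(read_prescriptions(empty_cell), "rx2")
  clash <- write_fixture(c("prescription_id\tdiseases\tmaterials",
                           "rx1\twound\tA",
                           "rx2\tA\tB"))
  expect_error(read_prescriptions(clash), class = "tmnet_namespace_error")
})

test_that("prescription write/read round-trips a synthetic database", {
  db <- synth_prescriptions(generator_config(
    n_transactions = 505, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prescriptions(db, path)
  back <- read_prescriptions(path)
  expect_length(back$ids, 505)
  expect_identical(back$ids, db$ids)
  for (i in c(1, 100, 505)) {
    expect_setequal(back$diseases[[i]], db$diseases[[i]])
    expect_setequal(back$materials[[i]], db$materials[[i]])
  }
})

test_that("filter_diseases respects the threshold, identity and idempotence", {
  db <- transaction_db(
    c("r1", "r2", "r3"),
    list("common", c("common", "rare"), "common"),
    list("A", "B", "C"))
  out <- suppressMessages(filter_diseases(db, 2))
  expect_false("rare" %in% out$disease_catalog)
  expect_true("common" %in% out$disease_catalog)
  # min = 1 is the identity
  same <- filter_diseases(db, 1)
  expect_identical(same$diseases, db$diseases)
  # idempotent at a fixed threshold
  twice <- suppressMessages(filter_diseases(out, 2))
  expect_identical(twice, out)
  # prescriptions left without any disease are dropped
  db2 <- transaction_db(c("r1", "r2", "r3"), list("solo", "other", "other"),
                        list("A", "B", "C"))
  dropped <- suppressMessages(filter_diseases(db2, 2))
  expect_identical(dropped$ids, c("r2", "r3"))
  expect_error(suppressMessages(filter_diseases(db2, 3)),
               class = "tmnet_empty_result")
})

test_that("filtering against brute-force frequency tallies on synthetic data", {
  db <- random_db(80, 8, 15, seed = 21)
  tally <- table(unlist(db$diseases))
  out <- suppressMessages(filter_diseases(db, 5))
  expect_setequal(out$disease_catalog, names(tally)[tally >= 5])
})

test_that("encode_matrix is the exact indicator encoding and decodes back", {
  db <- transaction_db("p1", list("d1"), list(c("m1", "m2")))
  m <- encode_matrix(db)
  expect_identical(as.integer(m["p1", c("d1", "m1", "m2")]), c(1L, 1L, 1L))
  expect_true(all(m %in% 0:1))
  expect_true(all(rowSums(m) >= 2))  # >= 1 disease + >= 1 material
  # encode o decode = identity on random databases
  for (seed in 1:3) {
    db <- random_db(30, 5, 8, seed = seed)
    back <- decode_matrix(encode_matrix(db))
    expect_identical(back$ids, db$ids)
    expect_identical(lapply(back$diseases, sort), lapply(db$diseases, sort))
    expect_identical(lapply(back$materials, sort),
                     lapply(db$materials, sort))
  }
  # column sums equal brute-force item frequencies
  db <- random_db(50, 6, 10, seed = 99)
  m <- encode_matrix(db)
  tally <- table(c(unlist(db$diseases), unlist(db$materials)))
  expect_equal(as.integer(colSums(m)[names(tally)]), as.integer(tally))
})

test_that("summarize_db reports study-scale totals and ranks by frequency", {
  db <- synth_prescriptions(generator_config(
    n_transactions = 505, n_diseases = 106, n_materials = 567,
    planted_rules = data.frame(disease = "wound", material = "mat_x",
                               n_both = 7, n_ante = 39, n_cons = 17),
    seed = 3))
  s <- summarize_db(db)
  expect_identical(as.integer(s$totals),
                   c(505L, 106L, 567L))
  # the planted disease is the most frequent by construction
  expect_identical(s$disease_frequency$disease[1], "wound")
  expect_identical(s$disease_frequency$n[1], 39L)
  # single-disease database gives a ranking of length 1
  db1 <- transaction_db(c("a", "b"), list("d", "d"), list("m1", "m2"))
  expect_identical(nrow(summarize_db(db1)$disease_frequency), 1L)
  # counts equal brute-force tallies on random data
  db <- random_db(60, 7, 9, seed = 5)
  s <- summarize_db(db)
  tally <- table(unlist(db$diseases))
  expect_equal(stats::setNames(s$disease_frequency$n,
                               s$disease_frequency$disease)[names(tally)],
               stats::setNames(as.integer(tally), names(tally)))
})
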