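test_that("activity table parsing filters endpoints and audits drops", {
  tmp <- withr_tempfile <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  df <- data.frame(
    compound_id = c("a", "b", "c", "d", "e"),
    smiles = c("CCO", "CCN", "CCC", "CCCC", "CCO"),
    cell_line_id = "X",
    assay_type = c("IC50", "GI50", "CC50", "EC50", "IC50"),
    standard_value = c(1, 2, 3, 4, 5),
    standard_units = "uM", standard_relation = "=")
  write.csv(df, tmp, row.names = FALSE)
  parsed <- parse_activity_table(tmp)
  expect_equal(nrow(parsed$records), 4L)
  expect_equal(unname(parsed$audit["dropped_assay_type"]), 1L)

  # empty file with header
  write.csv(df[0, ], tmp, row.names = FALSE)
  expect_equal(nrow(parse_activity_table(tmp)$records), 0L)

  # missing smiles column is fatal
  write.csv(df[, -2], tmp, row.names = FALSE)
  expect_error(parse_activity_table(tmp), "smiles")
})

test_that("unit conversion is exact and unknown units warn", {
  expect_equal(to_molar(5000, "nM"), 5e-6)
  expect_equal(to_molar(10, "uM"), 1e-5)
  expect_equal(to_molar(0.01, "M"), 1e-2)
  expect_equal(to_molar(c(1, 1), c("mM", "µM")), c(1e-3, 1e-6))
  expect_warning(x <- to_molar(1, "parsecs"), "unknown")
  expect_true(is.na(x))
})

test_that("sensitivity labeling includes the 1e-5 M boundary", {
  expect_identical(label_activity(5e-6), "sensitive")
  expect_identical(label_activity(1e-5), "sensitive")
  expect_identical(label_activity(2e-5), "resistant")
  expect_error(label_activity(-1), "positive")
})

test_that("replicate resolution requires total agreement", {
  expect_identical(resolve_replicates(c("sensitive", "sensitive", "sensitive")),
                   "sensitive")
  expect_identical(resolve_replicates(c("sensitive", "resistant")),
                   NA_character_)
  expect_identical(resolve_replicates("resistant"), "resistant")
})

test_that("curation pipeline matches the hand trace of the toy table", {
  # trace: a = two concordant sensitive replicates -> sensitive;
  # b = 0.5 uM vs 50 uM -> conflict, discarded; c = salt, 3 uM -> sensitive;
  # d = EC50 -> dropped; e = 2000 nM -> sensitive; h = two concordant
  # (4, 6 uM) -> sensitive; i = 9 uM -> sensitive. Cell X: 5 sensitive.
  # Cell Y: f sensitive, g resistant -> only 1 sensitive, removed at
  # min_sensitive = 2.
  db <- build_lcla_database(toy_raw_table(), min_sensitive = 2)
  expect_setequal(db$pairs$compound_id, c("a", "c", "e", "h", "i"))
  expect_true(all(db$pairs$label == "sensitive"))
  expect_true(all(db$pairs$cell_line_id == "X"))
  expect_equal(db$audit$dropped_conflicting_pairs, 1L)
  expect_equal(db$audit$dropped_cell_lines, 1L)
  # the salt compound is stored desalted
  expect_identical(db$compounds$canonical_smiles[db$compounds$compound_id == "c"],
                   canonical_smiles("c1ccccc1CCC"))
})

test_that("curation is order-invariant and idempotent", {
  raw <- fixture_sim()$raw
  db1 <- build_lcla_database(raw)
  db2 <- build_lcla_database(raw[rev(seq_len(nrow(raw))), ])
  expect_identical(db1$pairs, db2$pairs)
  expect_identical(db1$compounds, db2$compounds)
  # re-ingesting the curated output reproduces it
  curated <- merge(db1$pairs, db1$compounds, by = "compound_id")
  db3 <- lcla_from_pairs(curated)
  key <- function(d) d$pairs[order(d$pairs$compound_id, d$pairs$cell_line_id),
                            c("compound_id", "cell_line_id", "label")]
  expect_equal(key(db1), key(db3), ignore_attr = TRUE)
})

test_that("censored relation records are excluded under the strict policy", {
  df <- toy_raw_table()
  df$standard_relation[df$compound_id == "i"] <- ">"
  db <- build_lcla_database(df, min_sensitive = 2)
  expect_false("i" %in% db$pairs$compound_id)
  expect_equal(db$audit$dropped_relation, 1L)
  # gt_resistant admits > records above the threshold as resistant
  df2 <- toy_raw_table()
  df2$standard_relation[df2$compound_id == "e"] <- ">"
  df2$standard_value[df2$compound_id == "e"] <- 50000  # 50 uM in nM
  db2 <- build_lcla_database(df2, min_sensitive = 2,
                             relation_policy = "gt_resistant")
  expect_identical(db2$pairs$label[db2$pairs$compound_id == "e"], "resistant")
})

test_that("structure-identical compound ids are merged", {
  df <- data.frame(
    compound_id = c("z9", "z1", sprintf("s%02d", 1:10)),
    smiles = c("OCC", "CCO.Cl", paste0("c1ccccc1", c("C", "CC", "CCC", "CCCC",
               "CCO", "CCN", "CO", "CN", "COC", "OC"))),
    cell_line_id = "X", assay_type = "IC50",
    standard_value = 1, standard_units = "uM", standard_relation = "=",
    stringsAsFactors = FALSE)
  db <- build_lcla_database(df, min_sensitive = 1)
  # both ethanol records collapse onto the lexicographically smaller id
  expect_true("z1" %in% db$pairs$compound_id)
  expect_false("z9" %in% db$pairs$compound_id)
  expect_equal(db$audit$n_merged_input_ids, 1L)
})

test_that("cell-line filter boundary and monotonicity", {
  mk <- function(n_sens, n_res) {
    data.frame(
      compound_id = sprintf("c%02d", seq_len(n_sens + n_res)),
      smiles = paste0("c1ccccc1", c("C", "CC", "CCC", "CCCC", "CCO", "CCN",
                                    "CO", "CN", "COC", "OC", "CCl", "CBr",
                                    "CF", "CS", "N", "O")[seq_len(n_sens + n_res)]),
      cell_line_id = "A", assay_type = "IC50",
      standard_value = c(rep(1, n_sens), rep(100, n_res)),
      standard_units = "uM", standard_relation = "=",
      stringsAsFactors = FALSE)
  }
  # 9 sensitive -> removed at min_sensitive = 10; 10 -> retained
  expect_equal(nrow(build_lcla_database(mk(9, 5), 10)$pairs), 0L)
  db10 <- build_lcla_database(mk(10, 5), 10)
  expect_equal(nrow(db10$pairs), 15L)
  # raising min_sensitive never increases retained cell lines
  raw <- fixture_sim()$raw
  n_cells <- vapply(c(5, 10, 20, 40), function(ms) {
    length(unique(build_lcla_database(raw, min_sensitive = ms)$pairs$cell_line_id))
  }, 0)
  expect_true(all(diff(n_cells) <= 0))
})
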