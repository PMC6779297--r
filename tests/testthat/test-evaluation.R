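test_that("macro metrics average per-cell rates", {
  # two cells with TP rates 0.5 and 0.7 -> mean 0.6
  pc <- data.frame(cell_line_id = c("A", "B"), TP = c(5, 7), TN = c(4, 2),
                   N_AC = c(10, 10), N_RC = c(8, 4))
  m <- macro_metrics(pc)
  expect_equal(m$mean_TP, 0.6)
  expect_equal(m$mean_TN, mean(c(4 / 8, 2 / 4)))
  expect_equal(m$mean_ACU, mean(c(9 / 18, 9 / 14)))
  # single cell: TP 3/4, TN 1/2 -> ACU 4/6
  one <- data.frame(cell_line_id = "A", TP = 3, TN = 1, N_AC = 4, N_RC = 2)
  expect_equal(macro_metrics(one)$mean_ACU, 4 / 6)
  # perfect predictor
  perf <- data.frame(cell_line_id = c("A", "B"), TP = c(4, 6), TN = c(2, 3),
                     N_AC = c(4, 6), N_RC = c(2, 3))
  expect_equal(unlist(macro_metrics(perf)[1:3]), c(mean_TP = 1, mean_TN = 1,
                                                   mean_ACU = 1))
  # zero-denominator cells are excluded from that rate only
  zd <- data.frame(cell_line_id = c("A", "B"), TP = c(2, 0), TN = c(0, 3),
                   N_AC = c(4, 0), N_RC = c(0, 3))
  mz <- macro_metrics(zd)
  expect_equal(mz$mean_TP, 0.5)
  expect_equal(mz$mean_TN, 1)
  expect_error(macro_metrics(pc[0, ]), "no cell lines")
  # when every cell line has identical compound counts, macro and micro
  # rates coincide
  eq <- data.frame(cell_line_id = c("A", "B", "C"), TP = c(3, 5, 4),
                   TN = c(6, 2, 4), N_AC = 8, N_RC = 8)
  expect_equal(macro_metrics(eq)$mean_TP, sum(eq$TP) / sum(eq$N_AC))
  expect_equal(macro_metrics(eq)$mean_TN, sum(eq$TN) / sum(eq$N_RC))
})

test_that("fold assignment partitions compounds deterministically", {
  ids <- sprintf("c%03d", 1:100)
  f <- make_folds(ids, k = 10L, seed = 7L)
  expect_setequal(names(f), ids)
  expect_equal(unname(table(f)), rep(10L, 10L), ignore_attr = TRUE)
  expect_identical(f, make_folds(ids, k = 10L, seed = 7L))
  expect_false(identical(f, make_folds(ids, k = 10L, seed = 8L)))
  expect_error(make_folds(ids[1:5], k = 10L), "fewer compounds")
})

test_that("similarity cross-validation recovers the planted scaffold signal", {
  cv <- cached("cv_sim", cross_validate(fixture_db(), "similarity", k = 10L,
                                        seed = 3L, radius = 8L,
                                        cutoff = 0.25))
  expect_gt(cv$macro$mean_TP, 0.5)
  expect_gt(cv$macro$mean_TN, 0.5)
  # determinism: identical rerun
  cv2 <- cross_validate(fixture_db(), "similarity", k = 10L, seed = 3L,
                        radius = 8L, cutoff = 0.25)
  expect_identical(cv$predictions, cv2$predictions)
  # confusion counts conserve the known pair counts per cell
  counts <- table(fixture_db()$pairs$cell_line_id,
                  fixture_db()$pairs$label)
  for (i in seq_len(nrow(cv$per_cell))) {
    cl <- cv$per_cell$cell_line_id[i]
    expect_lte(cv$per_cell$N_AC[i], counts[cl, "sensitive"])
    expect_lte(cv$per_cell$N_RC[i], counts[cl, "resistant"])
    expect_lte(cv$per_cell$TP[i], cv$per_cell$N_AC[i])
    expect_lte(cv$per_cell$TN[i], cv$per_cell$N_RC[i])
  }
})

test_that("sweep covers the grid and shows the cutoff monotonicity", {
  sw <- cached("sweep", sweep_cutoffs(fixture_db(), radii = c(2L, 8L),
                                      cutoffs = seq(0.20, 0.60, 0.05),
                                      k = 10L, seed = 3L))
  expect_equal(nrow(sw), 2L * 9L)
  for (r in unique(sw$radius)) {
    s <- sw[sw$radius == r, ]
    s <- s[order(s$cutoff), ]
    expect_true(all(diff(s$mean_TP) <= 1e-12))
    expect_true(all(diff(s$mean_TN) >= -1e-12))
  }
  # identical rerun, same seed (reuse the sequence's own float values)
  picked <- seq(0.20, 0.60, 0.05)[c(1L, 3L)]
  sw2 <- sweep_cutoffs(fixture_db(), radii = 2L, cutoffs = picked,
                       k = 10L, seed = 3L)
  expect_equal(sw2$mean_ACU,
               sw$mean_ACU[sw$radius == 2L & sw$cutoff %in% picked])
})

test_that("well-modeled summary matches a hand tally", {
  svm <- data.frame(cell_line_id = paste0("C", 1:6),
                    TP = c(8, 5, 9, 2, 7, 6), TN = c(8, 5, 9, 2, 3, 6),
                    N_AC = 10, N_RC = 10)
  sim <- data.frame(cell_line_id = paste0("C", 1:6),
                    TP = c(9, 3, 5, 8, 2, 7), TN = c(9, 3, 5, 8, 2, 5),
                    N_AC = 10, N_RC = 10)
  # ACU(svm) = .80 .50 .90 .20 .50 .60 ; ACU(sim) = .90 .30 .50 .80 .20 .60
  s <- select_well_modeled(svm, sim, acu_threshold = 0.65)
  expect_equal(s$n_svm, 2L)          # C1, C3
  expect_equal(s$n_similarity, 2L)   # C1, C4
  expect_equal(s$n_common, 1L)       # C1
  expect_equal(s$n_total, 3L)        # C1, C3, C4
  expect_equal(s$TP_svm, mean(c(0.8, 0.9)))
  expect_equal(s$TP_similarity, mean(c(0.9, 0.8)))
  # total: C1 -> sim (0.9 > 0.8), C3 -> svm, C4 -> sim
  expect_equal(s$TP_total, mean(c(0.9, 0.9, 0.8)))
  # degenerate thresholds
  expect_equal(select_well_modeled(svm, sim, 0)$n_total, 6L)
  expect_equal(select_well_modeled(svm, sim, 1.01)$n_total, 0L)
  expect_error(select_well_modeled(svm, sim[0, ], 0.65), "no cell lines")
})

test_that("external validation rejects leakage and tracks coverage", {
  db <- fixture_db()
  # leakage: a query identical to a reference compound
  leak <- data.frame(compound_id = "new1",
                     smiles = db$compounds$canonical_smiles[1L],
                     cell_line_id = db$pairs$cell_line_id[1L],
                     label = "sensitive", stringsAsFactors = FALSE)
  expect_error(external_validate(db, leak), "already present")

  # new analogs of the reference scaffolds plus unseen chemotypes
  ext <- cached("ext_q", {
    q <- generate_external_queries(fixture_sim(), seed = 77)
    q$pairs[q$pairs$cell_line_id %in% unique(db$pairs$cell_line_id), ]
  })
  res <- cached("ext_res", external_validate(db, ext,
                                             cutoffs = c(0.20, 0.25, 0.30)))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1))
  sim_rows <- res[res$model == "similarity", ]
  sim_rows <- sim_rows[order(sim_rows$cutoff), ]
  # coverage decreases as the cutoff rises, trading recall for confidence
  expect_true(all(diff(sim_rows$coverage) <= 1e-12))
  expect_lt(sim_rows$coverage[3L], sim_rows$coverage[1L])
  expect_true(all(diff(sim_rows$TP) <= 1e-12))
  expect_true(all(diff(sim_rows$TN) >= -1e-12))
})

test_that("external query generator avoids the reference structures", {
  q <- cached("ext_q2", generate_external_queries(fixture_sim(), seed = 5))
  ref_can <- canonical_smiles(fixture_sim()$library$smiles)
  q_can <- canonical_smiles(q$library$smiles)
  expect_length(intersect(q_can, ref_can), 0L)
  # new-scaffold compounds use cores absent from the reference
  expect_length(intersect(q$library$core[q$library$new_scaffold],
                          fixture_sim()$library$core), 0L)
  # deterministic under seed
  expect_identical(q, generate_external_queries(fixture_sim(), seed = 5))
  # analog labels follow the reference scaffold tendencies (low noise)
  truth <- fixture_sim()$truth
  truth$scaffold <- fixture_sim()$library$scaffold[
    match(truth$compound_id, fixture_sim()$library$compound_id)]
  tend <- tapply(truth$tendency, list(truth$scaffold, truth$cell_line_id),
                 function(x) names(which.max(table(x))))
  an <- q$pairs[q$pairs$compound_id %in%
                  q$library$compound_id[!q$library$new_scaffold], ]
  an$scaffold <- q$library$scaffold[match(an$compound_id,
                                          q$library$compound_id)]
  agree <- mean(an$label == tend[cbind(an$scaffold, an$cell_line_id)])
  expect_gt(agree, 0.85)  # 5% label noise
})
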