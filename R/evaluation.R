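# Validation drivers and metrics.
#
# Two regimes: (1) 10-fold cross-validation with per-cell-line macro
# metrics -- the mean over cell lines of TP_j / N_j^AC, TN_j / N_j^RC and
# (TP_j + TN_j) / (N_j^AC + N_j^RC), where N_j^AC / N_j^RC are the numbers
# of compounds known sensitive / resistant for cell line j; (2) external
# validation of new compounds, where metrics are micro rates over the
# interaction space, plus compound coverage and the covered-only rates
# TP_C / TN_C.

#' Macro (per-cell-line averaged) metrics
#'
#' @param per_cell data.frame with columns `cell_line_id`, `TP`, `TN`,
#'   `N_AC`, `N_RC` (counts accumulated over folds). Cells with a zero
#'   denominator for a given rate are excluded from that rate's average.
#' @return list with `mean_TP`, `mean_TN`, `mean_ACU` and `n_cells`.
#' @export
macro_metrics <- function(per_cell) {
  stopifnot(is.data.frame(per_cell),
            all(c("TP", "TN", "N_AC", "N_RC") %in% names(per_cell)))
  if (nrow(per_cell) == 0L) stop("no cell lines to average", call. = FALSE)
  stopifnot(all(per_cell$TP <= per_cell$N_AC),
            all(per_cell$TN <= per_cell$N_RC))
  rate <- function(num, den) {
    ok <- den > 0
    if (!any(ok)) return(NA_real_)
    mean(num[ok] / den[ok])
  }
  list(mean_TP = rate(per_cell$TP, per_cell$N_AC),
       mean_TN = rate(per_cell$TN, per_cell$N_RC),
       mean_ACU = rate(per_cell$TP + per_cell$TN,
                       per_cell$N_AC + per_cell$N_RC),
       n_cells = nrow(per_cell))
}

#' Global compound-level fold assignment
#'
#' One partition of the compound set shared by every cell line and both
#' prediction methods, so the two methods are always evaluated on the same
#' held-out compounds.
#'
#' @param compound_ids character vector of compound ids.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return named integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(compound_ids, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  ids <- unique(compound_ids)
  if (length(ids) < k) stop("fewer compounds than folds", call. = FALSE)
  with_seed(seed, setNames(sample(rep(seq_len(k), length.out = length(ids))),
                           ids))
}

# Fold-wise similarity scores for every known pair of the database:
# the reference for each fold is rebuilt from training compounds only.
.cv_similarity_scores <- function(db, radius = 8L, n_bits = 1024L,
                                  n_top = 3L, k = 10L, seed = 1L,
                                  folds = NULL) {
  fp <- morgan_fingerprint(
    setNames(db$compounds$canonical_smiles, db$compounds$compound_id),
    radius = radius, n_bits = n_bits)
  if (is.null(folds)) folds <- make_folds(db$compounds$compound_id, k, seed)
  sims <- tanimoto_similarity(fp)
  idx <- per_cell_index(db)
  p <- db$pairs
  p$fold <- folds[p$compound_id]
  p$score <- NA_real_
  ref_audit <- list()
  for (f in sort(unique(p$fold))) {
    test_ids <- names(folds)[folds == f]
    fold_refs <- character(0)
    for (cl in names(idx)) {
      refs <- setdiff(idx[[cl]]$sensitive, test_ids)
      fold_refs <- union(fold_refs, refs)
      sel <- which(p$fold == f & p$cell_line_id == cl)
      if (length(refs) == 0L || length(sel) == 0L) next
      s <- sims[p$compound_id[sel], refs, drop = FALSE]
      p$score[sel] <- apply(s, 1L, .top_mean, n_top = n_top)
    }
    ref_audit[[as.character(f)]] <- sort(fold_refs)
  }
  list(scores = p, folds = folds, ref_audit = ref_audit)
}

.confusion_per_cell <- function(pred) {
  # pred: compound_id, cell_line_id, true_label, label (predicted)
  cells <- sort(unique(pred$cell_line_id))
  out <- do.call(rbind, lapply(cells, function(cl) {
    q <- pred[pred$cell_line_id == cl, , drop = FALSE]
    data.frame(cell_line_id = cl,
               TP = sum(q$true_label == "sensitive" & q$label == "sensitive"),
               TN = sum(q$true_label == "resistant" & q$label == "resistant"),
               N_AC = sum(q$true_label == "sensitive"),
               N_RC = sum(q$true_label == "resistant"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-validate a prediction method on a curated database
#'
#' Splits the compound set into `k` folds ([make_folds()]); in each fold
#' the similarity reference (or the SVM models, including re-balancing and
#' grid search) is rebuilt from training compounds only, and the held-out
#' compounds' known pairs are predicted. Confusion counts accumulate over
#' folds; macro metrics average per cell line.
#'
#' @param db an `lcla_db`.
#' @param method `"similarity"` or `"svm"`.
#' @param k,seed fold parameters.
#' @param radius,n_bits fingerprint parameters.
#' @param n_top,cutoff similarity-method parameters.
#' @param min_per_class,ratio,height,grid,svm_cv_folds SVM-method
#'   parameters; cell lines with fewer than `min_per_class` compounds in
#'   either class (in the full database) are excluded from the SVM run.
#' @param folds optional precomputed fold assignment (to share one
#'   partition across methods).
#' @return object of class `cv_result`: list with `method`, `per_cell`,
#'   `macro`, `predictions`, `folds` and `audit` (per-fold reference /
#'   training compound ids, for leakage auditing).
#' @export
cross_validate <- function(db, method = c("similarity", "svm"), k = 10L,
                           seed = 1L, radius = 8L, n_bits = 1024L,
                           n_top = 3L, cutoff = 0.25, min_per_class = 20L,
                           ratio = 1.2, height = 4.5, grid = svm_grid(),
                           svm_cv_folds = 3L, folds = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(db, "lcla_db"))
  if (method == "similarity") {
    cv <- .cv_similarity_scores(db, radius, n_bits, n_top, k, seed, folds)
    pred <- cv$scores
    names(pred)[names(pred) == "label"] <- "true_label"
    pred <- pred[!is.na(pred$score), , drop = FALSE]
    pred$label <- ifelse(pred$score >= cutoff, "sensitive", "resistant")
    audit <- list(reference_ids = cv$ref_audit)
    folds <- cv$folds
  } else {
    if (is.null(folds)) folds <- make_folds(db$compounds$compound_id, k, seed)
    cv <- .cv_svm_predictions(db, folds, radius, n_bits, min_per_class,
                              ratio, height, grid, svm_cv_folds, seed)
    pred <- cv$predictions
    audit <- list(training_ids = cv$train_audit)
  }
  per_cell <- .confusion_per_cell(pred)
  structure(list(method = method, per_cell = per_cell,
                 macro = macro_metrics(per_cell), predictions = pred,
                 folds = folds, cutoff = if (method == "similarity") cutoff
                 else NA_real_,
                 audit = audit),
            class = "cv_result")
}

.cv_svm_predictions <- function(db, folds, radius, n_bits, min_per_class,
                                ratio, height, grid, svm_cv_folds, seed) {
  fp <- morgan_fingerprint(
    setNames(db$compounds$canonical_smiles, db$compounds$compound_id),
    radius = radius, n_bits = n_bits)
  idx <- per_cell_index(db)
  eligible <- names(idx)[vapply(idx, function(e) {
    length(e$sensitive) >= min_per_class &&
      length(e$resistant) >= min_per_class
  }, TRUE)]
  p <- db$pairs[db$pairs$cell_line_id %in% eligible, , drop = FALSE]
  p$fold <- folds[p$compound_id]
  preds <- list()
  train_audit <- list()
  for (f in sort(unique(p$fold))) {
    test_ids <- names(folds)[folds == f]
    fold_train <- character(0)
    for (cl in eligible) {
      q <- p[p$cell_line_id == cl, , drop = FALSE]
      tr <- q[q$fold != f, , drop = FALSE]
      te <- q[q$fold == f, , drop = FALSE]
      if (nrow(te) == 0L || length(unique(tr$label)) < 2L) next
      labels <- setNames(tr$label, tr$compound_id)
      bal <- balance_classes(fp[tr$compound_id, , drop = FALSE], labels,
                             ratio = ratio, height = height)
      model <- train_cell_svm(fp[bal$ids, , drop = FALSE], labels[bal$ids],
                              grid = grid, cv_folds = svm_cv_folds,
                              seed = seed + f, cell_line_id = cl)
      fold_train <- union(fold_train, bal$ids)
      pr <- predict_cell_svm(model, fp[te$compound_id, , drop = FALSE])
      preds[[length(preds) + 1L]] <- data.frame(
        compound_id = te$compound_id, cell_line_id = cl,
        true_label = te$label, score = pr$score, label = pr$label,
        fold = f, stringsAsFactors = FALSE)
    }
    train_audit[[as.character(f)]] <- sort(fold_train)
  }
  list(predictions = do.call(rbind, preds), train_audit = train_audit)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s method%s: <TP> = %.3f, <TN> = %.3f, <ACU> = %.3f over %d cell lines\n",
              length(unique(x$folds)), x$method,
              if (!is.na(x$cutoff)) sprintf(" (cutoff %.2f)", x$cutoff) else "",
              x$macro$mean_TP, x$macro$mean_TN, x$macro$mean_ACU,
              x$macro$n_cells))
  invisible(x)
}

#' Radius / cutoff sweep of the similarity method
#'
#' Cross-validated macro metrics on a grid of Morgan radii and similarity
#' cutoffs (scores are computed once per radius; cutoffs reuse them).
#'
#' @param db an `lcla_db`.
#' @param radii Morgan radii to evaluate.
#' @param cutoffs similarity cutoffs to evaluate.
#' @param k,seed,n_bits,n_top as in [cross_validate()].
#' @return data.frame with one row per (radius, cutoff).
#' @export
sweep_cutoffs <- function(db, radii = c(2L, 4L, 8L),
                          cutoffs = seq(0.20, 0.60, by = 0.05), k = 10L,
                          seed = 1L, n_bits = 1024L, n_top = 3L) {
  folds <- make_folds(db$compounds$compound_id, k, seed)
  out <- list()
  for (r in radii) {
    cv <- .cv_similarity_scores(db, r, n_bits, n_top, k, seed, folds)
    sc <- cv$scores[!is.na(cv$scores$score), , drop = FALSE]
    for (ct in cutoffs) {
      pred <- sc
      names(pred)[names(pred) == "label"] <- "true_label"
      pred$label <- ifelse(pred$score >= ct, "sensitive", "resistant")
      m <- macro_metrics(.confusion_per_cell(pred))
      out[[length(out) + 1L]] <- data.frame(
        radius = r, cutoff = ct, mean_TP = m$mean_TP, mean_TN = m$mean_TN,
        mean_ACU = m$mean_ACU, n_cells = m$n_cells)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize well-modeled cell lines for two methods
#'
#' Counts cell lines whose cross-validated per-cell accuracy reaches
#' `acu_threshold` under the SVM only, the similarity method only, both
#' ("common") and either ("total"), with macro TP/TN rates inside each
#' group. In the "total" group each cell line contributes the rates of its
#' better-accuracy passing method (ties favour the SVM).
#'
#' @param per_cell_svm,per_cell_sim per-cell metric tables (`$per_cell` of
#'   [cross_validate()] results) on a shared cell-line set.
#' @param acu_threshold accuracy floor (inclusive).
#' @return one-row data.frame of group counts and rates.
#' @export
select_well_modeled <- function(per_cell_svm, per_cell_sim,
                                acu_threshold = 0.65) {
  common_cells <- intersect(per_cell_svm$cell_line_id,
                            per_cell_sim$cell_line_id)
  if (length(common_cells) == 0L) {
    stop("the two methods share no cell lines", call. = FALSE)
  }
  a <- per_cell_svm[match(common_cells, per_cell_svm$cell_line_id), ]
  b <- per_cell_sim[match(common_cells, per_cell_sim$cell_line_id), ]
  acu <- function(m) (m$TP + m$TN) / (m$N_AC + m$N_RC)
  pass_a <- acu(a) >= acu_threshold
  pass_b <- acu(b) >= acu_threshold
  grp_rate <- function(m, sel, num, den) {
    if (!any(sel)) return(NA_real_)
    mean(m[[num]][sel] / m[[den]][sel])
  }
  pick_a <- pass_a & (!pass_b | acu(a) >= acu(b))
  tot_tp <- ifelse(pick_a, a$TP / a$N_AC, b$TP / b$N_AC)
  tot_tn <- ifelse(pick_a, a$TN / a$N_RC, b$TN / b$N_RC)
  total <- pass_a | pass_b
  data.frame(
    acu_threshold = acu_threshold,
    n_svm = sum(pass_a), n_similarity = sum(pass_b),
    n_common = sum(pass_a & pass_b), n_total = sum(total),
    TP_svm = grp_rate(a, pass_a, "TP", "N_AC"),
    TN_svm = grp_rate(a, pass_a, "TN", "N_RC"),
    TP_similarity = grp_rate(b, pass_b, "TP", "N_AC"),
    TN_similarity = grp_rate(b, pass_b, "TN", "N_RC"),
    TP_total = if (any(total)) mean(tot_tp[total]) else NA_real_,
    TN_total = if (any(total)) mean(tot_tn[total]) else NA_real_
  )
}

#' External validation on new compounds
#'
#' Evaluates the similarity method (per cutoff), optionally the SVM models
#' and the combined strategy, on a table of new compounds with known
#' labels, reporting micro rates over the interaction space, compound
#' coverage, and covered-only rates TP_C / TN_C. Query compounds must be
#' structurally absent from the reference database; overlap is an error.
#'
#' @param reference_db the curated `lcla_db` the predictions draw on.
#' @param query_pairs data.frame with `compound_id`, `smiles`,
#'   `cell_line_id`, `label` for the new compounds (pairs outside the
#'   reference cell-line set are dropped).
#' @param cutoffs similarity cutoffs to evaluate.
#' @param svm_models optional models from [train_cell_svms()]; enables the
#'   `svm` and `combined` rows.
#' @param radius,n_bits,n_top similarity parameters.
#' @return data.frame with one row per evaluated configuration.
#' @export
external_validate <- function(reference_db, query_pairs,
                              cutoffs = c(0.20, 0.25, 0.30),
                              svm_models = NULL, radius = 8L,
                              n_bits = 1024L, n_top = 3L) {
  stopifnot(inherits(reference_db, "lcla_db"),
            all(c("compound_id", "smiles", "cell_line_id", "label") %in%
                  names(query_pairs)))
  ref <- similarity_reference(reference_db, radius, n_bits, n_top)
  qp <- query_pairs[query_pairs$cell_line_id %in% names(ref$per_cell), ,
                    drop = FALSE]
  smiles_of <- tapply(qp$smiles, qp$compound_id, `[[`, 1L)
  can <- strip_to_largest_fragment(unname(smiles_of))
  names(can) <- names(smiles_of)
  leaked <- names(can)[can %in% ref$canonical_smiles]
  if (length(leaked) > 0L) {
    stop("query compounds already present in the reference database: ",
         paste(utils::head(leaked, 10L), collapse = ", "), call. = FALSE)
  }
  qfp <- morgan_fingerprint(can, radius = radius, n_bits = n_bits)
  scores <- .fish_scores(qfp, NULL, ref, self_exclude = FALSE)
  truth <- setNames(qp$label, paste(qp$compound_id, qp$cell_line_id))
  micro <- function(pred) {
    key <- paste(pred$compound_id, pred$cell_line_id)
    tl <- truth[key]
    keep <- !is.na(tl)
    pred <- pred[keep, , drop = FALSE]; tl <- tl[keep]
    list(TP = mean(pred$label[tl == "sensitive"] == "sensitive"),
         TN = mean(pred$label[tl == "resistant"] == "resistant"),
         n = length(tl))
  }
  rows <- list()
  add_row <- function(model, cutoff, m, coverage, TP_C, TN_C) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, cutoff = cutoff, n_compounds = length(can),
      n_interactions = nrow(qp), TP = m$TP, TN = m$TN,
      coverage = coverage, TP_C = TP_C, TN_C = TN_C,
      stringsAsFactors = FALSE)
  }
  if (!is.null(svm_models)) {
    svm_pred <- predict_cell_svms(svm_models,
                                  setNames(unname(smiles_of),
                                           names(smiles_of)))
    m <- micro(svm_pred)
    add_row("svm", NA_real_, m, 1, NA_real_, NA_real_)
  }
  for (ct in cutoffs) {
    sim_pred <- .scores_to_predictions(scores, ct, "similarity")
    cov <- compound_coverage(sim_pred)
    m <- micro(sim_pred)
    covered_pred <- sim_pred[sim_pred$covered, , drop = FALSE]
    mc <- if (nrow(covered_pred) > 0L) micro(covered_pred) else
      list(TP = NA_real_, TN = NA_real_)
    add_row("similarity", ct, m, mean(cov), mc$TP, mc$TN)
    if (!is.null(svm_models)) {
      uncovered <- names(cov)[!cov]
      comb <- covered_pred
      if (length(uncovered) > 0L) {
        sv <- svm_pred[svm_pred$compound_id %in% uncovered, , drop = FALSE]
        sv$covered <- FALSE
        comb <- rbind(comb, sv[, names(comb)])
      }
      add_row("combined", ct, micro(comb), 1, NA_real_, NA_real_)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
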