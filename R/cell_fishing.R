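# The similarity-based "cell fishing" predictor: a query compound is called
# sensitive for a cell line when its mean Tanimoto similarity to the top-n
# most similar compounds known sensitive for that cell line reaches the
# similarity cutoff.

#' Build a similarity reference from a curated database
#'
#' Fingerprints every compound in the database and indexes, per cell line,
#' the compounds reported sensitive (the reference set the query is compared
#' against).
#'
#' @param db an `lcla_db` from [build_lcla_database()].
#' @param radius Morgan radius (default 8, i.e. ECFP16).
#' @param n_bits fingerprint length (default 1024).
#' @param n_top number of closest sensitive compounds averaged (default 3).
#' @return an object of class `sim_reference`.
#' @export
similarity_reference <- function(db, radius = 8L, n_bits = 1024L, n_top = 3L) {
  stopifnot(inherits(db, "lcla_db"), n_top >= 1L)
  if (nrow(db$compounds) == 0L) stop("empty database", call. = FALSE)
  fp <- morgan_fingerprint(
    setNames(db$compounds$canonical_smiles, db$compounds$compound_id),
    radius = radius, n_bits = n_bits)
  idx <- per_cell_index(db)
  per_cell <- lapply(idx, `[[`, "sensitive")
  per_cell <- per_cell[lengths(per_cell) > 0L]
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits),
                 n_top = as.integer(n_top), fp = fp, per_cell = per_cell,
                 canonical_smiles = setNames(db$compounds$canonical_smiles,
                                             db$compounds$compound_id)),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("Similarity reference:", length(x$per_cell), "cell lines,",
      nrow(x$fp), "fingerprinted compounds",
      sprintf("(radius %d, %d bits, top-%d)\n", x$radius, x$n_bits, x$n_top))
  invisible(x)
}

#' Sensitivity score of a query against one reference set
#'
#' Mean of the `n_top` largest Tanimoto similarities between the query
#' fingerprint and the reference fingerprints; when fewer than `n_top`
#' references exist, the mean over all of them.
#'
#' @param query_fp binary fingerprint vector.
#' @param ref_fps binary fingerprint matrix (rows are reference compounds).
#' @param n_top number of top similarities averaged.
#' @return score in \[0, 1\].
#' @export
sensitivity_score <- function(query_fp, ref_fps, n_top = 3L) {
  ref_fps <- .as_fp_matrix(ref_fps)
  if (nrow(ref_fps) == 0L) stop("empty reference set", call. = FALSE)
  sims <- tanimoto_similarity(.as_fp_matrix(query_fp), ref_fps)[1L, ]
  .top_mean(sims, n_top)
}

.top_mean <- function(sims, n_top) {
  k <- min(n_top, length(sims))
  mean(sort(sims, decreasing = TRUE, method = "quick")[seq_len(k)])
}

#' Fish cell lines for query compounds
#'
#' Scores each query compound against every cell line's sensitive reference
#' set and labels the pair sensitive when the score reaches `cutoff`
#' (inclusive). A query structurally identical (by canonical largest-fragment
#' SMILES) to a reference compound is excluded from its own reference lists
#' when `self_exclude = TRUE`, so validation never retrieves the query
#' itself.
#'
#' @param query_smiles character vector of query SMILES; names become
#'   compound ids.
#' @param reference a `sim_reference`.
#' @param cutoff similarity cutoff in (0, 1); the field's typical operating
#'   range here is 0.20-0.30.
#' @param self_exclude exclude structurally identical reference compounds.
#' @return data.frame of predictions: `compound_id`, `cell_line_id`,
#'   `score`, `label`, `method`, `covered`.
#' @export
fish <- function(query_smiles, reference, cutoff = 0.25, self_exclude = TRUE) {
  stopifnot(inherits(reference, "sim_reference"))
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  }
  ids <- if (!is.null(names(query_smiles))) names(query_smiles) else query_smiles
  can <- strip_to_largest_fragment(query_smiles)
  qfp <- morgan_fingerprint(setNames(can, ids),
                            radius = reference$radius,
                            n_bits = reference$n_bits)
  scores <- .fish_scores(qfp, can, reference, self_exclude)
  .scores_to_predictions(scores, cutoff, method = "similarity")
}

# Score matrix (queries x cell lines) for already-computed query
# fingerprints; query_can gives canonical SMILES for self-exclusion (NULL
# disables it).
.fish_scores <- function(qfp, query_can, reference, self_exclude = TRUE) {
  sims <- tanimoto_similarity(qfp, reference$fp)
  cells <- names(reference$per_cell)
  out <- matrix(NA_real_, nrow = nrow(qfp), ncol = length(cells),
                dimnames = list(rownames(qfp), cells))
  self <- if (self_exclude && !is.null(query_can)) {
    lapply(query_can, function(s)
      names(reference$canonical_smiles)[reference$canonical_smiles == s])
  } else {
    vector("list", nrow(qfp))
  }
  for (j in seq_along(cells)) {
    refs <- reference$per_cell[[j]]
    s <- sims[, refs, drop = FALSE]
    for (i in seq_len(nrow(qfp))) {
      use <- if (length(self[[i]])) !(refs %in% self[[i]]) else TRUE
      v <- s[i, use]
      out[i, j] <- if (length(v) == 0L) NA_real_ else
        .top_mean(v, reference$n_top)
    }
  }
  out
}

.scores_to_predictions <- function(scores, cutoff, method) {
  long <- data.frame(
    compound_id = rep(rownames(scores), times = ncol(scores)),
    cell_line_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$score), , drop = FALSE]
  long$label <- ifelse(long$score >= cutoff, "sensitive", "resistant")
  long$method <- method
  cov <- tapply(long$label == "sensitive", long$compound_id, any)
  long$covered <- unname(cov[long$compound_id])
  long <- long[order(long$compound_id, long$cell_line_id), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Compound-level coverage of similarity predictions
#'
#' A query compound is covered when the similarity method calls at least one
#' cell line sensitive for it.
#'
#' @param predictions prediction data.frame from [fish()] (similarity
#'   method).
#' @return named logical vector, one entry per compound.
#' @export
compound_coverage <- function(predictions) {
  stopifnot(all(predictions$method == "similarity"))
  res <- tapply(predictions$label == "sensitive", predictions$compound_id, any)
  setNames(as.logical(res), names(res))
}

#' Combined similarity + SVM prediction
#'
#' Applies the similarity method first; compounds it covers keep their
#' similarity predictions for every cell line, while uncovered compounds are
#' predicted by the per-cell-line SVM models instead. The `method` column
#' records the provenance of each prediction.
#'
#' @param query_smiles named character vector of query SMILES.
#' @param reference a `sim_reference`.
#' @param svm_models named list of `cell_svm` models (one per cell line), as
#'   from [train_cell_svms()]; must cover the same cell-line set as
#'   `reference`.
#' @param cutoff similarity cutoff.
#' @param self_exclude see [fish()].
#' @return prediction data.frame as in [fish()].
#' @export
combined_predict <- function(query_smiles, reference, svm_models,
                             cutoff = 0.25, self_exclude = TRUE) {
  if (!setequal(names(svm_models), names(reference$per_cell))) {
    stop("SVM models and similarity reference cover different cell-line sets",
         call. = FALSE)
  }
  sim <- fish(query_smiles, reference, cutoff, self_exclude)
  cov <- compound_coverage(sim)
  ids <- if (!is.null(names(query_smiles))) names(query_smiles) else query_smiles
  uncovered <- ids[!cov[ids]]
  keep <- sim[sim$covered, , drop = FALSE]
  if (length(uncovered) > 0L) {
    svm_part <- predict_cell_svms(svm_models,
                                  setNames(query_smiles[match(uncovered, ids)],
                                           uncovered))
    svm_part$covered <- FALSE
    keep <- rbind(keep, svm_part[, names(keep)])
  }
  keep <- keep[order(keep$compound_id, keep$cell_line_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep$method[keep$covered] <- "similarity"
  keep
}
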