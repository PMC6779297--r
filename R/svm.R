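# Per-cell-line RBF-kernel SVM classifiers on 1024-bit Morgan fingerprints,
# with C/gamma chosen by grid search over an internal cross-validation.

#' Default hyperparameter grid
#'
#' Spans C in 2^-5..2^15 and gamma in 2^-15..2^3; `step` sets the exponent
#' stride (default 4, a coarse grid; use 2 for the classical fine grid).
#'
#' @param step exponent stride.
#' @return list with numeric vectors `C` and `gamma`.
#' @export
svm_grid <- function(step = 4) {
  list(C = 2^seq(-5, 15, by = step), gamma = 2^seq(-15, 3, by = step))
}

#' Train one cell line's SVM
#'
#' Grid-searches C and gamma by internal k-fold cross-validated accuracy,
#' then fits an RBF-kernel SVM on all supplied rows with the winning pair.
#' Ties go to the smallest C, then the smallest gamma. Deterministic given
#' `seed`.
#'
#' @param fps binary fingerprint matrix (rows = compounds, row names = ids).
#' @param labels character vector (`"sensitive"`/`"resistant"`) aligned with
#'   rows.
#' @param grid list with vectors `C` and `gamma` (see [svm_grid()]).
#' @param cv_folds internal CV folds for the grid search (default 5).
#' @param seed integer seed for the internal fold assignment.
#' @param cell_line_id optional id stored in the model.
#' @return object of class `cell_svm`.
#' @export
train_cell_svm <- function(fps, labels, grid = svm_grid(), cv_folds = 5L,
                           seed = 1L, cell_line_id = NA_character_) {
  fps <- .as_fp_matrix(fps)
  y <- factor(labels, levels = c("resistant", "sensitive"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  k <- min(cv_folds, min(table(y)))
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = nrow(fps))))
  combos <- expand.grid(gamma = sort(grid$gamma), C = sort(grid$C))
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(fps[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = combos$C[i], gamma = combos$gamma[i],
                      scale = FALSE)
      correct <- correct + sum(predict(m, fps[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / nrow(fps)
  }, 0)
  best <- combos[order(-acc, combos$C, combos$gamma)[1L], ]
  model <- e1071::svm(fps, y, kernel = "radial", cost = best$C,
                      gamma = best$gamma, scale = FALSE)
  structure(list(model = model, C = best$C, gamma = best$gamma,
                 cv_accuracy = max(acc), cell_line_id = cell_line_id,
                 training_ids = rownames(fps),
                 n_bits = ncol(fps)),
            class = "cell_svm")
}

#' @export
print.cell_svm <- function(x, ...) {
  cat(sprintf("cell_svm [%s]: C = %g, gamma = %g, internal CV accuracy = %.3f, n = %d\n",
              x$cell_line_id, x$C, x$gamma, x$cv_accuracy,
              length(x$training_ids)))
  invisible(x)
}

#' Predict with one cell line's SVM
#'
#' @param model a `cell_svm`.
#' @param fps binary fingerprint matrix (or single vector) matching the
#'   model's bit length.
#' @return data.frame with `compound_id`, `score` (signed decision value,
#'   positive towards sensitive) and `label`.
#' @export
predict_cell_svm <- function(model, fps) {
  stopifnot(inherits(model, "cell_svm"))
  fps <- .as_fp_matrix(fps)
  if (ncol(fps) != model$n_bits) {
    stop("fingerprint length does not match the model", call. = FALSE)
  }
  pr <- predict(model$model, fps, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient decision values so positive means sensitive regardless of the
  # class order libsvm happened to use
  flip <- if (grepl("^sensitive", colnames(attr(pr, "decision.values"))[1L])) 1 else -1
  data.frame(compound_id = if (!is.null(rownames(fps))) rownames(fps)
             else as.character(seq_len(nrow(fps))),
             score = flip * as.numeric(dv),
             label = as.character(pr),
             stringsAsFactors = FALSE)
}

#' Train SVMs for every eligible cell line of a database
#'
#' Eligibility requires at least `min_per_class` compounds in each of the
#' sensitive and resistant classes. Unbalanced cell lines are undersampled
#' with [balance_classes()] before training.
#'
#' @param db an `lcla_db`.
#' @param radius,n_bits fingerprint parameters (defaults 8 and 1024).
#' @param min_per_class minimum class size for eligibility (default 20).
#' @param ratio,height balancing parameters.
#' @param grid,cv_folds,seed grid-search parameters.
#' @return named list of `cell_svm` models, with a `balancing` attribute
#'   holding each cell line's balancing report.
#' @export
train_cell_svms <- function(db, radius = 8L, n_bits = 1024L,
                            min_per_class = 20L, ratio = 1.2, height = 4.5,
                            grid = svm_grid(), cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(db, "lcla_db"))
  fp <- morgan_fingerprint(
    setNames(db$compounds$canonical_smiles, db$compounds$compound_id),
    radius = radius, n_bits = n_bits)
  idx <- per_cell_index(db)
  eligible <- names(idx)[vapply(idx, function(e) {
    length(e$sensitive) >= min_per_class && length(e$resistant) >= min_per_class
  }, TRUE)]
  reports <- list()
  models <- setNames(vector("list", length(eligible)), eligible)
  for (cl in eligible) {
    ids <- c(idx[[cl]]$sensitive, idx[[cl]]$resistant)
    labels <- setNames(rep(c("sensitive", "resistant"),
                           c(length(idx[[cl]]$sensitive),
                             length(idx[[cl]]$resistant))), ids)
    bal <- balance_classes(fp[ids, , drop = FALSE], labels[ids],
                           ratio = ratio, height = height)
    reports[[cl]] <- c(list(cell_line_id = cl), bal$report)
    models[[cl]] <- train_cell_svm(fp[bal$ids, , drop = FALSE],
                                   labels[bal$ids], grid = grid,
                                   cv_folds = cv_folds, seed = seed,
                                   cell_line_id = cl)
  }
  attr(models, "balancing") <- reports
  attr(models, "radius") <- as.integer(radius)
  attr(models, "n_bits") <- as.integer(n_bits)
  models
}

#' Predict query compounds with a set of per-cell-line SVMs
#'
#' @param models named list from [train_cell_svms()].
#' @param query_smiles named character vector of query SMILES.
#' @return prediction data.frame (`compound_id`, `cell_line_id`, `score`,
#'   `label`, `method`, `covered = NA`).
#' @export
predict_cell_svms <- function(models, query_smiles) {
  radius <- attr(models, "radius"); n_bits <- attr(models, "n_bits")
  if (is.null(radius)) radius <- 8L
  if (is.null(n_bits)) n_bits <- models[[1L]]$n_bits
  ids <- if (!is.null(names(query_smiles))) names(query_smiles) else query_smiles
  qfp <- morgan_fingerprint(setNames(strip_to_largest_fragment(query_smiles),
                                     ids), radius = radius, n_bits = n_bits)
  out <- do.call(rbind, lapply(names(models), function(cl) {
    p <- predict_cell_svm(models[[cl]], qfp)
    p$cell_line_id <- cl
    p
  }))
  out$method <- "svm"
  out$covered <- NA
  out <- out[order(out$compound_id, out$cell_line_id),
             c("compound_id", "cell_line_id", "score", "label", "method",
               "covered")]
  rownames(out) <- NULL
  out
}
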