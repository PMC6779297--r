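# Curation of raw growth-inhibition assay tables into a sensitive/resistant
# ligand-cell-line association (LCLA) database.
#
# Pipeline: admit IC50/GI50/CC50 endpoints -> strip salts to the largest
# fragment -> convert concentrations to mol/L -> label sensitive at
# <= 1e-5 M (50% growth inhibition at <= 10 uM) -> discard pairs whose
# replicate assays disagree -> drop cell lines sensitive to fewer than
# `min_sensitive` compounds. Every stage logs its drop count in the audit.

.ADMITTED_ASSAYS <- c("IC50", "GI50", "CC50")

#' Read a raw activity table
#'
#' Reads a CSV/TSV activity table (columns `compound_id`, `smiles`,
#' `cell_line_id`, `assay_type`, `standard_value`, `standard_units`,
#' `standard_relation`) and drops rows with unmapped assay types or missing
#' SMILES/values, counting them in the returned audit.
#'
#' @param path file path; a `.tsv`/`.txt` extension selects tab separation.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param col_map optional named character vector mapping required column
#'   names to the names actually present, e.g.
#'   `c(compound_id = "molregno", smiles = "canonical_smiles")`.
#' @return list with `records` (data.frame) and `audit` (named counts).
#' @export
parse_activity_table <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(df)) {
        names(df)[names(df) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("compound_id", "smiles", "cell_line_id", "assay_type",
                "standard_value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("activity table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"standard_units" %in% names(df)) df$standard_units <- NA_character_
  if (!"standard_relation" %in% names(df)) df$standard_relation <- "="
  n0 <- nrow(df)
  keep_assay <- toupper(trimws(df$assay_type)) %in% .ADMITTED_ASSAYS
  df <- df[keep_assay, , drop = FALSE]
  n1 <- nrow(df)
  has_smiles <- !is.na(df$smiles) & nzchar(trimws(df$smiles))
  has_value <- !is.na(suppressWarnings(as.numeric(df$standard_value))) &
    suppressWarnings(as.numeric(df$standard_value)) > 0
  df <- df[has_smiles & has_value, , drop = FALSE]
  df$standard_value <- as.numeric(df$standard_value)
  rownames(df) <- NULL
  list(records = df,
       audit = c(n_input = n0,
                 dropped_assay_type = n0 - n1,
                 dropped_missing_smiles_or_value = n1 - nrow(df)))
}

#' Convert a concentration to mol/L
#'
#' @param value numeric concentration(s).
#' @param units unit string(s): `nM`, `uM` (or `µM`), `mM`, `M`
#'   (case-insensitive).
#' @return concentration in mol/L; `NA` with a warning for unknown units.
#' @export
to_molar <- function(value, units) {
  factor <- c(nm = 1e-9, um = 1e-6, "µm" = 1e-6, mm = 1e-3, m = 1)
  f <- factor[tolower(trimws(units))]
  if (anyNA(f)) {
    warning("unknown concentration unit(s): ",
            paste(unique(units[is.na(f)]), collapse = ", "), call. = FALSE)
  }
  unname(value * f)
}

#' Label a concentration as sensitive or resistant
#'
#' A compound-cell-line association is sensitive when the growth-inhibiting
#' concentration is at or below `threshold` mol/L (default 1e-5 M, i.e. 50%
#' inhibition at <= 10 uM).
#'
#' @param concentration_molar positive concentration(s) in mol/L.
#' @param threshold sensitivity boundary in mol/L.
#' @return character vector of `"sensitive"` / `"resistant"`.
#' @export
label_activity <- function(concentration_molar, threshold = 1e-5) {
  if (any(!is.na(concentration_molar) & concentration_molar <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  ifelse(concentration_molar <= threshold, "sensitive", "resistant")
}

#' Resolve replicate labels for one compound-cell-line pair
#'
#' All replicate assays (across IC50/GI50/CC50, pooled) must agree; a pair
#' with conflicting labels is discarded.
#'
#' @param labels character vector of `"sensitive"`/`"resistant"`.
#' @return the common label, or `NA_character_` when replicates disagree.
#' @export
resolve_replicates <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  if (length(u) == 1L) u else NA_character_
}

#' Build a curated LCLA database from raw activity records
#'
#' Applies, in order: assay-endpoint filter, relation filter, unit
#' conversion, largest-fragment stripping, structure-based compound-id
#' merging, sensitivity labeling, replicate resolution, and the
#' minimum-sensitive cell-line filter. An audit of counts dropped at each
#' stage is attached to the result.
#'
#' @param records data.frame of raw records (see [parse_activity_table()]),
#'   or the list that function returns.
#' @param min_sensitive minimum number of sensitive compounds a cell line
#'   must have to be retained (default 10).
#' @param relation_policy `"strict"` uses only records whose relation is
#'   `"="` or empty; `"gt_resistant"` additionally admits `">"` records with
#'   values above the sensitivity threshold as resistant evidence.
#' @param threshold sensitivity boundary in mol/L.
#' @return an object of class `lcla_db`: list with `pairs` (data.frame
#'   `compound_id`, `cell_line_id`, `label`), `compounds` (data.frame
#'   `compound_id`, `canonical_smiles`) and `audit`.
#' @export
build_lcla_database <- function(records, min_sensitive = 10,
                                relation_policy = c("strict", "gt_resistant"),
                                threshold = 1e-5) {
  relation_policy <- match.arg(relation_policy)
  audit <- c()
  if (is.list(records) && !is.data.frame(records) && "records" %in% names(records)) {
    audit <- records$audit
    records <- records$records
  }
  df <- records
  audit["n_records"] <- nrow(df)
  if (nrow(df) == 0L) return(.empty_lcla_db(audit))

  # endpoint + missing-field filter (idempotent re-application)
  keep <- toupper(trimws(df$assay_type)) %in% .ADMITTED_ASSAYS &
    !is.na(df$smiles) & nzchar(trimws(df$smiles)) &
    !is.na(df$standard_value) & df$standard_value > 0
  audit["dropped_endpoint_or_missing"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  # relation symbols: censored values cannot be compared to the threshold
  rel <- trimws(as.character(df$standard_relation))
  rel[is.na(rel)] <- ""
  eq <- rel %in% c("", "=", "==")
  gt <- rel %in% c(">", ">=", ">>")
  keep <- if (relation_policy == "gt_resistant") eq | gt else eq
  audit["dropped_relation"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rel <- rel[keep]

  # unit conversion
  molar <- suppressWarnings(to_molar(df$standard_value, df$standard_units))
  audit["dropped_units"] <- sum(is.na(molar))
  df <- df[!is.na(molar), , drop = FALSE]
  rel <- rel[!is.na(molar)]
  molar <- molar[!is.na(molar)]

  # ">" records are resistant evidence only when above the threshold
  if (relation_policy == "gt_resistant") {
    bad_gt <- rel %in% c(">", ">=", ">>") & molar <= threshold
    audit["dropped_censored_below_threshold"] <- sum(bad_gt)
    df <- df[!bad_gt, , drop = FALSE]
    molar <- molar[!bad_gt]
  }

  if (nrow(df) == 0L) return(.empty_lcla_db(audit))

  # largest-fragment canonical structures; unparseable records are skipped
  can <- strip_to_largest_fragment(df$smiles, on_invalid = "na")
  audit["dropped_invalid_structure"] <- sum(is.na(can))
  df <- df[!is.na(can), , drop = FALSE]
  molar <- molar[!is.na(can)]
  can <- can[!is.na(can)]
  if (nrow(df) == 0L) return(.empty_lcla_db(audit))

  # merge ids that share a canonical largest-fragment structure
  key_of <- tapply(as.character(df$compound_id), can,
                   function(ids) sort(unique(ids))[1L])
  merged_from <- tapply(as.character(df$compound_id), can,
                        function(ids) sort(unique(ids)))
  cid <- unname(key_of[can])
  audit["n_structures"] <- length(key_of)
  audit["n_merged_input_ids"] <-
    sum(lengths(merged_from)) - length(merged_from)

  lab <- label_activity(molar, threshold)

  # replicate agreement, pooled across assay types
  pair_key <- paste(cid, df$cell_line_id, sep = "\r")
  resolved <- tapply(lab, pair_key, resolve_replicates)
  audit["dropped_conflicting_pairs"] <- sum(is.na(resolved))
  ok <- !is.na(resolved)
  keys <- strsplit(names(resolved)[ok], "\r", fixed = TRUE)
  pairs <- data.frame(
    compound_id = vapply(keys, `[[`, "", 1L),
    cell_line_id = vapply(keys, `[[`, "", 2L),
    label = unname(resolved[ok]),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$cell_line_id, pairs$compound_id), , drop = FALSE]
  rownames(pairs) <- NULL

  compounds <- data.frame(
    compound_id = unname(key_of),
    canonical_smiles = names(key_of),
    stringsAsFactors = FALSE
  )
  compounds <- compounds[order(compounds$compound_id), , drop = FALSE]
  rownames(compounds) <- NULL

  db <- structure(list(pairs = pairs, compounds = compounds,
                       audit = as.list(audit),
                       merged_ids = merged_from,
                       min_sensitive = min_sensitive),
                  class = "lcla_db")
  filter_cell_lines(db, min_sensitive)
}

.empty_lcla_db <- function(audit = c()) {
  structure(list(
    pairs = data.frame(compound_id = character(), cell_line_id = character(),
                       label = character(), stringsAsFactors = FALSE),
    compounds = data.frame(compound_id = character(),
                           canonical_smiles = character(),
                           stringsAsFactors = FALSE),
    audit = as.list(audit), merged_ids = list(), min_sensitive = NA
  ), class = "lcla_db")
}

#' Remove cell lines with too few sensitive compounds
#'
#' Drops every pair (sensitive and resistant) of any cell line with fewer
#' than `min_sensitive` sensitive compounds, then drops compounds left with
#' no pairs.
#'
#' @param db an `lcla_db`.
#' @param min_sensitive minimum sensitive-compound count.
#' @return the filtered `lcla_db` (audit updated).
#' @export
filter_cell_lines <- function(db, min_sensitive = 10) {
  stopifnot(inherits(db, "lcla_db"))
  p <- db$pairs
  sens <- p[p$label == "sensitive", , drop = FALSE]
  counts <- table(sens$cell_line_id)
  all_cells <- unique(p$cell_line_id)
  n_sens <- setNames(rep(0L, length(all_cells)), all_cells)
  n_sens[names(counts)] <- as.integer(counts)
  keep_cells <- names(n_sens)[n_sens >= min_sensitive]
  dropped_cells <- setdiff(all_cells, keep_cells)
  p2 <- p[p$cell_line_id %in% keep_cells, , drop = FALSE]
  rownames(p2) <- NULL
  db$audit$dropped_cell_lines <- length(dropped_cells)
  db$audit$dropped_pairs_cell_filter <- nrow(p) - nrow(p2)
  db$pairs <- p2
  db$compounds <- db$compounds[
    db$compounds$compound_id %in% unique(p2$compound_id), , drop = FALSE]
  rownames(db$compounds) <- NULL
  db$min_sensitive <- min_sensitive
  db
}

#' Per-cell-line index of sensitive and resistant compound ids
#'
#' @param db an `lcla_db`.
#' @return named list: `cell_line_id -> list(sensitive =, resistant =)`.
#' @export
per_cell_index <- function(db) {
  stopifnot(inherits(db, "lcla_db"))
  p <- db$pairs
  cells <- sort(unique(p$cell_line_id))
  setNames(lapply(cells, function(cl) {
    q <- p[p$cell_line_id == cl, , drop = FALSE]
    list(sensitive = sort(q$compound_id[q$label == "sensitive"]),
         resistant = sort(q$compound_id[q$label == "resistant"]))
  }), cells)
}

#' Build an `lcla_db` from an already-labeled pair table
#'
#' Ingests a pre-curated table (`compound_id`, `smiles`, `cell_line_id`,
#' `label`), canonicalizing structures and applying the same replicate and
#' cell-line filters as [build_lcla_database()]. Re-ingesting a curated
#' table reproduces it (the pipeline is idempotent).
#'
#' @param pairs data.frame with columns `compound_id`, `smiles` (or
#'   `canonical_smiles`), `cell_line_id`, `label`.
#' @inheritParams build_lcla_database
#' @return an `lcla_db`.
#' @export
lcla_from_pairs <- function(pairs, min_sensitive = 10) {
  smi_col <- if ("canonical_smiles" %in% names(pairs)) "canonical_smiles" else "smiles"
  stopifnot(all(c("compound_id", smi_col, "cell_line_id", "label") %in%
                  names(pairs)))
  lab <- tolower(trimws(pairs$label))
  ok <- lab %in% c("sensitive", "resistant")
  if (!all(ok)) {
    warning(sum(!ok), " pair(s) with unknown label token dropped",
            call. = FALSE)
  }
  pairs <- pairs[ok, , drop = FALSE]
  # encode labels as concentrations on either side of the boundary and
  # reuse the full pipeline so all invariants hold by construction
  records <- data.frame(
    compound_id = pairs$compound_id,
    smiles = pairs[[smi_col]],
    cell_line_id = pairs$cell_line_id,
    assay_type = "IC50",
    standard_value = ifelse(lab[ok] == "sensitive", 1, 100),
    standard_units = "uM",
    standard_relation = "=",
    stringsAsFactors = FALSE
  )
  build_lcla_database(records, min_sensitive = min_sensitive)
}

#' @export
print.lcla_db <- function(x, ...) {
  n_cells <- length(unique(x$pairs$cell_line_id))
  n_sens <- sum(x$pairs$label == "sensitive")
  cat("Curated LCLA database\n")
  cat("  cell lines:", n_cells, "\n")
  cat("  compounds: ", nrow(x$compounds), "\n")
  cat("  pairs:     ", nrow(x$pairs), sprintf("(%d sensitive, %d resistant)\n",
      n_sens, nrow(x$pairs) - n_sens))
  invisible(x)
}
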