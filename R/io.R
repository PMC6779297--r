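# File formats: SMILES (.smi, one "SMILES[<tab or space>]id" per line, '#'
# comments), CSV pair/prediction tables, JSON audit reports. Everything is
# plain text and round-trips losslessly.

#' Read a SMILES file
#'
#' @param path `.smi` file: one SMILES and an optional id per line,
#'   whitespace-separated; lines starting with `#` are ignored.
#' @return named character vector of SMILES (names are ids; missing ids
#'   become `mol<i>`).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else sprintf("mol%d", i)
  }, "")
  setNames(smi, ids)
}

#' Write a SMILES file
#'
#' @param smiles named character vector (names are written as ids).
#' @param path output path.
#' @export
write_smiles <- function(smiles, path) {
  ids <- if (!is.null(names(smiles))) names(smiles) else
    sprintf("mol%d", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), path)
}

#' Read a labeled pair table
#'
#' Accepts curated pair tables (`compound_id`, `smiles` or
#' `canonical_smiles`, `cell_line_id`, `label`), with optional column
#' aliasing for externally produced tables. Rows with unknown label tokens
#' are dropped with a warning; more than 50% malformed rows is an error.
#'
#' @param path CSV/TSV path.
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names.
#' @return data.frame.
#' @export
read_pair_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(df)) {
        names(df)[names(df) == col_map[[std]]] <- std
      }
    }
  }
  if ("canonical_smiles" %in% names(df) && !"smiles" %in% names(df)) {
    df$smiles <- df$canonical_smiles
  }
  need <- c("compound_id", "smiles", "cell_line_id", "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("pair table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- tolower(trimws(df$label)) %in% c("sensitive", "resistant")
  if (sum(!ok) > nrow(df) / 2) {
    stop("more than half of the pair-table rows are malformed", call. = FALSE)
  }
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with unknown label token dropped",
            call. = FALSE)
  }
  df <- df[ok, need, drop = FALSE]
  df$label <- tolower(trimws(df$label))
  rownames(df) <- NULL
  df
}

#' Write a curated database as a pair table
#'
#' @param db an `lcla_db`.
#' @param path output CSV path.
#' @export
write_pair_table <- function(db, path) {
  stopifnot(inherits(db, "lcla_db"))
  out <- merge(db$pairs, db$compounds, by = "compound_id")
  out <- out[order(out$cell_line_id, out$compound_id),
             c("compound_id", "canonical_smiles", "cell_line_id", "label")]
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Write predictions to CSV
#'
#' @param predictions data.frame from [fish()], [predict_cell_svms()] or
#'   [combined_predict()].
#' @param path output CSV path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
}

#' Write a fingerprint cache
#'
#' Stores a fingerprint matrix as a plain-text CSV (one hex-encoded bit
#' string per compound) together with its radius and bit length, so
#' expensive fingerprinting can be reused across runs.
#'
#' @param fps fingerprint matrix from [morgan_fingerprint()] (row names are
#'   compound ids; `n_bits` must be a multiple of 8).
#' @param path output CSV path.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(!is.null(rownames(fps)), ncol(fps) %% 8L == 0L)
  hex <- apply(fps, 1L, function(row) {
    paste(sprintf("%02x", as.integer(packBits(as.logical(row)))),
          collapse = "")
  })
  df <- data.frame(compound_id = rownames(fps),
                   radius = attr(fps, "radius") %||% NA_integer_,
                   n_bits = ncol(fps), bits_hex = hex,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' Read a fingerprint cache
#'
#' @param path CSV written by [write_fingerprints()].
#' @return integer 0/1 matrix with `radius`/`n_bits` attributes.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "radius", "n_bits", "bits_hex") %in%
                  names(df)), length(unique(df$n_bits)) == 1L)
  n_bits <- df$n_bits[1L]
  fp <- t(vapply(df$bits_hex, function(h) {
    bytes <- strtoi(substring(h, seq(1L, nchar(h), 2L),
                              seq(2L, nchar(h), 2L)), 16L)
    as.integer(rawToBits(as.raw(bytes)))
  }, integer(n_bits)))
  rownames(fp) <- df$compound_id
  attr(fp, "radius") <- df$radius[1L]
  attr(fp, "n_bits") <- n_bits
  fp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an audit report as JSON
#'
#' @param audit named list of counts (e.g. `db$audit`).
#' @param path output JSON path.
#' @export
write_audit <- function(audit, path) {
  jsonlite::write_json(audit, path, auto_unbox = TRUE, pretty = TRUE)
}
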