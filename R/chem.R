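# SMILES handling on top of OpenBabel (via ChemmineR/ChemmineOB).
#
# OpenBabel aborts a multi-line conversion at the first invalid structure, so
# canonicalization batches optimistically and retries molecule-by-molecule
# only when the batch comes back short.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES. Invalid structures are
#' returned as `NA` when `on_invalid = "na"`, or raise an error (the default).
#'
#' @param smiles character vector of SMILES strings.
#' @param on_invalid `"error"` to stop on the first unparseable structure,
#'   `"na"` to return `NA` for it.
#' @return character vector of canonical SMILES, same length as `smiles`.
#' @export
canonical_smiles <- function(smiles, on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (any(ok)) {
    idx <- which(ok)
    batch <- .ob_can_batch(smiles[idx])
    if (anyNA(batch)) {
      for (j in which(is.na(batch))) batch[j] <- .ob_can_one(smiles[idx[j]])
    }
    out[idx] <- batch
  }
  if (on_invalid == "error" && anyNA(out[ok])) {
    bad <- smiles[ok][is.na(out[ok])]
    stop("invalid SMILES: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  out
}

# One batched OpenBabel call; NA for every molecule whose tag is missing from
# the output (the batch stops at the first parse failure).
.ob_can_batch <- function(smiles) {
  tags <- paste0("cfx", seq_along(smiles))
  input <- paste0(paste(smiles, tags, collapse = "\n"), "\n")
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", input),
                  error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  can <- vapply(parts, `[[`, "", 1L)
  out <- rep(NA_character_, length(smiles))
  out[match(got, tags)] <- can
  out
}

.ob_can_one <- function(s) {
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, " x\n")),
                  error = function(e) "")
  line <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(line) == 0L || !nzchar(line[1L])) return(NA_character_)
  strsplit(line[1L], "\t", fixed = TRUE)[[1]][1L]
}

# Atomic numbers for elements we expect in drug-like SMILES; anything else
# falls back to a deterministic hash of the symbol so fingerprints stay
# well defined.
.ELEMENT_Z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
  Ca = 20, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
  As = 33, Se = 34, Br = 35, Sr = 38, Mo = 42, Ag = 47, Sn = 50, Sb = 51,
  I = 53, Ba = 56, Pt = 78, Au = 79, Hg = 80
)

.element_code <- function(sym) {
  z <- unname(.ELEMENT_Z[sym])
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- vapply(sym[miss],
                      function(s) 200 + sum(utf8ToInt(s)) %% 1000, 0)
  }
  z
}

# Old-style SDF atom-block charge codes -> formal charge.
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

.ELEMENT_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, Ag = 107.87, Sn = 118.71,
  I = 126.9, Pt = 195.08, Au = 196.97, Hg = 200.59, Li = 6.94
)

# Tokenize the atoms of a SMILES string (no graph): returns element symbols
# and formal charges. Used for heavy-atom counting of salt fragments and as
# a fallback for single-atom molecules that OpenBabel's SDF round-trip
# cannot represent.
.smiles_atoms <- function(smiles) {
  pat <- "\\[[^]]*\\]|Cl|Br|Si|Se|[BCNOPSFI]|[bcnops]"
  m <- gregexpr(pat, smiles)[[1]]
  if (m[1] == -1L) return(data.frame(sym = character(), charge = integer()))
  tok <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  sym <- character(length(tok)); chg <- integer(length(tok))
  for (i in seq_along(tok)) {
    t <- tok[i]
    if (startsWith(t, "[")) {
      inner <- sub("^\\[\\d*", "", sub("\\]$", "", t))
      el <- regmatches(inner, regexpr("^[A-Z][a-z]?|^[a-z]", inner))
      sym[i] <- if (nchar(el) > 1L || el %in% c("b","c","n","o","p","s")) {
        paste0(toupper(substr(el, 1, 1)), substring(el, 2))
      } else el
      cm <- regmatches(inner, regexpr("[+-]+\\d*$|[+-]\\d+", inner))
      if (length(cm) == 1L && nzchar(cm)) {
        sgn <- if (startsWith(cm, "-")) -1L else 1L
        dig <- gsub("[+-]", "", cm)
        chg[i] <- sgn * if (nzchar(dig)) as.integer(dig) else nchar(gsub("\\d", "", cm))
      }
    } else {
      sym[i] <- if (nchar(t) > 1L) t else toupper(t)
    }
  }
  data.frame(sym = sym, charge = chg, stringsAsFactors = FALSE)
}

.heavy_atom_count <- function(smiles) {
  a <- .smiles_atoms(smiles)
  sum(a$sym != "H")
}

.heavy_mass <- function(smiles) {
  a <- .smiles_atoms(smiles)
  m <- .ELEMENT_MASS[a$sym[a$sym != "H"]]
  m[is.na(m)] <- 100
  sum(m)
}

#' @keywords internal
# Parse SMILES into light-weight molecular graphs:
# list(elem, charge, bonds = matrix[, c("a1","a2","order")]) per molecule.
# Hydrogens are implicit (OpenBabel SDF from SMILES omits them).
.mol_graphs <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  names(smiles) <- paste0("m", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  valid <- suppressWarnings(ChemmineR::validSDF(sdf))
  lapply(seq_along(smiles), function(i) {
    if (!valid[i]) {
      # single-atom molecules (bare ions, HCl, ...) have no bond block and
      # fail the SDF round-trip; build the trivial graph from the SMILES
      a <- .smiles_atoms(smiles[[i]])
      if (nrow(a) != 1L) stop("cannot parse structure: ", smiles[[i]],
                              call. = FALSE)
      return(list(elem = a$sym, charge = a$charge,
                  bonds = matrix(numeric(0), ncol = 3L),
                  n_heavy = sum(a$sym != "H")))
    }
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    sym <- sub("_.*$", "", rownames(ab))
    chg <- .SDF_CHARGE[as.character(ab[, "C5"])]
    chg[is.na(chg)] <- 0L
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
      matrix(numeric(0), ncol = 3L)
    } else {
      cbind(bb[, 1L], bb[, 2L], bb[, 3L])
    }
    heavy <- sym != "H"
    list(elem = sym, charge = as.integer(chg), bonds = bonds,
         n_heavy = sum(heavy))
  })
}

#' Reduce a SMILES to its largest fragment
#'
#' Salts and mixtures are written as dot-separated fragments; only the
#' fragment with the most heavy atoms is kept (ties broken by molecular
#' weight, then by lexicographic canonical SMILES) and returned in canonical
#' form. Single-fragment input returns its canonical form unchanged in
#' composition.
#'
#' @param smiles character vector of SMILES.
#' @inheritParams canonical_smiles
#' @return character vector of canonical largest-fragment SMILES.
#' @export
strip_to_largest_fragment <- function(smiles, on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  can <- canonical_smiles(smiles, on_invalid = on_invalid)
  vapply(can, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    frags <- unique(frags)
    heavy <- vapply(frags, .heavy_atom_count, 0)
    mw <- vapply(frags, .heavy_mass, 0)
    canf <- canonical_smiles(frags, on_invalid = "na")
    ord <- order(-heavy, -mw, canf)
    canf[ord[1L]]
  }, "", USE.NAMES = FALSE)
}
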