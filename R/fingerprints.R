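# Hashed circular Morgan fingerprints (the ECFP family: diameter = 2 x
# radius, so radius 2/4/8 corresponds to ECFP4/ECFP8/ECFP16) and Tanimoto
# similarity. Fingerprints are hashed substructure identifiers folded into a
# fixed-length binary vector; identifiers are built by iteratively hashing
# each atom's invariants with the (bond order, identifier) multiset of its
# neighbours, which makes them independent of atom ordering in the input
# SMILES. Molecules are canonicalized before graph extraction, so a molecule
# written two different ways always yields the same bits.

# 32-bit polynomial hash over non-negative integers < 2^31 (exact in
# doubles: intermediate values stay below 2^53).
.hash32 <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147483647
  h
}

.morgan_bits_one <- function(graph, radius, n_bits) {
  n <- length(graph$elem)
  z <- .element_code(graph$elem)
  deg <- integer(n)
  bsum <- numeric(n)
  adj <- vector("list", n)
  b <- graph$bonds
  if (nrow(b) > 0L) {
    for (k in seq_len(nrow(b))) {
      a1 <- b[k, 1L]; a2 <- b[k, 2L]; o <- b[k, 3L]
      adj[[a1]] <- rbind(adj[[a1]], c(a2, o))
      adj[[a2]] <- rbind(adj[[a2]], c(a1, o))
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
      bsum[a1] <- bsum[a1] + o; bsum[a2] <- bsum[a2] + o
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    .hash32(c(z[i], deg[i], bsum[i], graph$charge[i] + 8))
  }, 0)
  all_ids <- ids
  if (radius >= 1L) {
    for (it in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        if (is.null(nb)) return(.hash32(c(it, ids[i])))
        nid <- ids[nb[, 1L]]
        ord <- order(nb[, 2L], nid)
        .hash32(c(it, ids[i], as.vector(rbind(nb[ord, 2L], nid[ord]))))
      }, 0)
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(all_ids %% n_bits)) + 1L
}

#' Morgan circular fingerprints for a set of SMILES
#'
#' Computes hashed, folded circular fingerprints of the given radius for each
#' molecule and returns them as a binary matrix (one row per molecule). The
#' same (SMILES, radius, n_bits) always yields the same bits, and two SMILES
#' describing the same molecule yield identical rows.
#'
#' @param smiles character vector of SMILES; names (if any) become row names,
#'   otherwise the SMILES themselves do.
#' @param radius neighbourhood radius (bond hops); the field's usual choices
#'   here are 2, 4 and 8 (ECFP4/ECFP8/ECFP16).
#' @param n_bits folded length, a power of two (default 1024).
#' @return integer 0/1 matrix, `length(smiles)` rows by `n_bits` columns.
#' @export
morgan_fingerprint <- function(smiles, radius = 8L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            radius >= 1L, n_bits >= 2L, bitwAnd(n_bits, n_bits - 1L) == 0L)
  can <- canonical_smiles(smiles)  # errors on invalid structures
  graphs <- .mol_graphs(can)
  fp <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(graphs)) {
    fp[i, .morgan_bits_one(graphs[[i]], as.integer(radius), n_bits)] <- 1L
  }
  rownames(fp) <- if (!is.null(names(smiles))) names(smiles) else smiles
  attr(fp, "radius") <- as.integer(radius)
  attr(fp, "n_bits") <- as.integer(n_bits)
  fp
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits; defined as 0 when both vectors
#' are empty.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity between two fingerprint matrices
#'
#' @param A,B binary matrices with the same number of columns (rows are
#'   molecules). `B` defaults to `A`.
#' @return `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
tanimoto_similarity <- function(A, B = A) {
  A <- .as_fp_matrix(A); B <- .as_fp_matrix(B)
  if (ncol(A) != ncol(B)) stop("fingerprint lengths differ", call. = FALSE)
  inter <- tcrossprod(A, B)
  pa <- rowSums(A); pb <- rowSums(B)
  un <- outer(pa, pb, "+") - inter
  s <- ifelse(un == 0, 0, inter / un)
  dimnames(s) <- list(rownames(A), rownames(B))
  s
}

#' Tanimoto distance matrix
#'
#' Symmetric matrix of `1 - Tc` with zero diagonal, the input to the Ward
#' clustering used for class balancing.
#'
#' @param fps binary fingerprint matrix (rows are molecules).
#' @return symmetric numeric matrix.
#' @export
tanimoto_distance_matrix <- function(fps) {
  d <- 1 - tanimoto_similarity(fps)
  diag(d) <- 0
  d
}

.as_fp_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}
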