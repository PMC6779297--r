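# Class balancing by hierarchical-clustering undersampling of the majority
# class. The majority compounds are Ward-clustered on their Tanimoto
# distance matrix (tree cut at a fixed height); if that yields fewer
# clusters (Nc) than the minority size (Nm), Nm compounds are drawn from the
# clusters proportionally to cluster size; otherwise the majority is
# re-clustered into exactly Nm clusters and each cluster's medoid is kept.

#' Are two class sizes balanced?
#'
#' A dataset is unbalanced when the majority class holds more than `ratio`
#' times the compounds of the minority class (default 1.2).
#'
#' @param n_majority,n_minority class sizes (>= 1).
#' @param ratio imbalance tolerance.
#' @return logical.
#' @export
is_balanced <- function(n_majority, n_minority, ratio = 1.2) {
  if (n_majority < 1 || n_minority < 1) {
    stop("class sizes must be >= 1", call. = FALSE)
  }
  # small tolerance so exact boundaries (e.g. 6 vs 5) are not lost to
  # binary-float representation of the ratio
  n_majority <= ratio * n_minority + 1e-9
}

#' Ward clustering of a distance matrix at a fixed height
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method `"ward.D2"`), cut at `height`.
#'
#' @param distance_matrix symmetric distance matrix (e.g. from
#'   [tanimoto_distance_matrix()]).
#' @param height tree cut height (default 4.5).
#' @return integer cluster labels named by the matrix row names.
#' @export
ward_clusters <- function(distance_matrix, height = 4.5) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (nrow(d) == 1L) {
    return(setNames(1L, rownames(d)))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  stats::cutree(tree, h = height)
}

#' Undersample the majority class to the minority size
#'
#' @param majority_fps fingerprint matrix of the majority-class compounds
#'   (row names are compound ids).
#' @param n_minority target size Nm (must be smaller than the majority).
#' @param height Ward tree cut height defining the initial clusters.
#' @return list with `selected_ids` (length Nm) and `report`: cell-agnostic
#'   balancing report (`branch`, `n_clusters`, `n_minority`).
#' @export
reduce_majority <- function(majority_fps, n_minority, height = 4.5) {
  fps <- .as_fp_matrix(majority_fps)
  ids <- rownames(fps)
  if (is.null(ids)) stop("majority fingerprints need row names", call. = FALSE)
  nm <- as.integer(n_minority)
  if (nm < 1L || nm >= nrow(fps)) {
    stop("n_minority must satisfy 1 <= Nm < majority size", call. = FALSE)
  }
  d <- tanimoto_distance_matrix(fps)
  cl <- ward_clusters(d, height)
  nc <- length(unique(cl))
  if (nc < nm) {
    selected <- .proportional_pick(d, cl, nm, ids)
    branch <- "proportional"
  } else {
    tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    cl_k <- stats::cutree(tree, k = nm)
    selected <- vapply(split(ids, cl_k), function(members) {
      .medoid(d, members)
    }, "")
    branch <- "centroid"
  }
  selected <- unname(sort(selected))
  list(selected_ids = selected,
       report = list(branch = branch, n_clusters = nc, n_minority = nm,
                     height = height))
}

# Medoid: member with minimum summed distance to the others; ties broken by
# lexicographic id (a mean bit vector is not a compound, so the centroid of
# a cluster in fingerprint space is its medoid).
.medoid <- function(d, members) {
  if (length(members) == 1L) return(members)
  tot <- rowSums(d[members, members, drop = FALSE])
  members[order(tot, members)][1L]
}

# Largest-remainder apportionment of Nm picks over clusters, capped at
# cluster sizes; within each cluster the most central compounds (ascending
# summed within-cluster distance, ties by id) are taken first.
.proportional_pick <- function(d, cl, nm, ids) {
  groups <- split(ids, cl)
  sizes <- lengths(groups)
  total <- sum(sizes)
  exact <- nm * sizes / total
  quota <- pmin(floor(exact), sizes)
  rem <- nm - sum(quota)
  if (rem > 0L) {
    # distribute remaining picks by largest fractional part among clusters
    # with spare capacity; ties to larger clusters, then lower cluster index
    frac <- exact - floor(exact)
    ord <- order(-frac, -sizes, seq_along(sizes))
    for (g in rep(ord, length.out = 10L * length(ord))) {
      if (rem == 0L) break
      if (quota[g] < sizes[g]) {
        quota[g] <- quota[g] + 1L
        rem <- rem - 1L
      }
    }
  }
  unlist(lapply(seq_along(groups), function(g) {
    members <- groups[[g]]
    if (quota[g] == 0L) return(character(0))
    tot <- if (length(members) == 1L) 0 else
      rowSums(d[members, members, drop = FALSE])
    members[order(tot, members)][seq_len(quota[g])]
  }), use.names = FALSE)
}

#' Balance one cell line's training classes
#'
#' Applies the 1.2-ratio test and, when unbalanced, [reduce_majority()] to
#' whichever class is larger.
#'
#' @param fps fingerprint matrix for all of the cell line's compounds.
#' @param labels named character vector (`"sensitive"`/`"resistant"`) aligned
#'   with `rownames(fps)`.
#' @param ratio imbalance tolerance.
#' @param height Ward cut height.
#' @return list with `ids` (compound ids retained for training) and
#'   `report` (a balancing report including `balanced` and `branch`).
#' @export
balance_classes <- function(fps, labels, ratio = 1.2, height = 4.5) {
  stopifnot(!is.null(rownames(fps)), length(labels) == nrow(fps))
  tab <- table(factor(labels, levels = c("sensitive", "resistant")))
  if (any(tab == 0L)) stop("both classes must be present", call. = FALSE)
  maj_lab <- names(tab)[which.max(tab)]
  min_lab <- setdiff(names(tab), maj_lab)[1L]
  if (is_balanced(max(tab), min(tab), ratio)) {
    return(list(ids = sort(rownames(fps)),
                report = list(balanced = TRUE, branch = "none",
                              n_sensitive = unname(tab["sensitive"]),
                              n_resistant = unname(tab["resistant"]),
                              n_clusters = NA_integer_,
                              n_minority = unname(min(tab)))))
  }
  maj_ids <- rownames(fps)[labels == maj_lab]
  min_ids <- rownames(fps)[labels == min_lab]
  red <- reduce_majority(fps[maj_ids, , drop = FALSE], length(min_ids),
                         height = height)
  list(ids = sort(c(min_ids, red$selected_ids)),
       report = c(list(balanced = FALSE,
                       n_sensitive = unname(tab["sensitive"]),
                       n_resistant = unname(tab["resistant"])),
                  red$report))
}
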