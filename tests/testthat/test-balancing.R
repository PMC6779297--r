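test_that("balance test uses the 1.2x majority rule inclusively", {
  expect_true(is_balanced(100, 90))
  expect_true(is_balanced(120, 100))   # not MORE than 1.2x
  expect_false(is_balanced(121, 100))
  expect_true(is_balanced(6, 5))       # exact boundary, small counts
  expect_false(is_balanced(7, 5))
  expect_error(is_balanced(0, 5), ">= 1")
})

test_that("ward clustering cuts the tree at the requested height", {
  # two tight groups at maximal separation: block distance matrix
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0.05; d[4:6, 4:6] <- 0.05
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("m", 1:6)
  cl <- ward_clusters(d, height = 0.5)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:3])), 1L)
  # identical compounds collapse into one cluster
  d0 <- matrix(0, 4, 4, dimnames = list(paste0("z", 1:4), paste0("z", 1:4)))
  expect_equal(length(unique(ward_clusters(d0, 4.5))), 1L)
  # the same block structure merges fully below a high cutoff
  expect_equal(length(unique(ward_clusters(d, height = 4.5))), 1L)
  expect_error(ward_clusters(matrix(1:6, 2, 3)), "square")
})

test_that("every merge within an h-cut cluster happened below the cut", {
  fps <- random_fp_matrix(30L, n_bits = 128L, n_on = 14L, seed = 9)
  d <- tanimoto_distance_matrix(fps)
  tree <- hclust(as.dist(d), method = "ward.D2")
  for (h in c(0.5, 1, 4.5)) {
    cl <- ward_clusters(d, height = h)
    # cutree with the same h on the same tree is the definition; check the
    # cluster count equals the number of merges above the height + 1
    expect_equal(length(unique(cl)), sum(tree$height > h) + 1L)
  }
})

test_that("proportional quotas follow cluster sizes (largest remainder)", {
  # two clear clusters of sizes 30 and 10 -> quotas 15 and 5 at Nm = 20
  set.seed(42)
  big <- matrix(0L, 30, 64); big[, 1:16] <- 1L
  for (i in 1:30) big[i, 16 + sample.int(8, 2)] <- 1L
  small <- matrix(0L, 10, 64); small[, 33:48] <- 1L
  for (i in 1:10) small[i, 48 + sample.int(8, 2)] <- 1L
  fps <- rbind(big, small)
  rownames(fps) <- sprintf("m%02d", 1:40)
  d <- tanimoto_distance_matrix(fps)
  # a cut height separating the two planted blocks (the blocks merge
  # internally well below 2, and with each other above it)
  cl <- ward_clusters(d, height = 2)
  expect_equal(length(unique(cl)), 2L)
  red <- reduce_majority(fps, 20L, height = 2)
  expect_identical(red$report$branch, "proportional")
  picked_big <- sum(red$selected_ids %in% sprintf("m%02d", 1:30))
  expect_equal(picked_big, 15L)
  expect_equal(length(red$selected_ids), 20L)
})

test_that("centroid branch returns one medoid per re-clustered group", {
  fps <- random_fp_matrix(25L, n_bits = 256L, n_on = 20L, seed = 2)
  # random fingerprints are far apart: Nc at height 4.5 is large, so a
  # small Nm exercises the re-cluster-to-Nm-medoids branch
  red <- reduce_majority(fps, 5L, height = 0.2)
  expect_identical(red$report$branch, "centroid")
  expect_equal(length(red$selected_ids), 5L)
  expect_true(all(red$selected_ids %in% rownames(fps)))
  expect_false(anyDuplicated(red$selected_ids) > 0)
})

test_that("reduction selections match an independent re-implementation", {
  fps <- random_fp_matrix(50L, n_bits = 128L, n_on = 12L, seed = 31)
  nm <- 20L
  red <- reduce_majority(fps, nm, height = 4.5)
  # independent oracle following the written rules
  d <- 1 - tanimoto_similarity(fps); diag(d) <- 0
  tree <- hclust(as.dist(d), method = "ward.D2")
  cl <- cutree(tree, h = 4.5)
  nc <- length(unique(cl))
  oracle <- if (nc < nm) {
    sizes <- table(cl)
    exact <- nm * as.numeric(sizes) / sum(sizes)
    quota <- floor(exact)
    lr <- order(-(exact - quota), -as.numeric(sizes), seq_along(sizes))
    for (g in lr) {
      if (sum(quota) >= nm) break
      if (quota[g] < sizes[g]) quota[g] <- quota[g] + 1
    }
    unlist(lapply(seq_along(sizes), function(g) {
      mem <- rownames(fps)[cl == g]
      cent <- rowSums(d[mem, mem, drop = FALSE])
      mem[order(cent, mem)][seq_len(quota[g])]
    }))
  } else {
    clk <- cutree(tree, k = nm)
    vapply(split(rownames(fps)[order(clk)], sort(clk)), function(mem) {
      cent <- rowSums(d[mem, mem, drop = FALSE])
      mem[order(cent, mem)][1L]
    }, "")
  }
  expect_setequal(red$selected_ids, unname(oracle))
  # determinism across reruns
  expect_identical(red$selected_ids,
                   reduce_majority(fps, nm, height = 4.5)$selected_ids)
  expect_error(reduce_majority(fps, 50L), "Nm")
})

test_that("balancing the fixture cell lines satisfies the 1.2 rule", {
  db <- fixture_small_db()
  fp <- cached("small_fp2", morgan_fingerprint(
    setNames(db$compounds$canonical_smiles, db$compounds$compound_id),
    radius = 2L, n_bits = 512L))
  idx <- per_cell_index(db)
  for (cl in names(idx)) {
    ids <- c(idx[[cl]]$sensitive, idx[[cl]]$resistant)
    labels <- setNames(rep(c("sensitive", "resistant"),
                           c(length(idx[[cl]]$sensitive),
                             length(idx[[cl]]$resistant))), ids)
    bal <- balance_classes(fp[ids, , drop = FALSE], labels)
    kept <- table(labels[bal$ids])
    expect_true(is_balanced(max(kept), min(kept)))
    if (!bal$report$balanced) {
      expect_equal(unname(min(kept)), bal$report$n_minority)
      expect_equal(unname(max(kept)), bal$report$n_minority)
    }
  }
})
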