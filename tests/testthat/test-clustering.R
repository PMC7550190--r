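planted_clouds <- function(centers, n_each, sd, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_each * ncol(centers), 0, sd), n_each) +
      matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_each))
}

test_that("responsiveness filter keeps units at or above threshold", {
  sc <- rbind(rep(0.1, 15),                      # below: removed
              c(0.2, rep(0.05, 14)),             # boundary: retained
              c(rep(0, 14), 0.9))
  expect_identical(filter_responsive(sc, 0.2), c(FALSE, TRUE, TRUE))
  set.seed(7)
  r <- matrix(runif(1500, 0, 0.5), 100, 15)
  expect_identical(filter_responsive(r, 0.4),
                   vapply(1:100, function(i) max(r[i, ]) >= 0.4, logical(1)))
})

test_that("affinity propagation finds planted exemplars and prunes small clusters", {
  ctr <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  pl <- planted_clouds(ctr, 50, 0.05, seed = 8)
  ex <- exemplar_extraction(pl$x, min_cluster_size = 5)
  expect_identical(nrow(ex$exemplar_scores), 3L)
  # each cloud intact: assignment constant within generative groups
  for (g in 1:3)
    expect_length(unique(ex$assignment[pl$labels == g]), 1)

  # identical duplicated rows collapse to a single exemplar
  dup <- matrix(1, 20, 4)
  ap <- affinity_propagation(dup)
  expect_identical(ap$exemplars, 1L)
  expect_identical(unique(ap$labels), 1L)

  # a 4-member group vanishes when the minimum size is 5
  set.seed(9)
  ctr2 <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  big <- planted_clouds(ctr2, 50, 0.05, seed = 9)
  small <- rbind(big$x, matrix(rnorm(12, 0, 0.05), 4, 3) +
                          matrix(c(0, 0, 5), 4, 3, byrow = TRUE))
  ex2 <- exemplar_extraction(small, min_cluster_size = 5)
  expect_true(all(is.na(ex2$assignment[151:154])))
  expect_true(all(!is.na(ex2$assignment[1:150])))
})

test_that("hierarchical merge cuts the correlation-distance tree", {
  # two exemplar families: r = 1 within, ~0 between
  v <- c(1, 2, 3, 4, 5, 4, 3, 2, 1, 2, 3, 4, 5, 4, 3)
  w <- c(5, 1, 4, 2, 5, 1, 4, 2, 5, 1, 4, 2, 5, 1, 4)
  ex <- rbind(v, 2 * v + 1, w, 3 * w - 2)
  mod <- hierarchical_merge(ex, assignment = c(1, 2, 3, 4, 1, 2, 3, 4),
                            distance_threshold = 0.25, min_final_size = 1)
  expect_identical(mod$n_clusters, 2L)
  expect_identical(mod$exemplar_labels[1], mod$exemplar_labels[2])
  expect_false(mod$exemplar_labels[1] == mod$exemplar_labels[3])

  # cut above the root: one cluster
  mod1 <- hierarchical_merge(ex, c(1, 2, 3, 4), 10, min_final_size = 1)
  expect_identical(mod1$n_clusters, 1L)

  expect_error(hierarchical_merge(rbind(rep(1, 15), v), c(1, 2), 0.3),
               "constant")
})

test_that("hierarchical merge agrees with a naive agglomeration oracle", {
  set.seed(10)
  ex <- matrix(rnorm(12 * 15), 12, 15)
  d <- 1 - cor(t(ex))
  orc <- oracle_upgma(d)
  canon <- function(x) as.integer(factor(x, levels = unique(x)))
  for (h in c(0.3, 0.7, 1.0)) {
    mod <- hierarchical_merge(ex, assignment = 1:12, distance_threshold = h,
                              min_final_size = 1)
    expect_identical(canon(mod$exemplar_labels), canon(orc$labels_at(h)))
  }
})

test_that("pruning by final cluster size is monotone and tracks unit counts", {
  ctr <- diag(3)[, c(1, 2, 3, 1, 2)] * 4
  pl <- planted_clouds(ctr, 30, 0.05, seed = 11)
  ex <- exemplar_extraction(pl$x, min_cluster_size = 5)
  prev <- Inf
  for (ms in c(1, 10, 35, 70)) {
    mod <- hierarchical_merge(ex$exemplar_scores, ex$assignment,
                              distance_threshold = 0.5, min_final_size = ms)
    expect_lte(mod$n_clusters, prev)
    prev <- mod$n_clusters
  }
})

test_that("silhouette threshold selection recovers a planted partition", {
  ctr <- matrix(c(4, 0, 0, 0, 4, 0, 0, 0, 4), 3, 3, byrow = TRUE)
  ctr <- cbind(ctr, matrix(0.5, 3, 12))
  pl <- planted_clouds(ctr, 40, 0.15, seed = 12)
  ex <- exemplar_extraction(pl$x, min_cluster_size = 5)
  sel <- select_threshold_by_silhouette(ex$exemplar_scores, pl$x,
                                        ex$assignment, min_final_size = 5)
  expect_identical(sel$model$n_clusters, 3L)
  expect_equal(mclust::adjustedRandIndex(sel$model$final_labels, pl$labels),
               1)

  # reported silhouette equals a first-principles oracle
  keep <- !is.na(sel$model$final_labels)
  d <- 1 - cor(t(pl$x[keep, ]))
  best <- sel$table$silhouette[which(sel$table$threshold == sel$threshold)]
  expect_equal(best, oracle_silhouette(sel$model$final_labels[keep], d),
               tolerance = 1e-12)
  expect_true(all(sel$table$silhouette >= -1 & sel$table$silhouette <= 1,
                  na.rm = TRUE))

  # a single candidate is returned as-is
  one <- select_threshold_by_silhouette(ex$exemplar_scores, pl$x,
                                        ex$assignment, candidates = 0.5,
                                        min_final_size = 5)
  expect_identical(one$threshold, 0.5)

  expect_error(select_threshold_by_silhouette(
    ex$exemplar_scores, pl$x, ex$assignment, candidates = 10,
    min_final_size = 5), "single cluster")
})

test_that("clustering is idempotent on its own output", {
  ctr <- rbind(c(4, rep(0, 14)), c(0, 4, rep(0, 13)), c(0, 0, 4, rep(0, 12)))
  pl <- planted_clouds(ctr, 30, 0.1, seed = 13)
  ex <- exemplar_extraction(pl$x, min_cluster_size = 5)
  m1 <- hierarchical_merge(ex$exemplar_scores, ex$assignment, 0.4,
                           min_final_size = 5)
  m2 <- hierarchical_merge(ex$exemplar_scores, ex$assignment, 0.4,
                           min_final_size = 5)
  expect_identical(m1$final_labels, m2$final_labels)
})

test_that("k-NN label transfer votes among nearest references", {
  set.seed(14)
  ref <- matrix(rnorm(200 * 15), 200, 15)
  lab <- sample(1:4, 200, replace = TRUE)

  # a query identical to a reference returns its label with probability 1
  out <- knn_label_transfer(ref, lab, ref[17, , drop = FALSE], k = 1)
  expect_identical(out$labels, lab[17])
  expect_identical(max(out$prob), 1)

  # vote tie at k = 2 resolves to the lowest class index
  ref2 <- rbind(c(1, rep(0, 14)), c(-1, rep(0, 14)))
  out2 <- knn_label_transfer(ref2, c(2L, 1L), matrix(0, 1, 15), k = 2)
  expect_identical(out2$labels, 1L)
  expect_equal(unname(out2$prob[1, ]), c(0.5, 0.5))

  expect_error(knn_label_transfer(ref2, c(1L, 2L), matrix(0, 1, 15), k = 3))
})

test_that("PCA shuffle control separates structured from unstructured scores", {
  set.seed(15)
  # rank-1: top components explain everything
  r1 <- outer(rnorm(60), rnorm(15))
  out <- pca_shuffle_control(r1, n_shuffles = 5, seed = 1)
  expect_equal(out$explained, 1, tolerance = 1e-9)

  # shared latent factor: true explained variance beats the shuffled mean
  z <- rnorm(100)
  corr <- outer(z, runif(15, 0.5, 1)) + matrix(rnorm(1500, 0, 0.3), 100)
  out2 <- pca_shuffle_control(corr, n_shuffles = 50, seed = 2)
  expect_gt(out2$explained, out2$shuffled_mean)

  # i.i.d. columns: shuffling preserves the distribution
  iid <- matrix(rnorm(1500), 100, 15)
  out3 <- pca_shuffle_control(iid, n_shuffles = 50, seed = 3)
  expect_equal(out3$explained, out3$shuffled_mean, tolerance = 0.05)
})
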