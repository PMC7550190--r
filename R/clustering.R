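#' Filter units by maximum response score
#'
#' A unit is retained iff its maximum over the 15 (normalized) scores is at
#' least the threshold; the boundary case (max exactly at threshold) is
#' retained. Defaults: 0.2 for tectal ROIs, 0.4 for RGC pixels.
#'
#' @param scores Units x 15 normalized score matrix.
#' @param max_score_threshold Retention threshold.
#' @return Logical vector of retained units.
#' @export
filter_responsive <- function(scores, max_score_threshold = 0.2) {
  stopifnot(is.matrix(scores))
  apply(scores, 1, max) >= max_score_threshold
}

#' Extract exemplars by affinity propagation
#'
#' Affinity propagation (negative squared Euclidean similarity, preference
#' = median similarity) on the retained units' score vectors; clusters with
#' fewer than `min_cluster_size` members (default 5) are dropped together
#' with their members.
#'
#' @param scores Retained units x 15 score matrix.
#' @param min_cluster_size Minimum members for an exemplar to survive.
#' @param ... Passed to [affinity_propagation()].
#' @return List with `exemplars` (row indices into `scores`),
#'   `exemplar_scores`, `assignment` (per-unit index into the exemplar
#'   list, `NA` for dropped units), `sizes`.
#' @export
exemplar_extraction <- function(scores, min_cluster_size = 5, ...) {
  stopifnot(nrow(scores) >= 2)
  ap <- affinity_propagation(scores, ...)
  sizes <- table(ap$labels)
  keep_ex <- as.integer(names(sizes))[sizes >= min_cluster_size]
  assignment <- match(ap$labels, keep_ex)
  list(exemplars = keep_ex,
       exemplar_scores = scores[keep_ex, , drop = FALSE],
       assignment = assignment,
       sizes = as.integer(sizes[as.character(keep_ex)]))
}

#' Merge exemplars by hierarchical clustering on correlation distance
#'
#' Average-linkage tree on 1 - Pearson correlation between exemplar score
#' vectors, cut at `distance_threshold`. Final clusters whose total unit
#' membership (units, not exemplars) falls below `min_final_size` are
#' removed; survivors are renumbered 1..K by decreasing size.
#'
#' @param exemplar_scores Exemplars x 15 matrix.
#' @param assignment Per-unit exemplar index (as from
#'   [exemplar_extraction()]); `NA`s pass through.
#' @param distance_threshold Tree cut height on correlation distance.
#' @param min_final_size Minimum units per final cluster (default 20).
#' @return A `cluster_model`: `exemplar_scores`, `linkage` (an `hclust`),
#'   `distance_threshold`, `exemplar_labels` (`NA` = pruned),
#'   `final_labels` per unit, `retained_fraction`, `n_clusters`.
#' @export
hierarchical_merge <- function(exemplar_scores, assignment,
                               distance_threshold, min_final_size = 20) {
  stopifnot(nrow(exemplar_scores) >= 2)
  sds <- apply(exemplar_scores, 1, stats::sd)
  if (any(sds == 0))
    stop("constant exemplar score vector: correlation distance undefined")
  d <- 1 - stats::cor(t(exemplar_scores))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ex_lab <- stats::cutree(hc, h = distance_threshold)
  unit_lab <- ex_lab[assignment]
  counts <- table(unit_lab)
  keep <- as.integer(names(counts))[counts >= min_final_size]
  # renumber surviving clusters by decreasing unit count
  keep <- keep[order(-counts[as.character(keep)])]
  remap <- stats::setNames(seq_along(keep), keep)
  final <- unname(remap[as.character(unit_lab)])
  ex_final <- unname(remap[as.character(ex_lab)])
  structure(list(exemplar_scores = exemplar_scores, linkage = hc,
                 distance_threshold = distance_threshold,
                 exemplar_labels = ex_final,
                 final_labels = final,
                 retained_fraction = mean(!is.na(final)),
                 n_clusters = length(keep)),
            class = "cluster_model")
}

mean_silhouette <- function(labels, dmat) {
  sil <- cluster::silhouette(labels, dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' Select the tree-cut threshold by silhouette analysis
#'
#' For each candidate cut height the exemplar tree is cut, labels are
#' propagated to units, small clusters pruned, and the mean silhouette
#' coefficient of the retained units (correlation distance between unit
#' score vectors) computed. The threshold with the highest silhouette wins;
#' ties are broken toward fewer clusters.
#'
#' @param exemplar_scores Exemplars x 15 matrix.
#' @param unit_scores Units x 15 matrix (for unit-level silhouettes).
#' @param assignment Per-unit exemplar index.
#' @param candidates Cut heights; default midpoints between consecutive
#'   distinct merge heights of the tree (every distinct partition once).
#' @param min_final_size Passed to [hierarchical_merge()].
#' @return List with `threshold`, `model` (the winning `cluster_model`),
#'   and `table` (threshold, n_clusters, silhouette per candidate).
#' @export
select_threshold_by_silhouette <- function(exemplar_scores, unit_scores,
                                           assignment, candidates = NULL,
                                           min_final_size = 20) {
  sds <- apply(exemplar_scores, 1, stats::sd)
  if (any(sds == 0))
    stop("constant exemplar score vector: correlation distance undefined")
  d <- 1 - stats::cor(t(exemplar_scores))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (is.null(candidates)) {
    h <- sort(unique(hc$height))
    h <- c(0, h)
    candidates <- (h[-1] + h[-length(h)]) / 2
  }
  stopifnot(length(candidates) >= 1)
  dunit <- NULL
  rows <- vector("list", length(candidates))
  models <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    mod <- hierarchical_merge(exemplar_scores, assignment, candidates[i],
                              min_final_size)
    keep <- !is.na(mod$final_labels)
    sil <- NA_real_
    if (mod$n_clusters >= 2) {
      if (is.null(dunit)) dunit <- 1 - stats::cor(t(unit_scores))
      sil <- mean_silhouette(mod$final_labels[keep],
                             dunit[keep, keep, drop = FALSE])
    }
    rows[[i]] <- data.frame(threshold = candidates[i],
                            n_clusters = mod$n_clusters, silhouette = sil)
    models[[i]] <- mod
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$silhouette))
  if (!length(ok)) stop("every candidate threshold yields a single cluster")
  best <- ok[order(-tab$silhouette[ok], tab$n_clusters[ok])][1]
  list(threshold = candidates[best], model = models[[best]], table = tab)
}

#' Transfer cluster labels by k-nearest neighbors
#'
#' Majority vote among the k Euclidean nearest reference units (k = 10 for
#' tectal cells, 100 for RGC pixels). Vote ties are broken toward the
#' lowest class index; distance ties are resolved by reference order.
#'
#' @param ref_scores Reference units x 15 matrix.
#' @param ref_labels Integer labels of the reference units.
#' @param query_scores Query units x 15 matrix.
#' @param k Number of neighbors.
#' @return List with `labels` (predicted class per query) and `prob`
#'   (query x class vote-fraction matrix).
#' @export
knn_label_transfer <- function(ref_scores, ref_labels, query_scores, k = 10) {
  stopifnot(nrow(ref_scores) >= k, k >= 1,
            length(ref_labels) == nrow(ref_scores))
  classes <- sort(unique(ref_labels))
  d2 <- outer(rowSums(query_scores^2), rowSums(ref_scores^2), "+") -
    2 * query_scores %*% t(ref_scores)
  nq <- nrow(query_scores)
  prob <- matrix(0, nq, length(classes),
                 dimnames = list(NULL, classes))
  labels <- integer(nq)
  for (i in seq_len(nq)) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(factor(ref_labels[nn], levels = classes))
    prob[i, ] <- as.numeric(votes) / k
    labels[i] <- classes[which.max(votes)]  # ties -> lowest class index
  }
  list(labels = labels, prob = prob)
}

#' Shuffle control for score-matrix principal components
#'
#' Explained-variance fraction of the top `n_components` principal
#' components of the score matrix, against the mean of the same quantity
#' over column-wise shuffles (each regressor's scores independently
#' permuted across units, destroying between-regressor correlation while
#' preserving marginals).
#'
#' @param scores Units x regressors matrix.
#' @param n_components Number of leading PCs (default 3).
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return List with `explained`, `shuffled_mean`, `shuffled` (per-draw
#'   values).
#' @export
pca_shuffle_control <- function(scores, n_components = 3, n_shuffles = 1000,
                                seed = 1) {
  stopifnot(ncol(scores) >= n_components)
  ev_frac <- function(m) {
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    v <- p$sdev^2
    sum(v[seq_len(n_components)]) / sum(v)
  }
  true <- ev_frac(scores)
  set.seed(seed)
  shuf <- vapply(seq_len(n_shuffles), function(i)
    ev_frac(apply(scores, 2, sample)), numeric(1))
  list(explained = true, shuffled_mean = mean(shuf), shuffled = shuf)
}

#' Two-stage functional clustering of a score matrix
#'
#' The full clustering pipeline: responsiveness filter, affinity
#' propagation, hierarchical merging with silhouette-selected cut. Modes
#' differ only in configuration: `"tectum"` (threshold 0.2, minimum final
#' cluster 20 units, k = 10) and `"rgc"` (threshold 0.4, minimum final
#' cluster 1% of units, k = 100).
#'
#' @param scores Units x 15 normalized score matrix.
#' @param mode `"tectum"` or `"rgc"`.
#' @param max_score_threshold,min_cluster_size,min_final_size Overrides of
#'   the mode defaults.
#' @param ... Passed to [affinity_propagation()].
#' @return List with `retained` (indices into `scores`), `exemplars`,
#'   `model` (`cluster_model` at the selected threshold), `threshold`,
#'   `silhouette_table`, and `labels` (length nrow(scores), `NA` for
#'   filtered or pruned units).
#' @export
cluster_scores <- function(scores, mode = c("tectum", "rgc"),
                           max_score_threshold = NULL,
                           min_cluster_size = 5, min_final_size = NULL,
                           ...) {
  mode <- match.arg(mode)
  if (is.null(max_score_threshold))
    max_score_threshold <- if (mode == "tectum") 0.2 else 0.4
  keep <- which(filter_responsive(scores, max_score_threshold))
  if (is.null(min_final_size))
    min_final_size <- if (mode == "tectum") 20
                      else max(5, ceiling(0.01 * length(keep)))
  s <- scores[keep, , drop = FALSE]
  ex <- exemplar_extraction(s, min_cluster_size, ...)
  sel <- select_threshold_by_silhouette(ex$exemplar_scores, s,
                                        ex$assignment,
                                        min_final_size = min_final_size)
  labels <- rep(NA_integer_, nrow(scores))
  labels[keep] <- sel$model$final_labels
  list(retained = keep, exemplars = ex, model = sel$model,
       threshold = sel$threshold, silhouette_table = sel$table,
       labels = labels)
}
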