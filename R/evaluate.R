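# Evaluation: classification metrics on labeled data, internal clustering
# metrics (Silhouette, Davies-Bouldin) on latent representations, the two
# target-evaluation modes (predicted labels as clusters vs seeded K-means
# with K = known class count), and the stratified cross-validation protocol
# on the labeled source.

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction of exact matches, in \[0, 1\].
#' @export
accuracy_score <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  mean(pred == truth)
}

#' Support-weighted F1 score
#'
#' Per-class F1 averaged with weights equal to each class's true-support
#' fraction. A class absent from the truth contributes 0 with 0 weight; a
#' class with no predictions or no true positives has F1 = 0.
#'
#' @param pred,truth label vectors with values in `1..K`.
#' @param K number of classes.
#' @return weighted F1 in \[0, 1\].
#' @export
weighted_f1 <- function(pred, truth, K) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  stopifnot(all(pred >= 1), all(pred <= K), all(truth >= 1), all(truth <= K))
  n <- length(truth)
  out <- 0
  for (k in seq_len(K)) {
    support <- sum(truth == k)
    if (support == 0) next
    tp <- sum(pred == k & truth == k)
    prec <- if (sum(pred == k) > 0) tp / sum(pred == k) else 0
    rec <- tp / support
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- out + (support / n) * f1
  }
  out
}

.pairwise_dist <- function(X) {
  as.matrix(stats::dist(X))
}

#' Silhouette score
#'
#' Mean over samples of \eqn{(b - a) / \max(a, b)}, where a is the mean
#' Euclidean distance to the sample's own cluster (excluding itself) and b
#' the smallest mean distance to any other cluster. Samples in singleton
#' clusters score 0.
#'
#' @param latent n x d numeric matrix.
#' @param cluster_labels length-n cluster assignment (>= 2 distinct values).
#' @return scalar in \[-1, 1\].
#' @export
silhouette_score <- function(latent, cluster_labels) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  stopifnot(n == length(cluster_labels), n >= 3)
  cl <- as.integer(factor(cluster_labels))
  k <- max(cl)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  D <- .pairwise_dist(latent)
  sizes <- tabulate(cl, k)
  # mean distance from each sample to each cluster (including itself for own)
  G <- matrix(0, n, k)
  for (c in seq_len(k)) G[, c] <- rowSums(D[, cl == c, drop = FALSE])
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cl[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- G[i, ci] / (sizes[ci] - 1L)
    b <- min(G[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Standard DBI with Euclidean centroid distances and mean intra-cluster
#' dispersion: \eqn{(1/k) \sum_i \max_{j \ne i} (S_i + S_j)/M_{ij}}. Lower
#' is better; 0 for point-mass clusters at distinct locations.
#'
#' @inheritParams silhouette_score
#' @return scalar >= 0.
#' @export
davies_bouldin <- function(latent, cluster_labels) {
  latent <- as.matrix(latent)
  cl <- as.integer(factor(cluster_labels))
  k <- max(cl)
  if (k < 2) stop("Davies-Bouldin requires at least 2 clusters")
  cent <- matrix(0, k, ncol(latent))
  S <- numeric(k)
  for (c in seq_len(k)) {
    Xi <- latent[cl == c, , drop = FALSE]
    cent[c, ] <- colMeans(Xi)
    S[c] <- mean(sqrt(rowSums((Xi - matrix(cent[c, ], nrow(Xi), ncol(Xi),
                                           byrow = TRUE))^2)))
  }
  M <- .pairwise_dist(cent)
  db <- 0
  for (i in seq_len(k)) {
    R <- (S[i] + S[-i]) / M[i, -i]
    db <- db + max(R)
  }
  db / k
}

#' Clustering metrics on a target embedding
#'
#' Evaluates the integrated latent representation in one of two modes:
#' `"pred"` treats the model's predicted labels as clusters; `"kmeans"`
#' clusters the latent with seeded K-means (k-means++ seeding, 10 restarts)
#' at the given K. If predicted labels collapse to fewer than 2 clusters in
#' pred mode, the metrics are recorded as `NA` with a warning.
#'
#' @param result an [embedding_result()].
#' @param K number of clusters for kmeans mode (the known class count).
#' @param mode `"pred"` or `"kmeans"`.
#' @param seed RNG seed for kmeans mode.
#' @return tibble with columns `mode`, `metric` (`silhouette`, `dbi`),
#'   `value`.
#' @export
evaluate_target <- function(result, K, mode = c("pred", "kmeans"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "embedding_result"))
  if (mode == "pred") {
    cl <- result$predicted_labels
    if (length(unique(cl)) < 2L) {
      warning("predicted labels form fewer than 2 clusters; metrics undefined")
      return(tibble::tibble(mode = mode, metric = c("silhouette", "dbi"),
                            value = NA_real_))
    }
  } else {
    set.seed(seed)
    cl <- kmeans_pp(result$latent, K)$cluster
  }
  tibble::tibble(mode = mode, metric = c("silhouette", "dbi"),
                 value = c(silhouette_score(result$latent, cl),
                           davies_bouldin(result$latent, cl)))
}

# ---- cross-validation protocol -------------------------------------------

#' Subset a multi-omics dataset by sample index
#'
#' @param ds a `multiomics_dataset`.
#' @param idx integer sample indices to keep.
#' @return a `multiomics_dataset` restricted to those samples.
#' @export
subset_samples <- function(ds, idx) {
  mats <- lapply(ds$matrices, function(m)
    omics_matrix(m$values[idx, , drop = FALSE],
                 sample_ids = m$sample_ids[idx], feature_ids = m$feature_ids,
                 modality = m$modality, domain = m$domain,
                 missing_mask = m$missing_mask[idx, , drop = FALSE]))
  structure(list(matrices = mats, labels = ds$labels[idx],
                 class_names = ds$class_names, domain = ds$domain,
                 sample_ids = ds$sample_ids[idx]),
            class = "multiomics_dataset")
}

#' Stratified cross-validation on the labeled source
#'
#' Splits the source into class-stratified folds; for each fold the
#' remaining samples act as the labeled source for a full [fit_modamix()]
#' run (the unlabeled target is passed through unchanged), and accuracy and
#' weighted F1 are reported on the held-out fold.
#'
#' @param source labeled `multiomics_dataset`.
#' @param target unlabeled `multiomics_dataset`.
#' @param config a [train_config()]; `config$seed` also seeds the fold split.
#' @param folds number of folds.
#' @return tibble with columns `fold`, `metric` (`accuracy`, `weighted_f1`),
#'   `value`.
#' @export
crossval_source <- function(source, target, config = train_config(), folds = 5L) {
  if (is.null(source$labels)) stop("crossval_source requires a labeled source")
  K <- length(source$class_names)
  counts <- tabulate(source$labels, K)
  if (any(counts < folds))
    stop(sprintf("class '%s' has fewer samples (%d) than folds (%d); reduce folds",
                 source$class_names[which.min(counts)], min(counts), folds))
  set.seed(config$seed)
  fold <- integer(n_samples(source))
  for (k in seq_len(K)) {
    idx <- which(source$labels == k)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- fit_modamix(subset_samples(source, tr), target, config)
    res <- predict(fit, subset_samples(source, te))
    truth <- source$labels[te]
    out[[f]] <- tibble::tibble(
      fold = f, metric = c("accuracy", "weighted_f1"),
      value = c(accuracy_score(res$predicted_labels, truth),
                weighted_f1(res$predicted_labels, truth, K)))
  }
  dplyr::bind_rows(out)
}
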