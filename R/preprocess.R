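# Feature engineering for the three supported omics layers:
#  - expression: low-expression filter, library-size + log1p normalization,
#    highly-variable-gene selection by mean-binned normalized dispersion;
#  - chromatin accessibility: gene-body peak aggregation into gene activity
#    scores;
#  - DNA methylation: common-CpG restriction, missingness filter, median
#    imputation, K-means CpG clustering into cluster-median features, and
#    promoter-based matching of genes to retained CpG features.
# All paired operations return source/target matrices with identical
# feature_ids in identical order. Genomic coordinates are 0-based half-open;
# overlap means a nonempty intersection.

#' Remove lowly expressed genes
#'
#' Keeps genes with a nonzero count in at least `min_cells` samples
#' (a gene nonzero in exactly `min_cells` cells is kept); column order is
#' preserved.
#'
#' @param expr an `omics_matrix` of nonnegative counts.
#' @param min_cells minimum number of samples with nonzero expression.
#' @return filtered `omics_matrix`.
#' @export
filter_low_expression <- function(expr, min_cells = 30L) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (any(expr$values < 0)) stop("expression counts must be nonnegative")
  keep <- colSums(expr$values > 0) >= min_cells
  if (!any(keep)) stop("all genes removed by the low-expression filter")
  omics_matrix(expr$values[, keep, drop = FALSE], sample_ids = expr$sample_ids,
               feature_ids = expr$feature_ids[keep], modality = expr$modality,
               domain = expr$domain)
}

#' Library-size normalization and log transform
#'
#' Scales each sample's counts to `target_sum` total, then applies
#' `log(1 + x)` elementwise.
#'
#' @param expr an `omics_matrix` of nonnegative counts.
#' @param target_sum per-sample total after scaling.
#' @return normalized `omics_matrix`.
#' @export
normalize_log <- function(expr, target_sum = 1e4) {
  stopifnot(inherits(expr, "omics_matrix"), target_sum > 0)
  if (any(expr$values < 0)) stop("expression counts must be nonnegative")
  tot <- rowSums(expr$values)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(utils::head(expr$sample_ids[tot == 0], 5L), collapse = ", "))
  vals <- log1p(expr$values * (target_sum / tot))
  omics_matrix(vals, sample_ids = expr$sample_ids, feature_ids = expr$feature_ids,
               modality = expr$modality, domain = expr$domain)
}

# Normalized dispersion: dispersion = var/mean per gene, z-scored within 20
# equal-width bins of the per-gene mean. Genes with zero mean get -Inf.
# Bins too small (or too flat) to define a z-score fall back to the global
# dispersion mean/sd, so isolated extreme genes keep their extreme rank.
#' @noRd
normalized_dispersion <- function(values, n_bins = 20L) {
  mu <- colMeans(values)
  v <- apply(values, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  z <- rep(-Inf, length(mu))
  ok <- !is.na(disp)
  if (any(ok)) {
    bins <- cut(mu[ok], breaks = n_bins, labels = FALSE, include.lowest = TRUE)
    d <- disp[ok]
    bm <- tapply(d, bins, mean)[as.character(bins)]
    bs <- tapply(d, bins, stats::sd)[as.character(bins)]
    g_mean <- mean(d)
    g_sd <- stats::sd(d)
    if (!is.finite(g_sd) || g_sd == 0) g_sd <- 1
    bad <- !is.finite(bs) | bs == 0
    bm[bad] <- g_mean
    bs[bad] <- g_sd
    z[ok] <- (d - bm) / bs
  }
  z
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion (dispersion = variance/mean,
#' z-scored within 20 bins of the gene mean) computed on the source matrix,
#' and restricts both matrices to the top `n_genes` (or all available,
#' whichever is smaller), identically ordered.
#'
#' @param expr_source,expr_target log-normalized `omics_matrix` objects
#'   sharing a feature space.
#' @param n_genes number of genes to keep.
#' @return list(source =, target =) of restricted matrices.
#' @export
select_hvg <- function(expr_source, expr_target, n_genes = 3000L) {
  stopifnot(inherits(expr_source, "omics_matrix"),
            inherits(expr_target, "omics_matrix"))
  shared <- intersect(expr_source$feature_ids, expr_target$feature_ids)
  if (length(shared) < 1L) stop("no shared genes between source and target")
  s_idx <- match(shared, expr_source$feature_ids)
  z <- normalized_dispersion(expr_source$values[, s_idx, drop = FALSE])
  keep <- shared[order(-z)][seq_len(min(n_genes, length(shared)))]
  keep <- keep[order(match(keep, expr_source$feature_ids))]  # original order
  restrict <- function(m) omics_matrix(
    m$values[, match(keep, m$feature_ids), drop = FALSE],
    sample_ids = m$sample_ids, feature_ids = keep,
    modality = m$modality, domain = m$domain)
  list(source = restrict(expr_source), target = restrict(expr_target))
}

# ---- chromatin accessibility ---------------------------------------------

#' Construct a peak set
#'
#' Accessibility peaks with genomic intervals (0-based half-open) and a
#' per-sample count matrix.
#'
#' @param peaks data frame with columns `peak_id`, `chrom`, `start`, `end`.
#' @param counts numeric matrix, samples x peaks, nonnegative; columns in
#'   the order of `peaks`.
#' @param sample_ids sample identifiers (rows of `counts`).
#' @return object of class `peak_set`.
#' @export
peak_set <- function(peaks, counts, sample_ids = rownames(counts)) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)),
            all(peaks$start < peaks$end), all(counts >= 0),
            ncol(counts) == nrow(peaks))
  structure(list(peaks = peaks, counts = as.matrix(counts),
                 sample_ids = as.character(sample_ids)),
            class = "peak_set")
}

#' Construct a gene annotation table
#'
#' @param gene_id,chrom,start,end,strand per-gene vectors; coordinates
#'   0-based half-open, strand `"+"` or `"-"`.
#' @return tibble of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")), all(nzchar(chrom)))
  out <- tibble::tibble(gene_id = as.character(gene_id), chrom = as.character(chrom),
                        start = as.integer(start), end = as.integer(end),
                        strand = as.character(strand))
  class(out) <- c("gene_annotation", class(out))
  out
}

#' Gene activity scores from accessibility peaks
#'
#' For each requested gene, the per-sample score is the sum of counts over
#' all peaks whose interval overlaps the gene body `[start, end)` by at
#' least 1 bp. Genes with no overlapping peak receive all-zero columns.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_annotation()] table covering `gene_ids`.
#' @param gene_ids genes to score (default: all annotated genes).
#' @param domain,modality tags for the returned matrix.
#' @return `omics_matrix` of samples x genes activity scores.
#' @export
gene_activity_scores <- function(peaks, genes, gene_ids = genes$gene_id,
                                 domain = c("source", "target"),
                                 modality = "atac_activity") {
  domain <- match.arg(domain)
  stopifnot(inherits(peaks, "peak_set"))
  missing_genes <- setdiff(gene_ids, genes$gene_id)
  if (length(missing_genes))
    stop("gene_id(s) missing from annotation: ",
         paste(missing_genes, collapse = ", "))
  g <- genes[match(gene_ids, genes$gene_id), ]
  scores <- matrix(0, nrow(peaks$counts), length(gene_ids),
                   dimnames = list(peaks$sample_ids, gene_ids))
  for (ch in unique(g$chrom)) {
    gi <- which(g$chrom == ch)
    pi <- which(peaks$peaks$chrom == ch)
    if (!length(pi)) next
    # 0-based half-open -> 1-based closed for IRanges
    gr <- IRanges::IRanges(start = g$start[gi] + 1L, end = g$end[gi])
    pr <- IRanges::IRanges(start = peaks$peaks$start[pi] + 1L,
                           end = peaks$peaks$end[pi])
    hits <- IRanges::findOverlaps(pr, gr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qh)) {
      j <- gi[sh[k]]
      scores[, j] <- scores[, j] + peaks$counts[, pi[qh[k]]]
    }
  }
  omics_matrix(scores, sample_ids = peaks$sample_ids, feature_ids = gene_ids,
               modality = modality, domain = domain)
}

# ---- DNA methylation -----------------------------------------------------

#' Filter and impute CpG beta values
#'
#' Restricts both matrices to CpGs present in both domains, drops CpGs whose
#' missing fraction over the pooled source+target samples exceeds
#' `max_missing_frac` (a fraction exactly equal to the threshold is kept),
#' and imputes remaining missing cells with the per-CpG median of the pooled
#' observed values. Observed values are never altered; outputs carry no
#' missingness.
#'
#' @param meth_source,meth_target `omics_matrix` objects of beta values in
#'   \[0, 1\] where observed.
#' @param max_missing_frac maximum tolerated pooled missing fraction.
#' @return list(source =, target =) of imputed matrices with identical
#'   feature sets.
#' @export
filter_impute_cpgs <- function(meth_source, meth_target, max_missing_frac = 0.2) {
  stopifnot(inherits(meth_source, "omics_matrix"),
            inherits(meth_target, "omics_matrix"))
  shared <- intersect(meth_source$feature_ids, meth_target$feature_ids)
  if (length(shared) == 0L) stop("no CpG sites common to source and target")
  sub <- function(m) {
    idx <- match(shared, m$feature_ids)
    list(v = m$values[, idx, drop = FALSE], mk = m$missing_mask[, idx, drop = FALSE])
  }
  s <- sub(meth_source); t <- sub(meth_target)
  pooled_miss <- colSums(s$mk) + colSums(t$mk)
  n_pooled <- nrow(s$v) + nrow(t$v)
  keep <- (pooled_miss / n_pooled) <= max_missing_frac
  if (!any(keep)) stop("all CpGs exceed the missingness threshold")
  shared <- shared[keep]
  s$v <- s$v[, keep, drop = FALSE]; s$mk <- s$mk[, keep, drop = FALSE]
  t$v <- t$v[, keep, drop = FALSE]; t$mk <- t$mk[, keep, drop = FALSE]
  for (j in which(colSums(s$mk) + colSums(t$mk) > 0)) {
    obs <- c(s$v[!s$mk[, j], j], t$v[!t$mk[, j], j])
    med <- stats::median(obs)
    s$v[s$mk[, j], j] <- med
    t$v[t$mk[, j], j] <- med
  }
  out <- function(m, x) omics_matrix(x$v, sample_ids = m$sample_ids,
                                     feature_ids = shared, modality = m$modality,
                                     domain = m$domain)
  list(source = out(meth_source, s), target = out(meth_target, t))
}

# k-means with k-means++ seeding and multiple restarts; returns the
# stats::kmeans fit with the lowest total within-cluster sum of squares.
#' @noRd
kmeans_pp <- function(X, k, nstart = 10L, iter_max = 50L) {
  n <- nrow(X)
  stopifnot(k <= n)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(X))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- X[idx, ]
    if (k > 1L) {
      d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
      for (j in 2:k) {
        if (all(d2 == 0)) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = d2 / sum(d2))
        centers[j, ] <- X[idx, ]
        nd <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
      }
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    # Hartigan-Wong requires k < n; fall back to Lloyd at the k = n limit
    algo <- if (nrow(centers) >= nrow(X)) "Lloyd" else "Hartigan-Wong"
    fit <- suppressWarnings(stats::kmeans(X, centers = centers,
                                          iter.max = iter_max, algorithm = algo))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster CpGs into methylation features
#'
#' Groups CpGs by K-means (k-means++ seeding, 10 restarts, fixed seed),
#' treating each CpG as a point in sample space of the source matrix. The
#' returned model maps every CpG to one cluster; clusters left empty by
#' K-means are dropped, so the effective cluster count can be below
#' `n_clusters`.
#'
#' @param meth_source imputed, missing-free methylation `omics_matrix`.
#' @param n_clusters requested number of CpG clusters.
#' @param seed RNG seed for the clustering.
#' @return object of class `cpg_cluster_model`.
#' @export
cluster_cpgs <- function(meth_source, n_clusters = 3000L, seed = 1L) {
  stopifnot(inherits(meth_source, "omics_matrix"))
  if (any(meth_source$missing_mask)) stop("methylation matrix must be imputed first")
  P <- t(meth_source$values)                       # CpGs as points
  if (n_clusters > nrow(P))
    stop(sprintf("n_clusters (%d) exceeds the number of CpGs (%d)",
                 n_clusters, nrow(P)))
  set.seed(seed)
  fit <- kmeans_pp(P, n_clusters)
  raw <- fit$cluster
  used <- sort(unique(raw))
  assignment <- stats::setNames(match(raw, used), meth_source$feature_ids)
  structure(list(n_clusters = length(used), requested_clusters = as.integer(n_clusters),
                 cluster_assignment = assignment, seed = seed),
            class = "cpg_cluster_model")
}

#' Apply a CpG cluster model
#'
#' Collapses a methylation matrix to cluster-level features: feature j of the
#' output is the per-sample median beta value over CpGs assigned to cluster
#' j. Output features are named `cluster_0001`, ...
#'
#' @param model a [cluster_cpgs()] model.
#' @param meth methylation `omics_matrix` containing all CpGs in the model.
#' @return `omics_matrix` of samples x clusters.
#' @export
apply_cpg_clusters <- function(model, meth) {
  stopifnot(inherits(model, "cpg_cluster_model"), inherits(meth, "omics_matrix"))
  cpgs <- names(model$cluster_assignment)
  missing <- setdiff(cpgs, meth$feature_ids)
  if (length(missing))
    stop("CpG(s) in model absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  idx <- match(cpgs, meth$feature_ids)
  out <- matrix(NA_real_, nrow(meth$values), model$n_clusters)
  for (j in seq_len(model$n_clusters)) {
    cols <- idx[model$cluster_assignment == j]
    out[, j] <- apply(meth$values[, cols, drop = FALSE], 1L, stats::median)
  }
  omics_matrix(out, sample_ids = meth$sample_ids,
               feature_ids = sprintf("cluster_%04d", seq_len(model$n_clusters)),
               modality = meth$modality, domain = meth$domain)
}

#' Match genes to retained CpG features by promoter proximity
#'
#' Keeps genes having at least one model-retained CpG within the promoter
#' window (default 2000 bp upstream of the TSS through the TSS, strand
#' aware), ranks them by normalized dispersion on `expr`, and truncates to
#' `n_genes`.
#'
#' @param expr log-normalized expression `omics_matrix`.
#' @param model a [cluster_cpgs()] model (defines the retained CpGs).
#' @param genes a [gene_annotation()] covering the expression genes.
#' @param cpg_positions data frame with columns `cpg_id`, `chrom`, `pos`
#'   (0-based position) covering the model CpGs.
#' @param promoter_window bases upstream of the TSS included.
#' @param n_genes maximum number of matched genes returned.
#' @return `omics_matrix` restricted to the matched genes.
#' @export
match_genes_to_cpg_features <- function(expr, model, genes, cpg_positions,
                                        promoter_window = 2000L, n_genes = 3000L) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(model, "cpg_cluster_model"))
  cpgs <- names(model$cluster_assignment)
  pos <- cpg_positions[match(cpgs, cpg_positions$cpg_id), ]
  if (anyNA(pos$pos))
    stop("cpg_positions missing for model CpGs: ",
         paste(utils::head(cpgs[is.na(pos$pos)], 5L), collapse = ", "))
  unknown <- setdiff(expr$feature_ids, genes$gene_id)
  if (length(unknown))
    stop("annotation missing for genes: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  g <- genes[match(expr$feature_ids, genes$gene_id), ]
  tss <- ifelse(g$strand == "+", g$start, g$end)
  win_lo <- ifelse(g$strand == "+", tss - promoter_window, tss)
  win_hi <- ifelse(g$strand == "+", tss, tss + promoter_window)
  matched <- vapply(seq_len(nrow(g)), function(i) {
    any(pos$chrom == g$chrom[i] & pos$pos >= win_lo[i] & pos$pos <= win_hi[i])
  }, TRUE)
  if (!any(matched)) stop("no genes matched any retained CpG in the promoter window")
  z <- normalized_dispersion(expr$values)
  keep_ids <- expr$feature_ids[matched]
  keep_ids <- keep_ids[order(-z[matched])][seq_len(min(n_genes, length(keep_ids)))]
  keep_ids <- keep_ids[order(match(keep_ids, expr$feature_ids))]
  omics_matrix(expr$values[, match(keep_ids, expr$feature_ids), drop = FALSE],
               sample_ids = expr$sample_ids, feature_ids = keep_ids,
               modality = expr$modality, domain = expr$domain)
}

# ---- readers for annotation-style inputs ---------------------------------

#' Read a BED6-like gene annotation
#'
#' Expects a header-less tab-delimited file with columns chrom, start, end,
#' gene_id, score (ignored), strand; coordinates 0-based half-open.
#'
#' @param path file path.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED6 annotation needs 6 columns")
  gene_annotation(gene_id = df[[4L]], chrom = df[[1L]], start = df[[2L]],
                  end = df[[3L]], strand = df[[6L]])
}

#' Read a peak set with per-sample counts
#'
#' Tab-delimited with a header row: columns `chrom`, `start`, `end`,
#' `peak_id`, then one count column per sample.
#'
#' @param path file path.
#' @return a [peak_set()].
#' @export
read_peak_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end", "peak_id") %in% names(df)))
  count_cols <- setdiff(names(df), c("chrom", "start", "end", "peak_id"))
  if (!length(count_cols)) stop("peak file has no sample count columns")
  counts <- t(as.matrix(df[, count_cols, drop = FALSE]))
  rownames(counts) <- count_cols
  peak_set(df[, c("peak_id", "chrom", "start", "end")], counts,
           sample_ids = count_cols)
}

#' Read CpG positions
#'
#' Two-column tab-delimited file with header `cpg_id`, `position`, the
#' position given as `chrom:pos` (0-based).
#'
#' @param path file path.
#' @return tibble with columns `cpg_id`, `chrom`, `pos`.
#' @export
read_cpg_positions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  parts <- strsplit(df[[2L]], ":", fixed = TRUE)
  tibble::tibble(cpg_id = as.character(df[[1L]]),
                 chrom = vapply(parts, `[`, "", 1L),
                 pos = as.integer(vapply(parts, `[`, "", 2L)))
}
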