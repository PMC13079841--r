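# Feature-engineering operators: expression filters, HVG selection, gene
# activity, methylation filtering/imputation/clustering, promoter matching.

test_that("low-expression filter keeps genes at the boundary", {
  set.seed(3)
  n <- 100
  counts <- matrix(0, n, 3)
  counts[1:30, 1] <- 5    # nonzero in exactly 30 cells -> kept
  counts[1:29, 2] <- 5    # 29 cells -> removed
  counts[, 3] <- 1
  m <- small_omics(counts)
  f <- filter_low_expression(m, min_cells = 30)
  expect_equal(f$feature_ids, c("f001", "f003"))
  # min_cells = 0 is the identity
  expect_identical(filter_low_expression(m, 0)$values, m$values)
  all_zero <- small_omics(matrix(0, 5, 2))
  expect_error(filter_low_expression(all_zero), "all genes removed")
})

test_that("normalize_log scales rows to target_sum then applies log1p", {
  m <- small_omics(matrix(c(1, 3), 1, 2))
  nl <- normalize_log(m, target_sum = 4)
  expect_equal(unname(nl$values[1, ]), c(log(2), log(4)))
  # exp(x) - 1 sums back to target_sum
  set.seed(4)
  m2 <- small_omics(matrix(rpois(50, 5) + 1, 5, 10))
  n2 <- normalize_log(m2, target_sum = 1e4)
  expect_true(all(abs(rowSums(expm1(n2$values)) - 1e4) < 1e-6))
  # all-equal rows map to identical rows
  m3 <- small_omics(matrix(rep(c(1, 2, 3), each = 4), 4, 3, byrow = FALSE))
  n3 <- normalize_log(m3, 10)
  expect_equal(n3$values[1, ], n3$values[3, ])
  zero <- small_omics(rbind(c(1, 2), c(0, 0)))
  expect_error(normalize_log(zero), "s002")
})

test_that("select_hvg ranks planted high-dispersion genes on the source", {
  set.seed(5)
  n <- 80; m_genes <- 105
  base <- matrix(rnorm(n * m_genes, mean = 5, sd = 0.2), n, m_genes)
  hv_idx <- c(10, 30, 50, 70, 90)
  base[, hv_idx] <- rnorm(n * 5, mean = 5, sd = 3)
  src <- small_omics(base)
  tgt <- small_omics(base + rnorm(n * m_genes, sd = 0.1), domain = "target",
                     prefix = "t")
  hv <- select_hvg(src, tgt, n_genes = 5)
  expect_setequal(hv$source$feature_ids, src$feature_ids[hv_idx])
  expect_identical(hv$source$feature_ids, hv$target$feature_ids)
  # n_genes >= m keeps the whole shared feature set
  all_hv <- select_hvg(src, tgt, n_genes = 1000)
  expect_equal(ncol(all_hv$source$values), m_genes)
})

test_that("gene activity scores equal the hand-computed toy table", {
  toy <- make_fixture("atac_toy")
  act <- gene_activity_scores(toy$peaks, toy$genes)
  expect_equal(unname(act$values), unname(toy$expected))
  expect_error(gene_activity_scores(toy$peaks, toy$genes,
                                    gene_ids = c("g1", "nope")), "nope")
})

test_that("gene activity matches a brute-force overlap oracle", {
  set.seed(6)
  n_peaks <- 40; n_genes <- 12; n_samp <- 5
  peaks_df <- tibble::tibble(
    peak_id = paste0("p", seq_len(n_peaks)),
    chrom = sample(c("chr1", "chr2"), n_peaks, TRUE),
    start = sample.int(5000, n_peaks))
  peaks_df$end <- peaks_df$start + sample.int(300, n_peaks)
  counts <- matrix(rpois(n_samp * n_peaks, 3), n_samp, n_peaks,
                   dimnames = list(paste0("s", 1:n_samp), peaks_df$peak_id))
  g_start <- sample.int(5000, n_genes)
  genes_df <- gene_annotation(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
    start = g_start, end = g_start + sample.int(800, n_genes),
    strand = sample(c("+", "-"), n_genes, TRUE))
  act <- gene_activity_scores(peak_set(peaks_df, counts), genes_df)
  expected <- oracle_gene_activity(peaks_df, counts, genes_df, genes_df$gene_id)
  expect_equal(unname(act$values), expected)
})

test_that("CpG filter applies the >20% pooled-missingness rule and median-imputes", {
  toy <- make_fixture("meth_toy", seed = 9)
  fi <- filter_impute_cpgs(toy$source, toy$target, max_missing_frac = 0.2)
  expect_false(toy$dropped_cpgs %in% fi$source$feature_ids)   # 3/10 missing
  expect_true(toy$imputed_cpgs %in% fi$source$feature_ids)    # 2/10, kept
  expect_false("cpg31" %in% fi$source$feature_ids)            # source-only
  expect_identical(fi$source$feature_ids, fi$target$feature_ids)
  expect_false(any(is.na(fi$source$values)))
  expect_false(any(is.na(fi$target$values)))
  # imputed value is the pooled median of observed cells
  j <- toy$imputed_cpgs
  obs <- c(toy$source$values[!toy$source$missing_mask[, j], j],
           toy$target$values[!toy$target$missing_mask[, j], j])
  miss_s <- which(toy$source$missing_mask[, j])
  expect_equal(unname(fi$source$values[miss_s, j]), rep(median(obs), length(miss_s)))
  # observed values are never altered
  k <- setdiff(fi$source$feature_ids, j)[1]
  expect_identical(fi$source$values[, k], toy$source$values[, k])
})

test_that("explicit missingness arithmetic at the 20% boundary", {
  # 10 pooled samples; cpgA missing in 3 (30% > 20% -> dropped),
  # cpgB missing in 2 (20%, not more -> kept), cpgC with known median
  vs <- matrix(runif(18), 6, 3, dimnames = list(NULL, c("cpgA", "cpgB", "cpgC")))
  vt <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("cpgA", "cpgB", "cpgC")))
  vs[1:2, 1] <- NA; vt[1, 1] <- NA
  vs[1, 2] <- NA; vt[1, 2] <- NA
  vs[, 3] <- c(0.2, 0.4, 0.6, NA, 0.9, 0.1); vt[, 3] <- c(0.5, 0.3, 0.7, 0.8)
  s <- omics_matrix(vs, sample_ids = paste0("s", 1:6),
                    feature_ids = colnames(vs), modality = "meth")
  t <- omics_matrix(vt, sample_ids = paste0("t", 1:4),
                    feature_ids = colnames(vt), modality = "meth",
                    domain = "target")
  fi <- filter_impute_cpgs(s, t)
  expect_setequal(fi$source$feature_ids, c("cpgB", "cpgC"))
  expect_equal(fi$source$values[4, "cpgC"],
               median(c(0.2, 0.4, 0.6, 0.9, 0.1, 0.5, 0.3, 0.7, 0.8)))
})

test_that("CpG clustering recovers planted groups and is deterministic", {
  set.seed(11)
  n_samp <- 8
  g1 <- matrix(rep(runif(n_samp, 0, 0.1), 6), n_samp, 6)
  g2 <- matrix(rep(runif(n_samp, 0.8, 1), 5), n_samp, 5)
  vals <- cbind(g1, g2) + matrix(rnorm(n_samp * 11, sd = 0.01), n_samp)
  vals <- pmin(pmax(vals, 0), 1)
  m <- small_omics(vals, modality = "meth")
  mod <- cluster_cpgs(m, n_clusters = 2, seed = 7)
  asg <- mod$cluster_assignment
  expect_equal(length(unique(asg[1:6])), 1L)
  expect_equal(length(unique(asg[7:11])), 1L)
  expect_false(asg[1] == asg[7])
  mod2 <- cluster_cpgs(m, n_clusters = 2, seed = 7)
  expect_identical(mod$cluster_assignment, mod2$cluster_assignment)
  # one cluster per CpG is the identity partition
  modn <- cluster_cpgs(m, n_clusters = 11, seed = 7)
  expect_equal(modn$n_clusters, 11L)
  expect_error(cluster_cpgs(m, n_clusters = 50, seed = 1), "exceeds")
})

test_that("apply_cpg_clusters takes per-cluster medians", {
  vals <- matrix(c(0.1, 0.3, 0.9,
                   0.2, 0.5, 0.8), 2, 3, byrow = TRUE)
  m <- small_omics(vals, modality = "meth")
  model <- structure(list(n_clusters = 1L, requested_clusters = 1L,
                          cluster_assignment = stats::setNames(rep(1L, 3), m$feature_ids),
                          seed = 1L), class = "cpg_cluster_model")
  out <- apply_cpg_clusters(model, m)
  expect_equal(unname(out$values[, 1]), c(0.3, 0.5))
  expect_equal(ncol(out$values), model$n_clusters)
  expect_equal(out$feature_ids, "cluster_0001")
  # singleton clusters reduce to a renamed identity
  model3 <- structure(list(n_clusters = 3L, requested_clusters = 3L,
                           cluster_assignment = stats::setNames(1:3, m$feature_ids),
                           seed = 1L), class = "cpg_cluster_model")
  expect_equal(unname(apply_cpg_clusters(model3, m)$values), unname(vals))
})

test_that("promoter matching is strand-aware within the upstream window", {
  set.seed(12)
  expr <- small_omics(matrix(rnorm(40, sd = rep(c(1, 2), each = 20)), 5, 8))
  genes <- gene_annotation(
    gene_id = expr$feature_ids,
    chrom = "chr1",
    start = seq(10000, 80000, by = 10000),
    end = seq(10000, 80000, by = 10000) + 3000,
    strand = c("+", "+", "-", "-", "+", "+", "+", "+"))
  # c1: 500 bp upstream of gene 1 (+ strand, TSS = start) -> matched
  # c2: 10 kb downstream of gene 2's TSS -> not matched at 2 kb
  # c3: 100 bp past gene 3's end (- strand, TSS = end) -> matched
  cpgs <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c_low", "c_high"),
                         chrom = "chr1",
                         pos = c(10000 - 500, 20000 + 10000, 33000 + 100,
                                 1, 10^7))
  model <- structure(list(n_clusters = 5L, requested_clusters = 5L,
                          cluster_assignment = stats::setNames(1:5, cpgs$cpg_id),
                          seed = 1L), class = "cpg_cluster_model")
  cpgs_near <- cpgs[1:3, ]
  model_near <- structure(list(n_clusters = 3L, requested_clusters = 3L,
                               cluster_assignment = stats::setNames(1:3, cpgs_near$cpg_id),
                               seed = 1L), class = "cpg_cluster_model")
  out <- match_genes_to_cpg_features(expr, model_near, genes, cpgs_near,
                                     promoter_window = 2000)
  expect_setequal(out$feature_ids, c("f001", "f003"))
  # a window spanning the chromosome (with CpGs at both extremes, since the
  # window extends upstream of each TSS) matches every gene
  all_out <- match_genes_to_cpg_features(expr, model, genes, cpgs,
                                         promoter_window = 10^8)
  expect_equal(ncol(all_out$values), 8L)
  # and an out-of-reach window errors
  far <- tibble::tibble(cpg_id = "c1", chrom = "chr9", pos = 1L)
  model1 <- structure(list(n_clusters = 1L, requested_clusters = 1L,
                           cluster_assignment = c(c1 = 1L), seed = 1L),
                      class = "cpg_cluster_model")
  expect_error(match_genes_to_cpg_features(expr, model1, genes, far), "no genes")
})

test_that("paired outputs always share identical feature ids in order", {
  toy <- make_fixture("meth_toy", seed = 21)
  fi <- filter_impute_cpgs(toy$source, toy$target)
  expect_identical(fi$source$feature_ids, fi$target$feature_ids)
  set.seed(22)
  src <- small_omics(matrix(rexp(200), 10, 20))
  tgt <- small_omics(matrix(rexp(200), 10, 20), domain = "target", prefix = "t")
  hv <- select_hvg(normalize_log(src, 100), normalize_log(tgt, 100), 7)
  expect_identical(hv$source$feature_ids, hv$target$feature_ids)
})
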