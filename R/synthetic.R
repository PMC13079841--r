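# Seeded generator of paired source/target multi-omics datasets with planted
# class structure and batch effects. The generative model is linear-Gaussian
# for analytical transparency: a shared low-dimensional class signal is
# mapped into each modality's feature space by a fixed random linear map
# (shared across domains), and the target domain receives an additive
# per-feature shift and a multiplicative per-feature distortion on top.

#' Simulation specification
#'
#' @param n_source,n_target sample counts per domain.
#' @param K number of classes (present in both domains).
#' @param O number of modalities.
#' @param m integer vector of length O: features per modality.
#' @param latent_signal_dim dimension of the shared class-signal space.
#' @param class_separation mean pairwise distance between class means in
#'   signal space (within-class signal spread is 1 per dimension).
#' @param batch_shift standard deviation of the per-feature additive offset
#'   applied to the target domain (0 = no batch effect).
#' @param batch_scale spread of the per-feature multiplicative distortion
#'   `1 + batch_scale * gamma_f` applied to the target domain.
#' @param noise_sd feature-level Gaussian noise standard deviation.
#' @param class_proportions_source,class_proportions_target class mixing
#'   proportions (default uniform; target defaults to source).
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_source = 300L, n_target = 300L, K = 3L, O = 2L,
                     m = c(200L, 200L), latent_signal_dim = 10L,
                     class_separation = 6, batch_shift = 1.5,
                     batch_scale = 0.1, noise_sd = 1,
                     class_proportions_source = rep(1 / K, K),
                     class_proportions_target = class_proportions_source,
                     seed = 1L) {
  stopifnot(n_source >= 1, n_target >= 1, K >= 1, O >= 1, length(m) == O,
            all(m >= 1), latent_signal_dim >= 1,
            abs(sum(class_proportions_source) - 1) < 1e-8,
            abs(sum(class_proportions_target) - 1) < 1e-8)
  structure(list(n_source = as.integer(n_source), n_target = as.integer(n_target),
                 K = as.integer(K), O = as.integer(O), m = as.integer(m),
                 latent_signal_dim = as.integer(latent_signal_dim),
                 class_separation = class_separation, batch_shift = batch_shift,
                 batch_scale = batch_scale, noise_sd = noise_sd,
                 class_proportions_source = class_proportions_source,
                 class_proportions_target = class_proportions_target,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.sim_labels <- function(n, props, K) {
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(props * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep.int(seq_len(K), counts))
}

#' Generate a paired source/target multi-omics dataset
#'
#' Draws class means separated by `class_separation` in signal space, maps
#' signal plus unit Gaussian latent noise into each modality's feature space
#' through a shared random linear map, then applies the domain-specific
#' batch effect (additive shift and multiplicative distortion) to the target
#' domain only. The target dataset is returned unlabeled; its true labels
#' are returned separately.
#'
#' @param spec a [sim_spec()].
#' @return list(source = labeled `multiomics_dataset`,
#'   target = unlabeled `multiomics_dataset`,
#'   truth = integer vector of target class indices,
#'   class_names = character vector).
#' @export
simulate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  q <- spec$latent_signal_dim
  K <- spec$K
  # class means with mean pairwise distance = class_separation
  M <- matrix(stats::rnorm(K * q), K, q)
  if (K > 1) {
    M <- scale(M, center = TRUE, scale = FALSE)
    d <- stats::dist(M)
    if (mean(d) > 0) M <- M * (spec$class_separation / mean(d))
  }
  y_s <- .sim_labels(spec$n_source, spec$class_proportions_source, K)
  y_t <- .sim_labels(spec$n_target, spec$class_proportions_target, K)
  Z_s <- M[y_s, , drop = FALSE] + matrix(stats::rnorm(spec$n_source * q), ncol = q)
  Z_t <- M[y_t, , drop = FALSE] + matrix(stats::rnorm(spec$n_target * q), ncol = q)
  class_names <- paste0("class", seq_len(K))
  ids_s <- sprintf("src_%04d", seq_len(spec$n_source))
  ids_t <- sprintf("tgt_%04d", seq_len(spec$n_target))
  mats_s <- vector("list", spec$O)
  mats_t <- vector("list", spec$O)
  for (o in seq_len(spec$O)) {
    m_o <- spec$m[o]
    A <- matrix(stats::rnorm(q * m_o, sd = 1 / sqrt(q)), q, m_o)
    shift <- stats::rnorm(m_o, sd = 1) * spec$batch_shift
    scl <- pmax(1 + stats::rnorm(m_o) * spec$batch_scale, 0.1)
    X_s <- Z_s %*% A + matrix(stats::rnorm(spec$n_source * m_o, sd = spec$noise_sd),
                              ncol = m_o)
    X_t <- (Z_t %*% A + matrix(stats::rnorm(spec$n_target * m_o, sd = spec$noise_sd),
                               ncol = m_o)) %*% diag(scl, m_o) +
      matrix(shift, spec$n_target, m_o, byrow = TRUE)
    feat <- sprintf("mod%d_f%04d", o, seq_len(m_o))
    mats_s[[o]] <- omics_matrix(X_s, sample_ids = ids_s, feature_ids = feat,
                                modality = paste0("mod", o), domain = "source")
    mats_t[[o]] <- omics_matrix(X_t, sample_ids = ids_t, feature_ids = feat,
                                modality = paste0("mod", o), domain = "target")
  }
  source <- suppressMessages(assemble_dataset(
    mats_s, labels = data.frame(sample_id = ids_s, class = class_names[y_s]),
    class_names = class_names))
  target <- suppressMessages(assemble_dataset(mats_t))
  list(source = source, target = target, truth = y_t, class_names = class_names)
}

#' Named benchmark fixtures
#'
#' Small, seeded datasets used throughout the test suite and examples:
#' \describe{
#'   \item{easy}{K = 3, O = 2, m = 200+200, n = 300/300; strong class
#'     separation with a moderate planted batch shift. The full pipeline
#'     recovers target labels on this fixture.}
#'   \item{hard}{batch shift three times the class separation
#'     (K = 3, O = 2, m = 60+60, n = 80/80); the batch-dominated regime
#'     used for ablation comparisons.}
#'   \item{meth_toy}{a beta-valued methylation pair in \[0, 1\] with planted
#'     missing cells: `cpg05` is missing in 3 of 10 pooled samples (30%,
#'     above the 20% rule), `cpg10` in 2 of 10 (20%, kept), and `cpg31`
#'     exists only in the source.}
#'   \item{atac_toy}{3 annotated genes and 6 peaks over 4 samples with
#'     hand-computable gene-body overlaps.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed (for the simulated fixtures).
#' @return fixture contents (see each description).
#' @export
make_fixture <- function(name = c("easy", "hard", "meth_toy", "atac_toy"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    easy = simulate_multiomics(sim_spec(
      n_source = 300L, n_target = 300L, K = 3L, O = 2L, m = c(200L, 200L),
      class_separation = 6, batch_shift = 1.5, batch_scale = 0.1,
      noise_sd = 1, seed = seed)),
    hard = simulate_multiomics(sim_spec(
      n_source = 80L, n_target = 80L, K = 3L, O = 2L, m = c(60L, 60L),
      class_separation = 3, batch_shift = 9, batch_scale = 0.3,
      noise_sd = 1, seed = seed)),
    meth_toy = .meth_toy(seed),
    atac_toy = .atac_toy())
}

# 6 source + 4 target samples, 30 shared CpGs (+1 source-only), beta values.
.meth_toy <- function(seed = 1L) {
  set.seed(seed)
  n_s <- 6L; n_t <- 4L; n_cpg <- 30L
  cpgs <- sprintf("cpg%02d", seq_len(n_cpg))
  V_s <- matrix(stats::runif(n_s * n_cpg), n_s, n_cpg)
  V_t <- matrix(stats::runif(n_t * n_cpg), n_t, n_cpg)
  mask_s <- matrix(FALSE, n_s, n_cpg); mask_t <- matrix(FALSE, n_t, n_cpg)
  # cpg05: 3/10 pooled missing (dropped); cpg10: 2/10 (kept)
  mask_s[c(1L, 3L), 5L] <- TRUE; mask_t[2L, 5L] <- TRUE
  mask_s[2L, 10L] <- TRUE; mask_t[1L, 10L] <- TRUE
  V_s[mask_s] <- NA; V_t[mask_t] <- NA
  # a CpG present only in the source; must be discarded by the common filter
  V_s <- cbind(V_s, stats::runif(n_s))
  list(
    source = omics_matrix(V_s, sample_ids = sprintf("s%02d", seq_len(n_s)),
                          feature_ids = c(cpgs, "cpg31"), modality = "meth",
                          domain = "source"),
    target = omics_matrix(V_t, sample_ids = sprintf("t%02d", seq_len(n_t)),
                          feature_ids = cpgs, modality = "meth",
                          domain = "target"),
    dropped_cpgs = "cpg05", imputed_cpgs = "cpg10")
}

# 3 genes, 6 peaks, 4 samples; overlaps computable by hand:
#   g1 [100,200)+ <- p1, p2;  g2 [150,300)+ <- p2, p3;  g3 [100,200)- <- p5
.atac_toy <- function() {
  genes <- gene_annotation(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 150L, 100L), end = c(200L, 300L, 200L),
    strand = c("+", "+", "-"))
  pk <- tibble::tibble(
    peak_id = paste0("p", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(120L, 190L, 250L, 300L, 150L, 400L),
    end = c(130L, 210L, 260L, 310L, 160L, 410L))
  counts <- matrix(seq_len(24), nrow = 4L, ncol = 6L,
                   dimnames = list(paste0("s", 1:4), pk$peak_id))
  list(peaks = peak_set(pk, counts), genes = genes,
       expected = cbind(g1 = counts[, "p1"] + counts[, "p2"],
                        g2 = counts[, "p2"] + counts[, "p3"],
                        g3 = counts[, "p5"]))
}
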