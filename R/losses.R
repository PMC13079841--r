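# Loss functions of the four training phases, implemented as pure functions
# over posterior/latent matrices so each is testable in isolation.

LOG_CLAMP <- 1e-12

#' Pseudo-label ramp schedule
#'
#' Parameters of the piecewise-linear schedule that controls the weight of
#' the pseudo-labeled target term in the semi-supervised loss: zero before
#' epoch `T1`, linear ramp between `T1` and `T2`, constant at `alpha_f`
#' afterwards.
#'
#' @param T1,T2 epoch thresholds (0 <= T1 < T2).
#' @param alpha_f plateau value of the coefficient.
#' @return list with class `schedule_params`.
#' @export
schedule_params <- function(T1 = 100L, T2 = 200L, alpha_f = 0.01) {
  stopifnot(T1 >= 0, T1 < T2, alpha_f >= 0)
  structure(list(T1 = as.integer(T1), T2 = as.integer(T2), alpha_f = alpha_f),
            class = "schedule_params")
}

#' @rdname schedule_params
#' @param t epoch number (>= 0); vectorized.
#' @param params a [schedule_params()] list.
#' @return the coefficient alpha(t).
#' @export
alpha_schedule <- function(t, params = schedule_params()) {
  stopifnot(all(t >= 0))
  ifelse(t < params$T1, 0,
         ifelse(t < params$T2,
                params$alpha_f * (t - params$T1) / (params$T2 - params$T1),
                params$alpha_f))
}

#' Mean cross-entropy
#'
#' \eqn{-(1/n) \sum_i \sum_k y_{ik} \log p_{ik}} with posteriors clamped at
#' 1e-12 before the log.
#'
#' @param posteriors n x K row-stochastic matrix.
#' @param onehot n x K one-hot matrix of true classes.
#' @return scalar loss.
#' @export
cross_entropy <- function(posteriors, onehot) {
  if (!all(dim(posteriors) == dim(onehot)))
    stop("posteriors and onehot must have identical shapes")
  -sum(onehot * log(pmax(posteriors, LOG_CLAMP))) / nrow(posteriors)
}

#' Domain discriminator loss
#'
#' Cross-entropy of a 2-class (source/target) domain discriminator over the
#' pooled samples; the quantity the discriminator minimizes in the
#' adversarial phases.
#'
#' @param domain_posteriors n x 2 row-stochastic matrix.
#' @param domain_onehot n x 2 one-hot domain indicators.
#' @return scalar loss.
#' @export
domain_discriminator_loss <- function(domain_posteriors, domain_onehot) {
  stopifnot(ncol(domain_posteriors) == 2L)
  cross_entropy(domain_posteriors, domain_onehot)
}

#' Extractor confusion loss
#'
#' The negation of [domain_discriminator_loss()]: minimizing it in the
#' extractor realizes the max over the extractor in the adversarial
#' min--max objective.
#'
#' @inheritParams domain_discriminator_loss
#' @return scalar loss (always <= 0).
#' @export
extractor_confusion_loss <- function(domain_posteriors, domain_onehot) {
  -domain_discriminator_loss(domain_posteriors, domain_onehot)
}

#' Pseudo-label assignment
#'
#' Assigns each sample the class with the highest posterior probability
#' (ties broken toward the lowest class index) and flags which samples pass
#' the confidence threshold.
#'
#' @param posteriors n x K row-stochastic matrix.
#' @param confidence_threshold keep samples whose max posterior is >= this.
#' @return list(labels = integer vector in 1..K, keep = logical vector).
#' @export
assign_pseudo_labels <- function(posteriors, confidence_threshold = 0) {
  labels <- max.col(posteriors, ties.method = "first")
  mx <- posteriors[cbind(seq_len(nrow(posteriors)), labels)]
  list(labels = labels, keep = mx >= confidence_threshold)
}

#' Semi-supervised loss
#'
#' Supervised cross-entropy on the source plus the ramped pseudo-label
#' cross-entropy on the kept target samples:
#' \eqn{CE_s + \alpha(t) \cdot CE_t}. With an empty keep set the target term
#' is 0.
#'
#' @param source_post,source_onehot source posteriors and one-hot labels.
#' @param target_post,target_pseudo_onehot target posteriors and one-hot
#'   pseudo-labels.
#' @param keep logical mask of target samples entering the loss.
#' @param t epoch number.
#' @param params a [schedule_params()].
#' @return scalar loss.
#' @export
ssl_loss <- function(source_post, source_onehot, target_post,
                     target_pseudo_onehot, keep, t, params = schedule_params()) {
  a <- alpha_schedule(t, params)
  total <- cross_entropy(source_post, source_onehot)
  if (a > 0 && any(keep)) {
    total <- total + a * cross_entropy(target_post[keep, , drop = FALSE],
                                       target_pseudo_onehot[keep, , drop = FALSE])
  }
  total
}

#' Class-level centroid alignment loss
#'
#' For each class k the global centroid (both domains pooled) and each
#' domain-specific centroid are computed in latent space, and the squared
#' Euclidean gaps are averaged over classes:
#' \eqn{(1/K) \sum_k \sum_m \lVert C^k - C^k_m \rVert_2^2}. A (class, domain)
#' cell with no samples contributes 0; a class with no samples at all
#' contributes 0 with a warning.
#'
#' @param latent n x d latent matrix.
#' @param class_labels integer vector in 1..K.
#' @param domain_labels integer vector in 1..M.
#' @param K,M class and domain counts.
#' @return scalar loss (>= 0).
#' @export
centroid_alignment_loss <- function(latent, class_labels, domain_labels, K, M) {
  stopifnot(nrow(latent) == length(class_labels),
            length(class_labels) == length(domain_labels),
            all(class_labels >= 1), all(class_labels <= K),
            all(domain_labels >= 1), all(domain_labels <= M))
  total <- 0
  for (k in seq_len(K)) {
    in_k <- class_labels == k
    if (!any(in_k)) {
      warning(sprintf("class %d has no samples; contributes 0 to centroid loss", k))
      next
    }
    Ck <- colMeans(latent[in_k, , drop = FALSE])
    for (m in seq_len(M)) {
      in_km <- in_k & domain_labels == m
      if (!any(in_km)) next
      Ckm <- colMeans(latent[in_km, , drop = FALSE])
      total <- total + sum((Ck - Ckm)^2)
    }
  }
  total / K
}

# Analytic gradient of centroid_alignment_loss w.r.t. the latent matrix.
# For sample i in class k, domain m0:
#   dL/dz_i = (2/K) * sum_m (C^k - C^k_m) * (1/n_k - [m == m0]/n_{k,m0})
#' @noRd
centroid_alignment_grad <- function(latent, class_labels, domain_labels, K, M) {
  n <- nrow(latent)
  G <- matrix(0, n, ncol(latent))
  for (k in seq_len(K)) {
    in_k <- class_labels == k
    nk <- sum(in_k)
    if (nk == 0L) next
    Ck <- colMeans(latent[in_k, , drop = FALSE])
    diffs <- vector("list", M)   # C^k - C^k_m
    counts <- integer(M)
    for (m in seq_len(M)) {
      in_km <- in_k & domain_labels == m
      counts[m] <- sum(in_km)
      if (counts[m] > 0L)
        diffs[[m]] <- Ck - colMeans(latent[in_km, , drop = FALSE])
    }
    present <- which(counts > 0L)
    sum_diff <- Reduce(`+`, diffs[present])  # sum over present domains
    for (m in present) {
      idx <- which(in_k & domain_labels == m)
      # common term through the global centroid plus the domain-specific term
      g_row <- (2 / K) * (sum_diff / nk - diffs[[m]] / counts[m])
      G[idx, ] <- matrix(g_row, length(idx), ncol(latent), byrow = TRUE)
    }
  }
  G
}

#' One-hot encoding of class indices
#'
#' @param labels integer vector in 1..K.
#' @param K number of classes.
#' @return n x K 0/1 matrix.
#' @export
one_hot <- function(labels, K) {
  stopifnot(all(labels >= 1), all(labels <= K))
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}
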