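# Brute-force reference implementations (plain double loops) used as
# independent oracles for the loss and clustering metrics.

oracle_cross_entropy <- function(P, Y) {
  n <- nrow(P); K <- ncol(P)
  total <- 0
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      total <- total - Y[i, k] * log(max(P[i, k], 1e-12))
    }
  }
  total / n
}

oracle_ssl <- function(Ps, Ys, Pt, Yt, keep, t, params) {
  a <- if (t < params$T1) 0
       else if (t < params$T2) params$alpha_f * (t - params$T1) / (params$T2 - params$T1)
       else params$alpha_f
  out <- oracle_cross_entropy(Ps, Ys)
  if (a > 0 && sum(keep) > 0)
    out <- out + a * oracle_cross_entropy(Pt[keep, , drop = FALSE],
                                          Yt[keep, , drop = FALSE])
  out
}

oracle_centroid <- function(latent, cls, dom, K, M) {
  total <- 0
  for (k in seq_len(K)) {
    idx_k <- which(cls == k)
    if (!length(idx_k)) next
    Ck <- colMeans(latent[idx_k, , drop = FALSE])
    for (m in seq_len(M)) {
      idx_km <- idx_k[dom[idx_k] == m]
      if (!length(idx_km)) next
      Ckm <- colMeans(latent[idx_km, , drop = FALSE])
      total <- total + sum((Ck - Ckm)^2)
    }
  }
  total / K
}

oracle_silhouette <- function(X, cl) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (c in setdiff(unique(cl), cl[i])) {
      ot <- which(cl == c)
      b <- min(b, mean(vapply(ot, function(j) d(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbi <- function(X, cl) {
  cls <- sort(unique(cl))
  k <- length(cls)
  cent <- S <- vector("list", k)
  for (ci in seq_len(k)) {
    Xi <- X[cl == cls[ci], , drop = FALSE]
    cent[[ci]] <- colMeans(Xi)
    S[[ci]] <- mean(apply(Xi, 1, function(r) sqrt(sum((r - cent[[ci]])^2))))
  }
  db <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (S[[i]] + S[[j]]) / M)
    }
    db <- db + best
  }
  db / k
}

oracle_gene_activity <- function(peaks_df, counts, genes_df, gene_ids) {
  out <- matrix(0, nrow(counts), length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- genes_df[genes_df$gene_id == gene_ids[gi], ]
    for (pi in seq_len(nrow(peaks_df))) {
      p <- peaks_df[pi, ]
      # 0-based half-open intervals: overlap iff nonempty intersection
      if (p$chrom == g$chrom && p$start < g$end && g$start < p$end) {
        out[, gi] <- out[, gi] + counts[, pi]
      }
    }
  }
  out
}
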