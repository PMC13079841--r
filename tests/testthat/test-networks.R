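# Network construction: architecture widths, determinism, forward contracts.

test_that("bundle components have the reference layer widths", {
  cfg <- train_config(seed = 5L)
  b <- build_bundle(c(3000L, 3000L), 7L, cfg)
  # single-omics extractor: m -> 1024 -> 512
  expect_equal(dim(b$F[[1]]$layers[[1]]$W), c(3000L, 1024L))
  expect_equal(dim(b$F[[1]]$layers[[2]]$W), c(1024L, 512L))
  # shared extractor: concat(2 x 512) = 1024 -> 512 -> 256
  expect_equal(dim(b$G$layers[[1]]$W), c(1024L, 512L))
  expect_equal(dim(b$G$layers[[2]]$W), c(512L, 256L))
  # classifier heads: 128 -> 64 -> K
  expect_equal(dim(b$C_multi$layers[[1]]$W), c(256L, 128L))
  expect_equal(dim(b$C_multi$layers[[2]]$W), c(128L, 64L))
  expect_equal(dim(b$C_multi$final$W), c(64L, 7L))
  expect_equal(dim(b$C_single[[1]]$layers[[1]]$W), c(512L, 128L))
  # discriminators: 256 -> 64 -> 2
  expect_equal(dim(b$D_single[[1]]$layers[[1]]$W), c(512L, 256L))
  expect_equal(dim(b$D_single[[1]]$layers[[2]]$W), c(256L, 64L))
  expect_equal(dim(b$D_single[[1]]$final$W), c(64L, 2L))
  expect_equal(dim(b$D_shared$layers[[1]]$W), c(256L, 256L))
  expect_equal(b$latent_dim, 256L)
  # single modality: G consumes one 512 block
  b1 <- build_bundle(100L, 3L, cfg)
  expect_equal(dim(b1$G$layers[[1]]$W), c(512L, 512L))
  expect_error(build_bundle(c(10L, 10L), 1L, cfg), "n_classes")
})

test_that("parameter counts match the closed-form width arithmetic", {
  cfg <- train_config(seed = 6L)
  b <- build_bundle(c(40L, 60L), 3L, cfg)
  # weights + 4 batch-norm vectors (gamma, beta, running mean/var) per hidden
  count_mlp <- function(dims, out = NULL) {
    tot <- 0
    for (i in seq_along(dims[-1])) tot <- tot + dims[i] * dims[i + 1] + 4 * dims[i + 1]
    if (!is.null(out)) tot <- tot + dims[length(dims)] * out + out
    tot
  }
  n_stored <- function(net) {
    tot <- sum(vapply(net$layers, function(l)
      length(l$W) + length(l$gamma) + length(l$beta) +
        length(l$r_mean) + length(l$r_var), 0))
    if (!is.null(net$final)) tot <- tot + length(net$final$W) + length(net$final$b)
    tot
  }
  expect_equal(n_stored(b$F[[1]]), count_mlp(c(40, 1024, 512)))
  expect_equal(n_stored(b$G), count_mlp(c(1024, 512, 256)))
  expect_equal(n_stored(b$C_multi), count_mlp(c(256, 128, 64), out = 3))
  expect_equal(n_stored(b$D_shared), count_mlp(c(256, 256, 64), out = 2))
  # n_parameters counts only trainable tensors (no running statistics)
  expect_equal(n_parameters(b$C_multi),
               256 * 128 + 2 * 128 + 128 * 64 + 2 * 64 + 64 * 3 + 3)
})

test_that("initialization is deterministic given the seed", {
  cfg <- train_config(seed = 11L)
  b1 <- build_bundle(c(30L, 30L), 3L, cfg)
  b2 <- build_bundle(c(30L, 30L), 3L, cfg)
  expect_identical(b1$F[[1]]$layers[[1]]$W, b2$F[[1]]$layers[[1]]$W)
  expect_identical(b1$D_shared$final$W, b2$D_shared$final$W)
  b3 <- build_bundle(c(30L, 30L), 3L, train_config(seed = 12L))
  expect_false(identical(b1$F[[1]]$layers[[1]]$W, b3$F[[1]]$layers[[1]]$W))
})

test_that("forward passes obey shape and determinism contracts", {
  cfg <- train_config(seed = 13L)
  b <- build_bundle(c(20L, 15L), 3L, cfg)
  X1 <- matrix(rnorm(8 * 20), 8, 20)
  X2 <- matrix(rnorm(8 * 15), 8, 15)
  lat1 <- forward_single(b, 1, X1)
  expect_equal(dim(lat1), c(8L, 512L))
  expect_identical(forward_single(b, 1, X1), lat1)  # inference determinism
  expect_error(forward_single(b, 1, X2), "expects 20 features")
  z <- forward_integrated(b, list(X1, X2))
  expect_equal(dim(z), c(8L, 256L))
  expect_error(forward_integrated(b, list(X1, X2[1:5, ])), "same number")
  # permutation equivariance
  perm <- sample(8)
  z_perm <- forward_integrated(b, list(X1[perm, ], X2[perm, ]))
  expect_equal(z_perm, z[perm, ], tolerance = 1e-12)
})

test_that("classifier posteriors are row-stochastic and shift-invariant", {
  cfg <- train_config(seed = 14L)
  b <- build_bundle(10L, 2L, cfg)
  lat <- matrix(rnorm(6 * 256), 6, 256)
  P <- classify(b$C_multi, lat)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P > 0 & P < 1))
  expect_error(classify(b$C_multi, lat[, 1:10]), "256")
  # softmax: equal logits and constant shifts
  expect_equal(softmax(matrix(c(2, 2), 1)), matrix(c(0.5, 0.5), 1))
  lg <- matrix(rnorm(12), 3, 4)
  expect_equal(softmax(lg), softmax(lg + 5), tolerance = 1e-12)
})

test_that("zeroed modality weights sever that modality's information flow", {
  cfg <- train_config(seed = 15L)
  b <- build_bundle(c(12L, 12L), 2L, cfg)
  for (l in seq_along(b$F[[2]]$layers)) {
    b$F[[2]]$layers[[l]]$W[] <- 0
    b$F[[2]]$layers[[l]]$gamma[] <- 0
  }
  X1 <- matrix(rnorm(5 * 12), 5, 12)
  X2a <- matrix(rnorm(5 * 12), 5, 12)
  X2b <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(forward_integrated(b, list(X1, X2a)),
               forward_integrated(b, list(X1, X2b)), tolerance = 1e-12)
  X1b <- X1; X1b[1, ] <- X1b[1, ] + 1
  expect_false(isTRUE(all.equal(forward_integrated(b, list(X1, X2a)),
                                forward_integrated(b, list(X1b, X2a)))))
  # zero-weight network maps every sample to the same point
  lat2 <- forward_single(b, 2, X2a)
  expect_equal(max(apply(lat2, 2, function(c) diff(range(c)))), 0)
})

test_that("checkpoints round-trip with manifest validation", {
  cfg <- train_config(seed = 16L)
  b <- build_bundle(c(10L, 10L), 3L, cfg)
  path <- tempfile(fileext = ".rds")
  save_bundle(b, path)
  b2 <- load_bundle(path, expect = list(feature_dims = c(10L, 10L), n_classes = 3L))
  expect_identical(b2$F[[1]]$layers[[1]]$W, b$F[[1]]$layers[[1]]$W)
  expect_error(load_bundle(path, expect = list(n_classes = 5L)), "n_classes")
})
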