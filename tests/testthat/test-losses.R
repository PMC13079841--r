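# Loss functions: closed-form examples, oracle equivalence, schedule shape,
# and gradient correctness of the centroid alignment term.

test_that("cross-entropy matches closed forms", {
  P <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(pmax(P, 1e-15), diag(3)), 0, tolerance = 1e-10)
  # uniform posterior over K = 4 classes
  P4 <- matrix(0.25, 5, 4)
  Y4 <- one_hot(sample(1:4, 5, TRUE), 4)
  expect_equal(cross_entropy(P4, Y4), log(4))
  # two samples with true-class probabilities 0.5 and 0.25
  P2 <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  Y2 <- rbind(c(1, 0), c(1, 0))
  expect_equal(cross_entropy(P2, Y2), (log(2) + log(4)) / 2)
  expect_error(cross_entropy(P2, diag(3)), "shape")
})

test_that("domain losses are two-class cross-entropy and its negation", {
  set.seed(31)
  P <- softmax(matrix(rnorm(20), 10, 2))
  D <- one_hot(sample(1:2, 10, TRUE), 2)
  expect_equal(domain_discriminator_loss(P, D), cross_entropy(P, D))
  expect_equal(extractor_confusion_loss(P, D), -domain_discriminator_loss(P, D))
  expect_equal(domain_discriminator_loss(matrix(0.5, 6, 2), one_hot(rep(1L, 6), 2)),
               log(2))
  # the two losses always cancel
  expect_equal(domain_discriminator_loss(P, D) + extractor_confusion_loss(P, D), 0)
})

test_that("pseudo-label assignment uses argmax with low-index ties", {
  P <- rbind(c(0.1, 0.7, 0.2),
             c(1, 1, 1) / 3,
             c(0.4, 0.4, 0.2))
  pl <- assign_pseudo_labels(P, confidence_threshold = 0.5)
  expect_equal(pl$labels, c(2L, 1L, 1L))
  expect_equal(pl$keep, c(TRUE, FALSE, FALSE))
  # threshold 1 on non-degenerate rows empties the keep set
  expect_false(any(assign_pseudo_labels(P, 1)$keep))
  expect_true(all(assign_pseudo_labels(P, 0)$keep))
})

test_that("ramp schedule has the documented piecewise shape", {
  sp <- schedule_params(T1 = 100, T2 = 200, alpha_f = 0.01)
  expect_equal(alpha_schedule(50, sp), 0)
  expect_equal(alpha_schedule(150, sp), 0.005)
  expect_equal(alpha_schedule(250, sp), 0.01)
  # non-decreasing and continuous at the thresholds
  t <- 0:300
  a <- alpha_schedule(t, sp)
  expect_true(all(diff(a) >= 0))
  expect_equal(alpha_schedule(100, sp), 0, tolerance = 1e-12)
  expect_lt(abs(alpha_schedule(199, sp) - 0.01), 2e-4)
  expect_error(schedule_params(T1 = 200, T2 = 100))
})

test_that("ssl loss composes source and ramped pseudo-label terms", {
  set.seed(32)
  Ps <- softmax(matrix(rnorm(12), 4, 3)); Ys <- one_hot(c(1, 2, 3, 1), 3)
  Pt <- softmax(matrix(rnorm(15), 5, 3)); Yt <- one_hot(c(2, 2, 1, 3, 1), 3)
  keep <- rep(TRUE, 5)
  sp <- schedule_params()
  # before T1 the pseudo-label term vanishes identically
  expect_identical(ssl_loss(Ps, Ys, Pt, Yt, keep, t = 50, sp),
                   cross_entropy(Ps, Ys))
  expect_equal(ssl_loss(Ps, Ys, Pt, Yt, keep, t = 150, sp),
               cross_entropy(Ps, Ys) + 0.005 * cross_entropy(Pt, Yt))
  # empty keep set drops the target term at any epoch
  expect_equal(ssl_loss(Ps, Ys, Pt, Yt, rep(FALSE, 5), t = 300, sp),
               cross_entropy(Ps, Ys))
})

test_that("centroid alignment matches hand computations", {
  # per-class centroids identical across domains
  lat <- rbind(c(1, 1), c(1, 1), c(5, 0), c(5, 0))
  expect_equal(centroid_alignment_loss(lat, c(1, 1, 2, 2), c(1, 2, 1, 2), 2, 2), 0)
  # K = 1, equal-size domains at (1,0) and (-1,0): global at origin -> 1 + 1
  lat2 <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  expect_equal(centroid_alignment_loss(lat2, rep(1, 4), c(1, 1, 2, 2), 1, 2), 2)
  # single domain: global centroid equals the only domain centroid
  set.seed(33)
  lat3 <- matrix(rnorm(20), 10, 2)
  expect_equal(centroid_alignment_loss(lat3, sample(1:2, 10, TRUE),
                                       rep(1, 10), 2, 1), 0)
  # an empty class contributes 0 with a warning
  expect_warning(
    v <- centroid_alignment_loss(lat2, rep(1, 4), c(1, 1, 2, 2), 2, 2),
    "class 2")
  expect_equal(v, 1)  # (1/K) scaling with K = 2
  # translation invariance
  shift <- matrix(rep(c(3, -7), each = 4), 4, 2)
  expect_equal(centroid_alignment_loss(lat2 + shift, rep(1, 4), c(1, 1, 2, 2), 1, 2),
               centroid_alignment_loss(lat2, rep(1, 4), c(1, 1, 2, 2), 1, 2))
})

test_that("losses match brute-force oracles on random 5-sample instances", {
  set.seed(34)
  sp <- schedule_params()
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    Ps <- softmax(matrix(rnorm(5 * K), 5, K))
    Ys <- one_hot(sample.int(K, 5, TRUE), K)
    expect_equal(cross_entropy(Ps, Ys), oracle_cross_entropy(Ps, Ys),
                 tolerance = 1e-10)
    Pd <- softmax(matrix(rnorm(10), 5, 2))
    Yd <- one_hot(sample(1:2, 5, TRUE), 2)
    expect_equal(domain_discriminator_loss(Pd, Yd), oracle_cross_entropy(Pd, Yd),
                 tolerance = 1e-10)
    Pt <- softmax(matrix(rnorm(5 * K), 5, K))
    Yt <- one_hot(sample.int(K, 5, TRUE), K)
    keep <- sample(c(TRUE, FALSE), 5, TRUE)
    t_ep <- sample(0:300, 1)
    expect_equal(ssl_loss(Ps, Ys, Pt, Yt, keep, t_ep, sp),
                 oracle_ssl(Ps, Ys, Pt, Yt, keep, t_ep, sp), tolerance = 1e-10)
    lat <- matrix(rnorm(15), 5, 3)
    cls <- sample.int(K, 5, TRUE)
    dom <- sample(1:2, 5, TRUE)
    expect_equal(suppressWarnings(centroid_alignment_loss(lat, cls, dom, K, 2)),
                 oracle_centroid(lat, cls, dom, K, 2), tolerance = 1e-10)
  }
})

test_that("centroid alignment gradient agrees with finite differences", {
  set.seed(35)
  lat <- matrix(rnorm(24), 8, 3)
  cls <- sample(1:3, 8, TRUE)
  dom <- sample(1:2, 8, TRUE)
  g <- modamix:::centroid_alignment_grad(lat, cls, dom, 3, 2)
  eps <- 1e-6
  for (idx in sample(length(lat), 6)) {
    lp <- lat; lp[idx] <- lp[idx] + eps
    lm <- lat; lm[idx] <- lm[idx] - eps
    num <- (suppressWarnings(centroid_alignment_loss(lp, cls, dom, 3, 2)) -
              suppressWarnings(centroid_alignment_loss(lm, cls, dom, 3, 2))) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-6)
  }
})
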