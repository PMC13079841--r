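# Four-phase training orchestration:
#   1. supervised pre-training: each modality extractor F^(o) with its own
#      classifier head, then the shared extractor G (+ C_multi) on the
#      frozen-F concatenated embeddings;
#   2. per-modality adversarial domain adaptation (D^(o) vs F^(o));
#   3. adversarial alignment of the integrated latent (D_shared vs G);
#   4. semi-supervised refinement: pseudo-labeled cross-entropy with the
#      ramp schedule plus class-level centroid alignment, training F, G and
#      C_multi jointly.
# The min--max adversarial objectives are realized by alternating updates
# (one discriminator step and one extractor step per iteration, both
# gradients evaluated at the current parameters — the confusion loss being
# the exact negation of the discriminator loss, one shared backward pass
# yields both), which fits the separate per-component learning rates
# naturally. Classifiers are
# frozen during phases 2-3; discriminators are frozen in phase 4. Each phase
# gets fresh Adam state for the components it trains.

#' Training configuration
#'
#' All hyperparameters of the four-phase trainer. Defaults are the model's
#' reference settings: 500 epochs for phases 1-3 and 800 for phase 4, Adam
#' with learning rates 1e-4 (extractors), 1e-5 (classifiers) and 1e-6
#' (discriminators), full-batch updates, ramp schedule thresholds
#' T1 = 100 / T2 = 200 with plateau 0.01.
#'
#' @param epochs_phase1,epochs_phase2,epochs_phase3,epochs_phase4 epoch
#'   counts per phase.
#' @param lr_extractor,lr_classifier,lr_discriminator Adam learning rates.
#' @param schedule a [schedule_params()] for the pseudo-label ramp.
#' @param centroid_weight weight of the centroid alignment loss in phase 4.
#' @param batch_size `"full"` or an integer minibatch size.
#' @param seed integer seed controlling initialization and any shuffling.
#' @param ablation `"none"`, `"no_at_multi"` (skip phase 3) or
#'   `"no_at_all"` (skip phases 2 and 3).
#' @param confidence_threshold minimum posterior for a pseudo-label to enter
#'   the phase-4 loss (0 keeps all).
#' @param leaky_slope LeakyReLU negative slope.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs_phase1 = 500L, epochs_phase2 = 500L,
                         epochs_phase3 = 500L, epochs_phase4 = 800L,
                         lr_extractor = 1e-4, lr_classifier = 1e-5,
                         lr_discriminator = 1e-6,
                         schedule = schedule_params(),
                         centroid_weight = 1.0, batch_size = "full",
                         seed = 1L,
                         ablation = c("none", "no_at_multi", "no_at_all"),
                         confidence_threshold = 0, leaky_slope = 0.01) {
  ablation <- match.arg(ablation)
  stopifnot(lr_extractor > 0, lr_classifier > 0, lr_discriminator > 0,
            epochs_phase1 >= 0, epochs_phase2 >= 0, epochs_phase3 >= 0,
            epochs_phase4 >= 0, centroid_weight >= 0,
            confidence_threshold >= 0, confidence_threshold <= 1)
  if (!identical(batch_size, "full")) stopifnot(batch_size >= 1)
  structure(list(epochs_phase1 = as.integer(epochs_phase1),
                 epochs_phase2 = as.integer(epochs_phase2),
                 epochs_phase3 = as.integer(epochs_phase3),
                 epochs_phase4 = as.integer(epochs_phase4),
                 lr_extractor = lr_extractor, lr_classifier = lr_classifier,
                 lr_discriminator = lr_discriminator, schedule = schedule,
                 centroid_weight = centroid_weight, batch_size = batch_size,
                 seed = as.integer(seed), ablation = ablation,
                 confidence_threshold = confidence_threshold,
                 leaky_slope = leaky_slope),
            class = "train_config")
}

.batches <- function(n, batch_size) {
  if (identical(batch_size, "full")) return(list(seq_len(n)))
  split(sample.int(n), ceiling(seq_len(n) / batch_size))
}

.hist_tbl <- function(phase, epoch, loss, value) {
  tibble::tibble(phase = phase, epoch = as.integer(epoch), loss = loss,
                 value = as.numeric(value))
}

# ---- phase 1 --------------------------------------------------------------

#' Phase 1: supervised pre-training
#'
#' Trains each modality extractor with its per-modality classifier head on
#' labeled source data (cross-entropy), then the shared extractor and the
#' integrated classifier head on the frozen-F concatenated embeddings.
#'
#' @param bundle a [build_bundle()] bundle.
#' @param source labeled source `multiomics_dataset`.
#' @param config a [train_config()].
#' @return list(bundle, history).
#' @export
phase1_pretrain <- function(bundle, source, config) {
  if (is.null(source$labels)) stop("phase 1 requires a labeled source dataset")
  X <- dataset_values(source)
  Y <- one_hot(source$labels, bundle$n_classes)
  n <- nrow(Y)
  hist <- list()
  for (o in seq_len(bundle$n_modalities)) {
    stF <- adam_new(); stC <- adam_new()
    ep <- seq_len(config$epochs_phase1)
    ce_tr <- acc_tr <- numeric(length(ep))
    for (t in ep) {
      ce_b <- 0; acc_b <- 0
      for (idx in .batches(n, config$batch_size)) {
        fF <- nn_forward(bundle$F[[o]], X[[o]][idx, , drop = FALSE],
                         training = TRUE, keep_cache = TRUE)
        bundle$F[[o]] <- fF$net
        fC <- nn_forward(bundle$C_single[[o]], fF$out,
                         training = TRUE, keep_cache = TRUE)
        bundle$C_single[[o]] <- fC$net
        P <- softmax(fC$out)
        Yb <- Y[idx, , drop = FALSE]
        ce_b <- ce_b + cross_entropy(P, Yb) * length(idx)
        acc_b <- acc_b + sum(max.col(P, ties.method = "first") ==
                               source$labels[idx])
        dlog <- (P - Yb) / length(idx)
        bC <- nn_backward(bundle$C_single[[o]], fC$cache, dlog, input_grad = TRUE)
        bF <- nn_backward(bundle$F[[o]], fF$cache, bC$d_input, input_grad = FALSE)
        r <- adam_step(bundle$C_single[[o]], bC$grads, stC, config$lr_classifier)
        bundle$C_single[[o]] <- r$net; stC <- r$state
        r <- adam_step(bundle$F[[o]], bF$grads, stF, config$lr_extractor)
        bundle$F[[o]] <- r$net; stF <- r$state
      }
      ce_tr[t] <- ce_b / n; acc_tr[t] <- acc_b / n
    }
    if (length(ep))
      hist[[length(hist) + 1L]] <- dplyr::bind_rows(
        .hist_tbl("phase1", ep, sprintf("pretrain_ce_mod%d", o), ce_tr),
        .hist_tbl("phase1", ep, sprintf("pretrain_acc_mod%d", o), acc_tr))
  }
  # shared extractor on frozen-F embeddings (inference mode, precomputed)
  Z <- do.call(cbind, lapply(seq_len(bundle$n_modalities), function(o)
    nn_forward(bundle$F[[o]], X[[o]], training = FALSE)$out))
  stG <- adam_new(); stC <- adam_new()
  ep <- seq_len(config$epochs_phase1)
  ce_tr <- acc_tr <- numeric(length(ep))
  for (t in ep) {
    ce_b <- 0; acc_b <- 0
    for (idx in .batches(n, config$batch_size)) {
      fG <- nn_forward(bundle$G, Z[idx, , drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
      bundle$G <- fG$net
      fC <- nn_forward(bundle$C_multi, fG$out, training = TRUE, keep_cache = TRUE)
      bundle$C_multi <- fC$net
      P <- softmax(fC$out)
      Yb <- Y[idx, , drop = FALSE]
      ce_b <- ce_b + cross_entropy(P, Yb) * length(idx)
      acc_b <- acc_b + sum(max.col(P, ties.method = "first") == source$labels[idx])
      dlog <- (P - Yb) / length(idx)
      bC <- nn_backward(bundle$C_multi, fC$cache, dlog, input_grad = TRUE)
      bG <- nn_backward(bundle$G, fG$cache, bC$d_input, input_grad = FALSE)
      r <- adam_step(bundle$C_multi, bC$grads, stC, config$lr_classifier)
      bundle$C_multi <- r$net; stC <- r$state
      r <- adam_step(bundle$G, bG$grads, stG, config$lr_extractor)
      bundle$G <- r$net; stG <- r$state
    }
    ce_tr[t] <- ce_b / n; acc_tr[t] <- acc_b / n
  }
  if (length(ep))
    hist[[length(hist) + 1L]] <- dplyr::bind_rows(
      .hist_tbl("phase1", ep, "pretrain_ce_shared", ce_tr),
      .hist_tbl("phase1", ep, "pretrain_acc_shared", acc_tr))
  list(bundle = bundle, history = dplyr::bind_rows(hist))
}

# ---- phases 2 and 3 (adversarial) ----------------------------------------

# one adversarial epoch on precomputed-or-not latents; used by both phases.
# ext_fwd(bundle, idx) must return list(out, cache, commit(bundle, net));
# here we inline instead for clarity and speed.

#' Phase 2: single-omics adversarial domain adaptation
#'
#' For each modality, alternates a discriminator step (minimize the domain
#' cross-entropy on pooled source+target latents) with an extractor step
#' (minimize the confusion loss, i.e. maximize the discriminator's loss).
#' Classifiers are untouched. Skipped entirely under
#' `ablation = "no_at_all"`.
#'
#' @inheritParams phase1_pretrain
#' @param target unlabeled target `multiomics_dataset`.
#' @return list(bundle, history).
#' @export
phase2_single_omics_da <- function(bundle, source, target, config) {
  if (config$ablation == "no_at_all")
    return(list(bundle = bundle, history = .hist_tbl(character(), integer(),
                                                     character(), numeric())))
  Xs <- dataset_values(source); Xt <- dataset_values(target)
  n_s <- n_samples(source); n_t <- n_samples(target)
  n <- n_s + n_t
  Dlab <- one_hot(c(rep(1L, n_s), rep(2L, n_t)), 2L)
  hist <- list()
  for (o in seq_len(bundle$n_modalities)) {
    Xp <- rbind(Xs[[o]], Xt[[o]])
    stD <- adam_new(); stF <- adam_new()
    ep <- seq_len(config$epochs_phase2)
    ld <- lc <- numeric(length(ep))
    for (t in ep) {
      ld_b <- lc_b <- 0
      for (idx in .batches(n, config$batch_size)) {
        Db <- Dlab[idx, , drop = FALSE]
        fF <- nn_forward(bundle$F[[o]], Xp[idx, , drop = FALSE],
                         training = TRUE, keep_cache = TRUE)
        bundle$F[[o]] <- fF$net
        # one discriminator forward/backward serves both players: the
        # confusion loss is the exact negation of the discriminator loss,
        # so the extractor's latent gradient is -d_input (simultaneous
        # alternation: both steps evaluated at the current parameters)
        fD <- nn_forward(bundle$D_single[[o]], fF$out,
                         training = TRUE, keep_cache = TRUE)
        bundle$D_single[[o]] <- fD$net
        P <- softmax(fD$out)
        ld_c <- domain_discriminator_loss(P, Db)
        ld_b <- ld_b + ld_c * length(idx)
        lc_b <- lc_b - ld_c * length(idx)
        dlog <- (P - Db) / length(idx)
        bD <- nn_backward(bundle$D_single[[o]], fD$cache, dlog, input_grad = TRUE)
        bF <- nn_backward(bundle$F[[o]], fF$cache, -bD$d_input, input_grad = FALSE)
        r <- adam_step(bundle$D_single[[o]], bD$grads, stD, config$lr_discriminator)
        bundle$D_single[[o]] <- r$net; stD <- r$state
        r <- adam_step(bundle$F[[o]], bF$grads, stF, config$lr_extractor)
        bundle$F[[o]] <- r$net; stF <- r$state
      }
      ld[t] <- ld_b / n; lc[t] <- lc_b / n
    }
    if (length(ep))
      hist[[length(hist) + 1L]] <- dplyr::bind_rows(
        .hist_tbl("phase2", ep, sprintf("da_disc_mod%d", o), ld),
        .hist_tbl("phase2", ep, sprintf("da_confusion_mod%d", o), lc))
  }
  list(bundle = bundle, history = dplyr::bind_rows(hist))
}

#' Phase 3: multi-omics adversarial alignment
#'
#' Alternating updates of the shared discriminator and the shared extractor
#' G on the integrated latents (per-modality extractors frozen). Skipped
#' under `ablation` `"no_at_multi"` or `"no_at_all"`.
#'
#' @inheritParams phase2_single_omics_da
#' @return list(bundle, history).
#' @export
phase3_multi_omics_da <- function(bundle, source, target, config) {
  if (config$ablation %in% c("no_at_multi", "no_at_all"))
    return(list(bundle = bundle, history = .hist_tbl(character(), integer(),
                                                     character(), numeric())))
  Xs <- dataset_values(source); Xt <- dataset_values(target)
  n_s <- n_samples(source); n_t <- n_samples(target)
  n <- n_s + n_t
  Dlab <- one_hot(c(rep(1L, n_s), rep(2L, n_t)), 2L)
  # F is frozen here: precompute pooled concatenated embeddings once
  Z <- do.call(cbind, lapply(seq_len(bundle$n_modalities), function(o)
    nn_forward(bundle$F[[o]], rbind(Xs[[o]], Xt[[o]]), training = FALSE)$out))
  stD <- adam_new(); stG <- adam_new()
  ep <- seq_len(config$epochs_phase3)
  ld <- lc <- numeric(length(ep))
  for (t in ep) {
    ld_b <- lc_b <- 0
    for (idx in .batches(n, config$batch_size)) {
      Db <- Dlab[idx, , drop = FALSE]
      fG <- nn_forward(bundle$G, Z[idx, , drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
      bundle$G <- fG$net
      fD <- nn_forward(bundle$D_shared, fG$out, training = TRUE, keep_cache = TRUE)
      bundle$D_shared <- fD$net
      P <- softmax(fD$out)
      ld_c <- domain_discriminator_loss(P, Db)
      ld_b <- ld_b + ld_c * length(idx)
      lc_b <- lc_b - ld_c * length(idx)
      dlog <- (P - Db) / length(idx)
      bD <- nn_backward(bundle$D_shared, fD$cache, dlog, input_grad = TRUE)
      bG <- nn_backward(bundle$G, fG$cache, -bD$d_input, input_grad = FALSE)
      r <- adam_step(bundle$D_shared, bD$grads, stD, config$lr_discriminator)
      bundle$D_shared <- r$net; stD <- r$state
      r <- adam_step(bundle$G, bG$grads, stG, config$lr_extractor)
      bundle$G <- r$net; stG <- r$state
    }
    ld[t] <- ld_b / n; lc[t] <- lc_b / n
  }
  hist <- if (length(ep)) dplyr::bind_rows(
    .hist_tbl("phase3", ep, "da_disc_shared", ld),
    .hist_tbl("phase3", ep, "da_confusion_shared", lc))
  else .hist_tbl(character(), integer(), character(), numeric())
  list(bundle = bundle, history = hist)
}

# ---- phase 4 --------------------------------------------------------------

#' Phase 4: semi-supervised class alignment
#'
#' Each epoch recomputes target posteriors through the current model,
#' assigns pseudo-labels (posterior argmax, optional confidence threshold),
#' and takes one joint Adam step on F, G and C_multi minimizing the
#' semi-supervised loss plus `centroid_weight` times the class-level
#' centroid alignment loss. Discriminators are frozen.
#'
#' @inheritParams phase2_single_omics_da
#' @return list(bundle, history).
#' @export
phase4_semi_supervised <- function(bundle, source, target, config) {
  if (is.null(source$labels)) stop("phase 4 requires a labeled source dataset")
  Xs <- dataset_values(source); Xt <- dataset_values(target)
  n_s <- n_samples(source); n_t <- n_samples(target)
  n <- n_s + n_t
  O <- bundle$n_modalities
  K <- bundle$n_classes
  Xp <- lapply(seq_len(O), function(o) rbind(Xs[[o]], Xt[[o]]))
  Y_s <- one_hot(source$labels, K)
  dom <- c(rep(1L, n_s), rep(2L, n_t))
  lam <- config$centroid_weight
  stF <- lapply(seq_len(O), function(o) adam_new())
  stG <- adam_new(); stC <- adam_new()
  ep <- seq_len(config$epochs_phase4)
  l_ssl <- l_cen <- l_alpha <- numeric(length(ep))
  for (t in ep) {
    a <- alpha_schedule(t, config$schedule)
    ssl_b <- cen_b <- 0
    for (idx in .batches(n, config$batch_size)) {
      src_in <- idx[idx <= n_s]
      tgt_in <- idx[idx > n_s]
      fF <- vector("list", O)
      for (o in seq_len(O)) {
        fF[[o]] <- nn_forward(bundle$F[[o]], Xp[[o]][idx, , drop = FALSE],
                              training = TRUE, keep_cache = TRUE)
        bundle$F[[o]] <- fF[[o]]$net
      }
      Z <- do.call(cbind, lapply(fF, `[[`, "out"))
      fG <- nn_forward(bundle$G, Z, training = TRUE, keep_cache = TRUE)
      bundle$G <- fG$net
      fC <- nn_forward(bundle$C_multi, fG$out, training = TRUE, keep_cache = TRUE)
      bundle$C_multi <- fC$net
      P <- softmax(fC$out)
      is_src <- idx <= n_s
      P_s <- P[is_src, , drop = FALSE]
      P_t <- P[!is_src, , drop = FALSE]
      Yb_s <- Y_s[src_in, , drop = FALSE]
      pl <- assign_pseudo_labels(P_t, config$confidence_threshold)
      Y_t <- one_hot(pl$labels, K)
      nb_s <- nrow(P_s); nb_t <- nrow(P_t); nk <- sum(pl$keep)
      # semi-supervised loss and its logit gradient
      lv <- ssl_loss(P_s, Yb_s, P_t, Y_t, pl$keep, t, config$schedule)
      ssl_b <- ssl_b + lv * length(idx)
      dlog <- matrix(0, length(idx), K)
      if (nb_s > 0) dlog[is_src, ] <- (P_s - Yb_s) / nb_s
      if (a > 0 && nk > 0) {
        dt <- matrix(0, nb_t, K)
        dt[pl$keep, ] <- a * (P_t[pl$keep, , drop = FALSE] -
                                Y_t[pl$keep, , drop = FALSE]) / nk
        dlog[!is_src, ] <- dt
      }
      bC <- nn_backward(bundle$C_multi, fC$cache, dlog, input_grad = TRUE)
      d_lat <- bC$d_input
      # centroid alignment on the integrated latent; target side uses the
      # kept pseudo-labels, source side the true labels
      cls <- integer(length(idx))
      cls[is_src] <- source$labels[src_in]
      cls[!is_src] <- pl$labels
      use <- is_src | c(rep(FALSE, nb_s), pl$keep)
      if (lam > 0 && any(use)) {
        lat <- fG$out[use, , drop = FALSE]
        cl_u <- cls[use]; dm_u <- dom[idx][use]
        present <- sort(unique(cl_u))
        cen <- suppressWarnings(
          centroid_alignment_loss(lat, cl_u, dm_u, K, 2L))
        cen_b <- cen_b + cen * length(idx)
        gc_ <- centroid_alignment_grad(lat, cl_u, dm_u, K, 2L)
        d_lat[use, ] <- d_lat[use, , drop = FALSE] + lam * gc_
      }
      bG <- nn_backward(bundle$G, fG$cache, d_lat, input_grad = TRUE)
      col0 <- 0L
      for (o in seq_len(O)) {
        cols <- (col0 + 1L):(col0 + SINGLE_LATENT_DIM)
        bF <- nn_backward(bundle$F[[o]], fF[[o]]$cache,
                          bG$d_input[, cols, drop = FALSE], input_grad = FALSE)
        r <- adam_step(bundle$F[[o]], bF$grads, stF[[o]], config$lr_extractor)
        bundle$F[[o]] <- r$net; stF[[o]] <- r$state
        col0 <- col0 + SINGLE_LATENT_DIM
      }
      r <- adam_step(bundle$G, bG$grads, stG, config$lr_extractor)
      bundle$G <- r$net; stG <- r$state
      r <- adam_step(bundle$C_multi, bC$grads, stC, config$lr_classifier)
      bundle$C_multi <- r$net; stC <- r$state
    }
    l_ssl[t] <- ssl_b / n; l_cen[t] <- cen_b / n; l_alpha[t] <- a
  }
  hist <- if (length(ep)) dplyr::bind_rows(
    .hist_tbl("phase4", ep, "ssl", l_ssl),
    .hist_tbl("phase4", ep, "centroid", l_cen),
    .hist_tbl("phase4", ep, "alpha", l_alpha))
  else .hist_tbl(character(), integer(), character(), numeric())
  list(bundle = bundle, history = hist)
}

# ---- fit / predict --------------------------------------------------------

#' Fit the full four-phase model
#'
#' Runs pre-training, single-omics adversarial adaptation, multi-omics
#' adversarial alignment and semi-supervised class alignment in sequence,
#' honoring the `ablation` switch in `config`. Fully reproducible given
#' `config$seed`.
#'
#' @param source labeled source `multiomics_dataset`.
#' @param target unlabeled target `multiomics_dataset` whose per-modality
#'   feature spaces match the source.
#' @param config a [train_config()].
#' @return object of class `modamix_fit` with elements `bundle`, `history`
#'   (tibble: phase, epoch, loss, value), `config`, `class_names`.
#' @export
fit_modamix <- function(source, target, config = train_config()) {
  stopifnot(inherits(source, "multiomics_dataset"),
            inherits(target, "multiomics_dataset"))
  if (length(source$matrices) != length(target$matrices))
    stop("source and target must have the same number of modalities")
  for (o in seq_along(source$matrices)) {
    if (!identical(source$matrices[[o]]$feature_ids,
                   target$matrices[[o]]$feature_ids))
      stop(sprintf("feature space mismatch in modality %d ('%s')",
                   o, source$matrices[[o]]$modality))
  }
  if (is.null(source$labels)) stop("source dataset must be labeled")
  feature_dims <- vapply(source$matrices, function(m) ncol(m$values), 1L)
  K <- length(source$class_names)
  bundle <- build_bundle(feature_dims, K, config)  # seeds the RNG
  p1 <- phase1_pretrain(bundle, source, config)
  p2 <- phase2_single_omics_da(p1$bundle, source, target, config)
  p3 <- phase3_multi_omics_da(p2$bundle, source, target, config)
  p4 <- phase4_semi_supervised(p3$bundle, source, target, config)
  bundle <- p4$bundle
  history <- dplyr::bind_rows(p1$history, p2$history, p3$history, p4$history)
  fit <- structure(list(bundle = bundle, history = history, config = config,
                        class_names = source$class_names),
                   class = "modamix_fit")
  src_res <- predict(fit, source)
  fit$history <- dplyr::bind_rows(
    history,
    .hist_tbl("final", 1L, "final_source_accuracy",
              mean(src_res$predicted_labels == source$labels)))
  fit
}

#' @export
print.modamix_fit <- function(x, ...) {
  acc <- dplyr::filter(x$history, .data$loss == "final_source_accuracy")$value
  cat(sprintf("<modamix_fit> K = %d classes, O = %d modalities; ablation = %s\n",
              x$bundle$n_classes, x$bundle$n_modalities, x$config$ablation))
  if (length(acc)) cat(sprintf("  final source accuracy: %.3f\n", acc))
  invisible(x)
}

#' Integrated latent representation of a dataset
#'
#' Inference-mode pass through the per-modality extractors and the shared
#' extractor (batch normalization uses running statistics).
#'
#' @param bundle a trained `modamix_bundle`.
#' @param dataset a `multiomics_dataset`.
#' @return n x 256 latent matrix.
#' @export
integrated_latent <- function(bundle, dataset) {
  forward_integrated(bundle, dataset_values(dataset), training = FALSE)
}

#' Predict labels and embeddings for a dataset
#'
#' @param object a `modamix_fit`.
#' @param dataset a `multiomics_dataset` with the fit's feature spaces.
#' @param ... unused.
#' @return an [embedding_result()] with integrated latents, class
#'   posteriors from the integrated classifier head, and argmax labels.
#' @export
predict.modamix_fit <- function(object, dataset, ...) {
  bundle <- object$bundle
  lat <- integrated_latent(bundle, dataset)
  post <- classify(bundle$C_multi, lat)
  embedding_result(lat, post, sample_ids = dataset$sample_ids,
                   domain = dataset$domain, class_names = object$class_names)
}

# ---- probe discriminator (evaluation utility) -----------------------------

#' Probe domain-discriminator accuracy
#'
#' Fits a ridge-regularized logistic regression (fixed small penalty) to
#' separate source from target rows of a representation and reports seeded
#' 5-fold cross-validated accuracy. Used to quantify how much domain signal
#' a representation still carries (0.5 = fully mixed).
#'
#' @param latent_source,latent_target representation matrices.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return scalar CV accuracy in \[0, 1\].
#' @export
probe_domain_accuracy <- function(latent_source, latent_target, folds = 5L,
                                  seed = 1L) {
  X <- rbind(latent_source, latent_target)
  y <- c(rep(0L, nrow(latent_source)), rep(1L, nrow(latent_target)))
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = 1e-3, standardize = TRUE)
    p <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
    correct <- correct + sum((p > 0.5) == (y[!tr] == 1L))
  }
  correct / n
}
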