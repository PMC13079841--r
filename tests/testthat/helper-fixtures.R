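# Small shared fixtures and a memoized cache for the expensive full-pipeline
# runs, so the recovery, mixing and ablation checks reuse the same fits.

tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_source = 60L, n_target = 60L, K = 2L, O = 2L, m = c(25L, 25L),
    latent_signal_dim = 4L, class_separation = 6, batch_shift = 1,
    batch_scale = 0.05, noise_sd = 1, seed = seed), list(...))
  do.call(sim_spec, args)
}

tiny_config <- function(seed = 1L, epochs = 5L, ...) {
  args <- utils::modifyList(list(
    epochs_phase1 = epochs, epochs_phase2 = epochs, epochs_phase3 = epochs,
    epochs_phase4 = epochs, seed = seed), list(...))
  do.call(train_config, args)
}

small_omics <- function(values, domain = "source", modality = "omics",
                        prefix = "s") {
  omics_matrix(values,
               sample_ids = sprintf("%s%03d", prefix, seq_len(nrow(values))),
               feature_ids = sprintf("f%03d", seq_len(ncol(values))),
               modality = modality, domain = domain)
}

# ---- memoized full-pipeline runs -----------------------------------------

.run_cache <- new.env(parent = emptyenv())

# Full four-phase run on the "easy" benchmark at the reduced-epoch protocol
# (100/100/100/200), returning target accuracy and probe accuracies after
# phases 1 and 3. Memoized per seed.
easy_run <- function(seed) {
  key <- paste0("easy_", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  fx <- make_fixture("easy", seed = seed)
  cfg <- train_config(epochs_phase1 = 100L, epochs_phase2 = 100L,
                      epochs_phase3 = 100L, epochs_phase4 = 200L, seed = seed)
  bundle <- build_bundle(vapply(fx$source$matrices, function(m) ncol(m$values), 1L),
                         length(fx$class_names), cfg)
  p1 <- phase1_pretrain(bundle, fx$source, cfg)
  probe1 <- probe_domain_accuracy(integrated_latent(p1$bundle, fx$source),
                                  integrated_latent(p1$bundle, fx$target),
                                  seed = 1L)
  p2 <- phase2_single_omics_da(p1$bundle, fx$source, fx$target, cfg)
  p3 <- phase3_multi_omics_da(p2$bundle, fx$source, fx$target, cfg)
  probe3 <- probe_domain_accuracy(integrated_latent(p3$bundle, fx$source),
                                  integrated_latent(p3$bundle, fx$target),
                                  seed = 1L)
  p4 <- phase4_semi_supervised(p3$bundle, fx$source, fx$target, cfg)
  fit <- structure(list(bundle = p4$bundle,
                        history = dplyr::bind_rows(p1$history, p2$history,
                                                   p3$history, p4$history),
                        config = cfg, class_names = fx$class_names),
                   class = "modamix_fit")
  pred <- predict(fit, fx$target)
  probe_final <- probe_domain_accuracy(integrated_latent(p4$bundle, fx$source),
                                       pred$latent, seed = 1L)
  out <- list(accuracy = mean(pred$predicted_labels == fx$truth),
              probe_phase1 = probe1, probe_phase3 = probe3,
              probe_final = probe_final, result = pred, truth = fx$truth)
  .run_cache[[key]] <- out
  out
}

# Ablation run on the "hard" benchmark (batch shift >> class separation) at a
# reduced-epoch protocol; returns the pred-mode target silhouette. Memoized.
hard_run <- function(seed, ablation) {
  key <- paste0("hard_", seed, "_", ablation)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  fx <- make_fixture("hard", seed = seed)
  cfg <- train_config(epochs_phase1 = 30L, epochs_phase2 = 30L,
                      epochs_phase3 = 30L, epochs_phase4 = 210L,
                      seed = seed, ablation = ablation)
  fit <- fit_modamix(fx$source, fx$target, cfg)
  pred <- predict(fit, fx$target)
  sil <- if (length(unique(pred$predicted_labels)) < 2L) NA_real_
         else silhouette_score(pred$latent, pred$predicted_labels)
  out <- list(silhouette = sil, accuracy = mean(pred$predicted_labels == fx$truth))
  .run_cache[[key]] <- out
  out
}
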