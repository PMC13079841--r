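# Model bundle: the parametric maps of the staged domain-adaptation model.
#
# Per modality o: feature extractor F^(o): m_o -> 1024 -> 512 (both hidden,
# batch-norm + LeakyReLU; the 512-unit activation is the modality latent).
# Shared extractor G: (O*512) -> 512 -> 256. Classifier heads (one per
# single-omics attachment point plus one on the integrated latent):
# latent -> 128 -> 64 -> K logits, softmax at the output. Domain
# discriminators: latent -> 256 -> 64 -> 2 logits, softmax.

SINGLE_LATENT_DIM <- 512L
SHARED_LATENT_DIM <- 256L

#' Build the model bundle
#'
#' Constructs all parametric maps (per-modality extractors, shared extractor,
#' classifier heads, domain discriminators) with freshly initialized, seeded
#' weights. Layer widths are fixed by the model architecture: 1024/512 for the
#' single-omics extractors, 512/256 for the shared extractor, 128/64 for every
#' classifier head, 256/64 for every discriminator.
#'
#' @param feature_dims integer vector of length O, features per modality.
#' @param n_classes number of classes K (>= 2).
#' @param config a [train_config()] list; `seed` and `leaky_slope` are used.
#' @return an object of class `modamix_bundle`.
#' @export
build_bundle <- function(feature_dims, n_classes, config = train_config()) {
  feature_dims <- as.integer(feature_dims)
  stopifnot(length(feature_dims) >= 1L, all(feature_dims >= 1L))
  if (n_classes < 2) stop("n_classes must be >= 2")
  slope <- config$leaky_slope %||% 0.01
  set.seed(config$seed)
  O <- length(feature_dims)
  F_nets <- lapply(feature_dims, function(m)
    nn_init_mlp(m, c(1024L, 512L), out_dim = NULL, slope = slope))
  G_net <- nn_init_mlp(O * SINGLE_LATENT_DIM, c(512L, 256L), out_dim = NULL, slope = slope)
  C_single <- lapply(seq_len(O), function(o)
    nn_init_mlp(SINGLE_LATENT_DIM, c(128L, 64L), out_dim = n_classes, slope = slope))
  C_multi <- nn_init_mlp(SHARED_LATENT_DIM, c(128L, 64L), out_dim = n_classes, slope = slope)
  D_single <- lapply(seq_len(O), function(o)
    nn_init_mlp(SINGLE_LATENT_DIM, c(256L, 64L), out_dim = 2L, slope = slope))
  D_shared <- nn_init_mlp(SHARED_LATENT_DIM, c(256L, 64L), out_dim = 2L, slope = slope)
  structure(list(
    F = F_nets, G = G_net, C_single = C_single, C_multi = C_multi,
    D_single = D_single, D_shared = D_shared,
    feature_dims = feature_dims, n_classes = as.integer(n_classes),
    n_modalities = O, latent_dim = SHARED_LATENT_DIM, seed = config$seed
  ), class = "modamix_bundle")
}

#' Single-omics latent representation
#'
#' Passes one modality's matrix through its feature extractor. In inference
#' mode (`training = FALSE`, the default) batch normalization uses running
#' statistics, so the map is deterministic.
#'
#' @param bundle a `modamix_bundle`.
#' @param o modality index.
#' @param X numeric matrix, samples in rows.
#' @param training logical; use batch statistics and update running stats.
#' @return n x 512 latent matrix.
#' @export
forward_single <- function(bundle, o, X, training = FALSE) {
  stopifnot(o >= 1, o <= bundle$n_modalities)
  if (ncol(X) != bundle$feature_dims[o])
    stop(sprintf("modality %d expects %d features, got %d",
                 o, bundle$feature_dims[o], ncol(X)))
  nn_forward(bundle$F[[o]], X, training = training)$out
}

#' Integrated multi-omics latent representation
#'
#' Concatenates the per-modality latents and passes them through the shared
#' extractor G.
#'
#' @param bundle a `modamix_bundle`.
#' @param X_list list of O matrices with equal row counts.
#' @param training logical, as in [forward_single()].
#' @return n x 256 integrated latent matrix.
#' @export
forward_integrated <- function(bundle, X_list, training = FALSE) {
  stopifnot(length(X_list) == bundle$n_modalities)
  ns <- vapply(X_list, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("all modalities must have the same number of samples")
  Z <- do.call(cbind, lapply(seq_along(X_list), function(o)
    forward_single(bundle, o, X_list[[o]], training = training)))
  nn_forward(bundle$G, Z, training = training)$out
}

#' Class posteriors from a classifier head
#'
#' @param head a classifier network (e.g. `bundle$C_multi`).
#' @param latent latent matrix whose column count matches the head input.
#' @return n x K row-stochastic posterior matrix.
#' @export
classify <- function(head, latent) {
  if (ncol(latent) != head$input_dim)
    stop(sprintf("head expects %d-dimensional latents, got %d",
                 head$input_dim, ncol(latent)))
  softmax(nn_forward(head, latent, training = FALSE)$out)
}

#' Total parameter count of a bundle component
#'
#' @param net a network as stored in a `modamix_bundle` (class `nn_mlp`).
#' @return integer parameter count (weights, biases, batch-norm scale/shift).
#' @export
n_parameters <- function(net) nn_n_params(net)

#' @export
print.modamix_bundle <- function(x, ...) {
  cat(sprintf("<modamix_bundle> O = %d modalities, K = %d classes\n",
              x$n_modalities, x$n_classes))
  cat(sprintf("  feature dims: %s; latent dim: %d\n",
              paste(x$feature_dims, collapse = ", "), x$latent_dim))
  invisible(x)
}

# ---- checkpoint serialization --------------------------------------------

#' Save / load a model bundle checkpoint
#'
#' The checkpoint stores all parameters together with an architecture
#' manifest (feature dims, class count, modality count); loading validates
#' the manifest.
#'
#' @param bundle a `modamix_bundle`.
#' @param path file path for the checkpoint.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "modamix_bundle"))
  saveRDS(list(manifest = list(feature_dims = bundle$feature_dims,
                               n_classes = bundle$n_classes,
                               n_modalities = bundle$n_modalities,
                               latent_dim = bundle$latent_dim),
               bundle = unclass(bundle)), path)
  invisible(path)
}

#' @rdname save_bundle
#' @param path file path of an existing checkpoint.
#' @param expect optional list with any of `feature_dims`, `n_classes` to
#'   validate against the stored manifest.
#' @export
load_bundle <- function(path, expect = NULL) {
  x <- readRDS(path)
  if (is.null(x$manifest) || is.null(x$bundle)) stop("not a bundle checkpoint: ", path)
  man <- x$manifest
  if (!is.null(expect$feature_dims) &&
      !identical(as.integer(expect$feature_dims), as.integer(man$feature_dims)))
    stop("checkpoint feature_dims do not match expectation")
  if (!is.null(expect$n_classes) && expect$n_classes != man$n_classes)
    stop("checkpoint n_classes does not match expectation")
  structure(x$bundle, class = "modamix_bundle")
}
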