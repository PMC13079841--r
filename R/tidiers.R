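# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a fitted model's training history
#'
#' @param x a `modamix_fit`.
#' @param ... unused.
#' @return tibble with columns `phase`, `epoch`, `loss`, `value` (one row
#'   per recorded loss term per epoch per phase).
#' @exportS3Method generics::tidy
tidy.modamix_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x a `modamix_fit`.
#' @param ... unused.
#' @return tibble with class/modality counts, ablation setting, total epochs
#'   and final source accuracy.
#' @exportS3Method generics::glance
glance.modamix_fit <- function(x, ...) {
  acc <- dplyr::filter(x$history, .data$loss == "final_source_accuracy")$value
  tibble::tibble(
    n_classes = x$bundle$n_classes,
    n_modalities = x$bundle$n_modalities,
    latent_dim = x$bundle$latent_dim,
    ablation = x$config$ablation,
    epochs_total = x$config$epochs_phase1 + x$config$epochs_phase2 +
      x$config$epochs_phase3 + x$config$epochs_phase4,
    seed = x$config$seed,
    final_source_accuracy = if (length(acc)) acc else NA_real_)
}

#' Plot training loss curves
#'
#' One panel per phase, one line per recorded loss term.
#'
#' @param object a `modamix_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.modamix_fit <- function(object, ...) {
  df <- dplyr::filter(object$history, .data$phase != "final")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase), scales = "free") +
    ggplot2::labs(x = "epoch", y = "loss / metric value") +
    ggplot2::theme_minimal()
}

#' Plot an integrated embedding
#'
#' Projects the latent coordinates onto their first two principal components
#' and colors samples by predicted class.
#'
#' @param object an `embedding_result`.
#' @param labels optional vector overriding the point coloring (e.g. true
#'   labels or domain tags).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.embedding_result <- function(object, labels = NULL, ...) {
  pc <- stats::prcomp(object$latent, rank. = 2L)
  lab <- labels %||% (
    if (is.null(object$class_names)) as.character(object$predicted_labels)
    else object$class_names[object$predicted_labels])
  df <- tibble::tibble(PC1 = pc$x[, 1L], PC2 = pc$x[, 2L],
                       label = as.character(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.2) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}
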