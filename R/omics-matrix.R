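# Data model: one modality's sample-by-feature matrix, the sample-aligned
# multi-omics dataset for one domain, and the integrated embedding result.
# Matrices travel as plain delimited text (tab or comma) with one header row
# and one ID column.

#' Construct an omics matrix
#'
#' A single modality's numeric sample-by-feature matrix with sample and
#' feature identifiers, a modality tag, a domain tag (`"source"` or
#' `"target"`), and a missingness mask. Values must be finite wherever not
#' flagged missing; IDs must be unique.
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids,feature_ids character vectors naming rows and columns.
#' @param modality free-form modality tag (e.g. `"rna"`, `"meth"`).
#' @param domain `"source"` or `"target"`.
#' @param missing_mask logical matrix of the same shape; `TRUE` = missing.
#' @return object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         modality = "omics", domain = c("source", "target"),
                         missing_mask = NULL) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample_ids and feature_ids are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("omics_matrix needs at least one sample and one feature")
  stopifnot(length(sample_ids) == nrow(values),
            length(feature_ids) == ncol(values))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample_ids: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f))
    stop("duplicate feature_ids: ", paste(dup_f, collapse = ", "))
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)
    stopifnot(is.logical(missing_mask), all(dim(missing_mask) == dim(values)))
  }
  if (any(!is.finite(values[!missing_mask])))
    stop("non-finite values outside the missing mask")
  dimnames(values) <- list(sample_ids, feature_ids)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, modality = modality,
                 domain = domain, missing_mask = missing_mask),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s/%s: %d samples x %d features (%d missing cells)\n",
              x$modality, x$domain, nrow(x$values), ncol(x$values),
              sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

#' Read a delimited omics matrix
#'
#' Reads a tab- or comma-delimited text matrix (delimiter auto-detected from
#' the header row) with one header row and one leading ID column. Cells that
#' are empty, `NA` or `NaN` are flagged in the missing mask; any other
#' non-numeric cell is a parse error reported with its row and column.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (ID column = sample IDs, header =
#'   feature IDs) or `"features_in_rows"` (the transpose layout).
#' @param modality,domain tags passed to [omics_matrix()].
#' @return an `omics_matrix`, always samples-in-rows internally.
#' @export
read_omics_matrix <- function(path, orientation = c("samples_in_rows", "features_in_rows"),
                              modality = "omics", domain = c("source", "target")) {
  orientation <- match.arg(orientation)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          na = character(), progress = FALSE,
                          show_col_types = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an ID column and at least one data column")
  row_ids <- as.character(df[[1L]])
  col_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  miss <- raw == "" | raw == "NA" | raw == "NaN" | is.na(raw)
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop(sprintf("non-numeric cell '%s' at row %d (%s), column %d (%s) in %s",
                 raw[b[1L], b[2L]], b[1L], row_ids[b[1L]], b[2L], col_ids[b[2L]], path))
  }
  num[miss] <- NA_real_
  if (orientation == "features_in_rows") {
    num <- t(num); miss <- t(miss)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  omics_matrix(num, sample_ids = row_ids, feature_ids = col_ids,
               modality = modality, domain = domain, missing_mask = miss)
}

#' Write an omics matrix as delimited text
#'
#' Samples-in-rows layout with a `sample_id` ID column; missing cells are
#' written as `NA`. Values round-trip through [read_omics_matrix()] to within
#' 1e-9.
#'
#' @param x an `omics_matrix`.
#' @param path output file path.
#' @param delim field delimiter.
#' @export
write_omics_matrix <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "omics_matrix"))
  .write_matrix(x$values, x$sample_ids, x$feature_ids, path, delim,
                mask = x$missing_mask)
  invisible(path)
}

.fmt_num <- function(v) {
  out <- sprintf("%.12g", v)
  out[is.na(v)] <- "NA"
  out
}

.write_matrix <- function(values, row_ids, col_ids, path, delim = "\t",
                          id_col = "sample_id", mask = NULL) {
  vals <- values
  if (!is.null(mask)) vals[mask] <- NA_real_
  lines <- character(nrow(vals) + 1L)
  lines[1L] <- paste(c(id_col, col_ids), collapse = delim)
  body <- apply(vals, 1L, function(r) paste(.fmt_num(r), collapse = delim))
  lines[-1L] <- paste(row_ids, body, sep = delim)
  writeLines(lines, path)
}

# ---- multi-omics dataset -------------------------------------------------

#' Assemble a sample-aligned multi-omics dataset
#'
#' Aligns a list of `omics_matrix` objects (one per modality, same domain) on
#' the intersection of their sample IDs, in the order of the first matrix.
#' Samples lacking any modality are dropped with a message reporting the
#' count. An optional label table (columns `sample_id`, `class`) attaches
#' class labels; labels are stored as 1-based indices with a class-name
#' vector. Labels referencing unknown samples are dropped with a warning.
#'
#' @param matrices list of `omics_matrix` objects sharing a domain tag.
#' @param labels optional data frame with columns `sample_id` and `class`,
#'   or a named character vector.
#' @param class_names optional explicit class-name ordering; defaults to the
#'   sorted unique class names in `labels`.
#' @return object of class `multiomics_dataset`.
#' @export
assemble_dataset <- function(matrices, labels = NULL, class_names = NULL) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "omics_matrix")))
  domains <- unique(vapply(matrices, function(m) m$domain, ""))
  if (length(domains) != 1L)
    stop("all matrices must share one domain tag, got: ",
         paste(domains, collapse = ", "))
  ids <- matrices[[1L]]$sample_ids
  for (m in matrices[-1L]) ids <- ids[ids %in% m$sample_ids]
  if (length(ids) == 0L) stop("no samples shared across all modalities")
  total_dropped <- sum(vapply(matrices, function(m)
    sum(!(m$sample_ids %in% ids)), 1L))
  if (total_dropped > 0L)
    message(sprintf("assemble_dataset: dropped %d sample entries not shared across all modalities (n = %d kept)",
                    total_dropped, length(ids)))
  aligned <- lapply(matrices, function(m) {
    idx <- match(ids, m$sample_ids)
    omics_matrix(m$values[idx, , drop = FALSE], sample_ids = ids,
                 feature_ids = m$feature_ids, modality = m$modality,
                 domain = m$domain,
                 missing_mask = m$missing_mask[idx, , drop = FALSE])
  })
  lab_idx <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      stopifnot(ncol(labels) >= 2L)
      lab_tab <- stats::setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
    } else {
      lab_tab <- stats::setNames(as.character(labels), names(labels))
    }
    unknown <- setdiff(names(lab_tab), ids)
    if (length(unknown))
      warning(sprintf("dropping %d label(s) for unknown samples: %s",
                      length(unknown), paste(utils::head(unknown, 5L), collapse = ", ")))
    lab_tab <- lab_tab[names(lab_tab) %in% ids]
    missing_lab <- setdiff(ids, names(lab_tab))
    if (length(missing_lab))
      stop("labels missing for samples: ", paste(utils::head(missing_lab, 5L), collapse = ", "))
    if (is.null(class_names)) class_names <- sort(unique(unname(lab_tab)))
    lab_idx <- match(lab_tab[ids], class_names)
    if (anyNA(lab_idx)) stop("label values outside class_names")
  }
  structure(list(matrices = aligned, labels = lab_idx,
                 class_names = class_names, domain = domains,
                 sample_ids = ids),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %s: n = %d samples, O = %d modalities (%s)%s\n",
              x$domain, length(x$sample_ids), length(x$matrices),
              paste(vapply(x$matrices, function(m) m$modality, ""), collapse = ", "),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", K = %d classes", length(x$class_names))))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds a `multiomics_dataset`.
#' @export
n_samples <- function(ds) length(ds$sample_ids)

# Values of all modalities as a list of matrices; refuses missingness
# (only methylation matrices prior to imputation may carry missing cells).
#' @noRd
dataset_values <- function(ds) {
  lapply(ds$matrices, function(m) {
    if (any(m$missing_mask))
      stop(sprintf("modality '%s' still contains %d missing cells; impute before training",
                   m$modality, sum(m$missing_mask)))
    m$values
  })
}

# ---- embedding result ----------------------------------------------------

#' Construct an embedding result
#'
#' Integrated latent coordinates plus class posteriors for one dataset.
#' Predicted labels are the posterior argmax (ties toward the lowest class
#' index); posterior rows must sum to 1 within 1e-6.
#'
#' @param latent n x d numeric matrix.
#' @param posteriors n x K row-stochastic matrix.
#' @param sample_ids character vector of length n.
#' @param domain `"source"` or `"target"`.
#' @param class_names optional K class names.
#' @return object of class `embedding_result`.
#' @export
embedding_result <- function(latent, posteriors, sample_ids,
                             domain = c("source", "target"), class_names = NULL) {
  domain <- match.arg(domain)
  latent <- as.matrix(latent); posteriors <- as.matrix(posteriors)
  if (nrow(latent) == 0L) stop("empty embedding result refused")
  stopifnot(nrow(latent) == nrow(posteriors),
            length(sample_ids) == nrow(latent))
  if (any(abs(rowSums(posteriors) - 1) > 1e-6))
    stop("posterior rows must sum to 1 (within 1e-6)")
  structure(list(latent = latent, posteriors = posteriors,
                 predicted_labels = max.col(posteriors, ties.method = "first"),
                 sample_ids = as.character(sample_ids), domain = domain,
                 class_names = class_names),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %s: n = %d, latent dim = %d, K = %d\n",
              x$domain, nrow(x$latent), ncol(x$latent), ncol(x$posteriors)))
  invisible(x)
}

#' Write an embedding result to a directory
#'
#' Writes `latent.tsv`, `posteriors.tsv` and `predictions.tsv` (sample_id,
#' predicted_label) as tab-delimited text. Numeric values round-trip through
#' [read_embedding_result()] to within 1e-9.
#'
#' @param result an `embedding_result`.
#' @param out_dir output directory (created if absent).
#' @export
write_embedding_result <- function(result, out_dir) {
  stopifnot(inherits(result, "embedding_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix(result$latent, result$sample_ids,
                paste0("latent_", seq_len(ncol(result$latent))),
                file.path(out_dir, "latent.tsv"))
  .write_matrix(result$posteriors, result$sample_ids,
                if (is.null(result$class_names))
                  paste0("class_", seq_len(ncol(result$posteriors)))
                else result$class_names,
                file.path(out_dir, "posteriors.tsv"))
  pred <- if (is.null(result$class_names)) result$predicted_labels
          else result$class_names[result$predicted_labels]
  writeLines(c("sample_id\tpredicted_label",
               paste(result$sample_ids, pred, sep = "\t")),
             file.path(out_dir, "predictions.tsv"))
  invisible(out_dir)
}

#' @rdname write_embedding_result
#' @param domain domain tag to attach on re-read.
#' @export
read_embedding_result <- function(out_dir, domain = c("source", "target")) {
  domain <- match.arg(domain)
  lat <- read_omics_matrix(file.path(out_dir, "latent.tsv"), domain = domain)
  post <- read_omics_matrix(file.path(out_dir, "posteriors.tsv"), domain = domain)
  embedding_result(lat$values, post$values, sample_ids = lat$sample_ids,
                   domain = domain, class_names = post$feature_ids)
}
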