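#' Subject similarity layer
#'
#' One layer of the multilayer network: a symmetric subjects-by-subjects
#' matrix of edge weights with a zero diagonal.
#'
#' @param weights symmetric numeric matrix, zero diagonal.
#' @param subject_ids subject identifiers, one per row/column.
#' @param modality_id modality tag.
#' @return list of class `similarity_layer`.
#' @export
similarity_layer <- function(weights, subject_ids, modality_id) {
  weights <- as.matrix(weights)
  subject_ids <- as.character(subject_ids)
  stopifnot(nrow(weights) == ncol(weights),
            nrow(weights) == length(subject_ids))
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("similarity weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0))
    stop("similarity diagonal must be exactly zero")
  dimnames(weights) <- list(subject_ids, subject_ids)
  structure(list(modality_id = modality_id, subject_ids = subject_ids,
                 weights = weights),
            class = "similarity_layer")
}

#' @export
print.similarity_layer <- function(x, ...) {
  cat(sprintf("<similarity_layer '%s'> %d subjects, weight range [%.3f, %.3f]\n",
              x$modality_id, length(x$subject_ids),
              min(x$weights[upper.tri(x$weights)]),
              max(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Build a similarity layer by correlating subjects' feature vectors
#'
#' Edge weight between two subjects is the correlation of their feature
#' vectors within the modality; the diagonal is set to zero. Because
#' correlating features of mixed provenance is only meaningful after
#' per-feature normalization, tables not flagged as preprocessed are refused
#' (construct them via [preprocess_modality()], or set the flag explicitly
#' when the input is already on a common scale).
#'
#' @param table a preprocessed [modality_table()] with at least 2 features.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [similarity_layer()].
#' @export
build_similarity_layer <- function(table, method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "modality_table"))
  method <- match.arg(method)
  if (!table$preprocessed)
    stop("modality '", table$modality_id, "' is not flagged as preprocessed; ",
         "run preprocess_modality() first")
  if (length(table$subject_ids) < 3)
    stop("similarity network needs at least 3 subjects, got ",
         length(table$subject_ids))
  p <- length(table$features)
  if (p < 2)
    stop("pairwise correlation needs at least 2 features, got ", p)
  if (p < 3)
    warning("modality '", table$modality_id, "' has only ", p,
            " features; pairwise correlations over ", p,
            " values are degenerate (r = +/-1)")
  rowsd <- apply(table$values, 1, stats::sd)
  if (any(rowsd == 0))
    stop("zero-variance feature vector (correlation undefined) for subject(s): ",
         paste(table$subject_ids[rowsd == 0], collapse = ", "))
  w <- stats::cor(t(table$values), method = method)
  diag(w) <- 0
  similarity_layer(w, table$subject_ids, table$modality_id)
}

#' Map similarity weights to a nonnegative range
#'
#' Pairwise correlations are signed; the multilayer modularity core accepts
#' signed weights directly (`keep_signed`, the default), but classical
#' nonnegative graphs can be obtained by clipping negative weights at zero
#' (`clip_negative`) or by the affine map `(w + 1) / 2` applied off-diagonal
#' (`shift_rescale`). Symmetry and the zero diagonal are preserved.
#'
#' @param layer a [similarity_layer()].
#' @param mode one of `"keep_signed"`, `"clip_negative"`, `"shift_rescale"`.
#' @return A [similarity_layer()].
#' @export
sanitize_layer <- function(layer,
                           mode = c("keep_signed", "clip_negative", "shift_rescale")) {
  stopifnot(inherits(layer, "similarity_layer"))
  mode <- match.arg(mode)
  w <- layer$weights
  if (mode == "clip_negative") {
    w <- pmax(w, 0)
  } else if (mode == "shift_rescale") {
    w <- (w + 1) / 2
    diag(w) <- 0
  }
  similarity_layer(w, layer$subject_ids, layer$modality_id)
}

#' Write a similarity layer as a dense CSV matrix
#'
#' @param layer a [similarity_layer()].
#' @param path output path; subject IDs become the header and first column.
#' @return `path`, invisibly.
#' @export
write_similarity_layer <- function(layer, path) {
  df <- data.frame(subject_id = layer$subject_ids, check.names = FALSE)
  for (j in seq_along(layer$subject_ids))
    df[[layer$subject_ids[j]]] <- sprintf("%.17g", layer$weights[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
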