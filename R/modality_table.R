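#' Modality table: subjects-by-features matrix for one data modality
#'
#' The basic container for one modality's measurements: a numeric matrix with
#' one row per subject and one column per feature, tagged with a modality
#' identifier. Rows are identified by unique subject IDs; columns by feature
#' names. Units are modality specific (mm^3 volumes, SUVRs, pg/mL analyte
#' concentrations, test scores, allele counts).
#'
#' @param values numeric matrix, `n_subjects x n_features`.
#' @param subject_ids character vector of unique subject identifiers, one per
#'   row of `values`.
#' @param features character vector of feature names, one per column.
#' @param modality_id one of `"mri"`, `"pet"`, `"csf"`, `"cognition"`,
#'   `"genetics"`.
#' @param preprocessed logical flag; set by [preprocess_modality()] so that
#'   downstream steps can refuse raw tables.
#'
#' @return An object of class `modality_table`: a list with elements
#'   `modality_id`, `subject_ids`, `features`, `values` (matrix with dimnames)
#'   and attribute-like field `preprocessed`.
#' @export
modality_table <- function(values, subject_ids, features,
                           modality_id = c("mri", "pet", "csf", "cognition", "genetics"),
                           preprocessed = FALSE) {
  modality_id <- match.arg(modality_id)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subject_ids <- as.character(subject_ids)
  features <- as.character(features)
  if (nrow(values) != length(subject_ids))
    stop("number of rows of 'values' must match length of 'subject_ids'")
  if (ncol(values) != length(features))
    stop("number of columns of 'values' must match length of 'features'")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject IDs: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (nrow(values) < 1)
    stop("a modality table needs at least 1 subject")
  if (ncol(values) < 1)
    stop("a modality table needs at least 1 feature")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    stop("missing values in modality '", modality_id, "' at (row, column): ",
         paste(sprintf("(%s, %s)", subject_ids[idx[, 1]], features[idx[, 2]]),
               collapse = ", "))
  }
  dimnames(values) <- list(subject_ids, features)
  structure(
    list(modality_id = modality_id,
         subject_ids = subject_ids,
         features = features,
         values = values,
         preprocessed = isTRUE(preprocessed)),
    class = "modality_table"
  )
}

#' @export
print.modality_table <- function(x, ...) {
  cat(sprintf("<modality_table '%s'> %d subjects x %d features%s\n",
              x$modality_id, length(x$subject_ids), length(x$features),
              if (x$preprocessed) " (preprocessed)" else ""))
  invisible(x)
}

#' @export
dim.modality_table <- function(x) dim(x$values)

#' Read a modality table from CSV
#'
#' Reads a comma-separated UTF-8 file with a header row; the first column
#' holds subject IDs, the remaining columns are numeric features. Row order
#' is preserved. Blank cells, non-numeric cells, duplicate subject IDs and
#' empty files are errors (complete-case design: converters and imputation
#' are the caller's job).
#'
#' @param path path to a CSV file.
#' @param modality_id modality tag, see [modality_table()].
#' @return A [modality_table()].
#' @export
read_modality_table <- function(path, modality_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL, fileEncoding = "UTF-8")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty or header-only modality file: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate subject IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feat <- names(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  blank <- which(matrix(!nzchar(trimws(raw)), nrow(raw)), arr.ind = TRUE)
  if (nrow(blank) > 0)
    stop("missing value(s) in ", path, " at (row, column): ",
         paste(sprintf("(%s, %s)", ids[blank[, 1]], feat[blank[, 2]]),
               collapse = ", "))
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell(s) in ", path, " at (row, column): ",
         paste(sprintf("(%s, %s) = '%s'", ids[bad[, 1]], feat[bad[, 2]],
                       raw[bad, drop = FALSE]), collapse = ", "))
  modality_table(vals, ids, feat, modality_id = modality_id)
}

#' Write a modality table to CSV
#'
#' Values are written as decimal text with 17 significant digits, so a
#' write/read round trip reproduces them bit-exactly for doubles.
#'
#' @param table a [modality_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modality_table <- function(table, path) {
  stopifnot(inherits(table, "modality_table"))
  df <- data.frame(subject_id = table$subject_ids, check.names = FALSE)
  for (j in seq_along(table$features))
    df[[table$features[j]]] <- sprintf("%.17g", table$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
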