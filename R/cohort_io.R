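#' Read a covariate table
#'
#' Expects columns `subject_id`, `age` (years), `sex` (0/1 indicator) and
#' optionally `icv` (total intracranial volume, mm^3; cohorts without imaging
#' may omit it).
#'
#' @param path CSV path.
#' @return A `covariate_table`: a data.frame with the columns above.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("covariate table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  covariate_table(df)
}

#' Construct/validate a covariate table
#'
#' @param df data.frame with `subject_id`, `age`, `sex` and optionally `icv`.
#' @return The validated data.frame with class `covariate_table`.
#' @export
covariate_table <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject IDs in covariate table")
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("age must be positive and finite")
  if (!all(df$sex %in% c(0, 1)))
    stop("sex must be coded 0/1")
  if (!is.null(df$icv) && any(df$icv <= 0, na.rm = TRUE))
    stop("icv must be positive (mm^3)")
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Read a cohort label table
#'
#' Expects columns `subject_id`, `baseline_dx` (one of CN, EMCI, LMCI, AD),
#' `final_dx` (CN, MCI, AD; may be empty for subjects lost to follow-up),
#' `amyloid_suvr` (composite SUVR, whole-cerebellum normalized; may be empty)
#' and optionally `follow_up_years`.
#'
#' @param path CSV path.
#' @return A `cohort_labels` data.frame.
#' @export
read_cohort_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("", "NA"))
  need <- c("subject_id", "baseline_dx")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("label table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  cohort_labels(df)
}

#' Construct/validate a cohort label table
#'
#' @param df data.frame with at least `subject_id` and `baseline_dx`; optional
#'   `final_dx`, `amyloid_suvr`, `follow_up_years`.
#' @return The validated data.frame with class `cohort_labels`.
#' @export
cohort_labels <- function(df) {
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject IDs in label table")
  if (anyNA(df$baseline_dx))
    stop("every subject needs a baseline diagnosis")
  bad <- setdiff(unique(df$baseline_dx), c("CN", "EMCI", "LMCI", "AD"))
  if (length(bad) > 0)
    stop("unknown baseline diagnosis code(s): ", paste(bad, collapse = ", "))
  if (is.null(df$final_dx)) df$final_dx <- NA_character_
  bad <- setdiff(unique(df$final_dx[!is.na(df$final_dx)]), c("CN", "MCI", "AD"))
  if (length(bad) > 0)
    stop("unknown final diagnosis code(s): ", paste(bad, collapse = ", "))
  if (is.null(df$amyloid_suvr)) df$amyloid_suvr <- NA_real_
  if (any(df$amyloid_suvr <= 0, na.rm = TRUE))
    stop("amyloid SUVR must be positive where present")
  if (is.null(df$follow_up_years)) df$follow_up_years <- NA_real_
  class(df) <- c("cohort_labels", "data.frame")
  df
}

#' Restrict all inputs to the complete-case subject intersection
#'
#' Subjects are kept only if present in every modality table, the covariate
#' table and the label table; all outputs share the ordering of the
#' intersection (order of appearance in the first table). Dropped subjects are
#' reported with the input that excluded them, never silently removed.
#'
#' @param tables list of [modality_table()] objects.
#' @param covs a `covariate_table`.
#' @param labels a `cohort_labels` table.
#' @param quiet suppress the drop report message.
#' @return list with elements `tables`, `covariates`, `labels`, `dropped`
#'   (data.frame subject_id, missing_from).
#' @export
align_complete_cases <- function(tables, covs, labels, quiet = FALSE) {
  stopifnot(length(tables) >= 1)
  id_sets <- c(lapply(tables, `[[`, "subject_ids"),
               list(covs$subject_id, labels$subject_id))
  names(id_sets) <- c(vapply(tables, `[[`, "", "modality_id"),
                      "covariates", "labels")
  keep <- Reduce(intersect, id_sets)
  if (length(keep) == 0) stop("empty subject intersection across inputs")
  all_ids <- unique(unlist(id_sets))
  dropped_ids <- setdiff(all_ids, keep)
  dropped <- data.frame(subject_id = character(0), missing_from = character(0))
  if (length(dropped_ids) > 0) {
    missing_from <- vapply(dropped_ids, function(s) {
      paste(names(id_sets)[!vapply(id_sets, function(ids) s %in% ids, TRUE)],
            collapse = ";")
    }, "")
    dropped <- data.frame(subject_id = dropped_ids, missing_from = missing_from,
                          row.names = NULL)
    if (!quiet)
      message("align_complete_cases: dropped ", length(dropped_ids),
              " subject(s): ",
              paste(sprintf("%s (absent from %s)", dropped_ids, missing_from),
                    collapse = ", "))
  }
  # unified order: order of appearance in the first modality table
  keep <- tables[[1]]$subject_ids[tables[[1]]$subject_ids %in% keep]
  tables_out <- lapply(tables, function(tb) {
    idx <- match(keep, tb$subject_ids)
    modality_table(tb$values[idx, , drop = FALSE], keep, tb$features,
                   modality_id = tb$modality_id, preprocessed = tb$preprocessed)
  })
  covs_out <- covs[match(keep, covs$subject_id), , drop = FALSE]
  rownames(covs_out) <- NULL
  labels_out <- labels[match(keep, labels$subject_id), , drop = FALSE]
  rownames(labels_out) <- NULL
  list(tables = tables_out, covariates = covariate_table(covs_out),
       labels = cohort_labels(labels_out), dropped = dropped)
}
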