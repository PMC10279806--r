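#' Per-modality preprocessing specification
#'
#' Defaults follow standard practice for multimodal Alzheimer's cohorts:
#' structural MRI and amyloid PET are adjusted for age, sex and total
#' intracranial volume; CSF analytes and cognitive scores for age and sex;
#' genetics for sex only. All modalities are scaled to the unit interval
#' except genetics, which is z-scored (allele counts and polygenic scores
#' have no natural maximum).
#'
#' @param covariates named list: modality_id -> character vector drawn from
#'   `c("age", "sex", "icv")` (may be empty).
#' @param normalization named list: modality_id -> one of `"unit_interval"`,
#'   `"max_divide"`, `"zscore"`, `"none"`.
#' @return list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(covariates = list(), normalization = list()) {
  def_cov <- list(mri = c("age", "sex", "icv"), pet = c("age", "sex", "icv"),
                  csf = c("age", "sex"), cognition = c("age", "sex"),
                  genetics = "sex")
  def_norm <- list(mri = "unit_interval", pet = "unit_interval",
                   csf = "unit_interval", cognition = "unit_interval",
                   genetics = "zscore")
  cov <- utils::modifyList(def_cov, covariates)
  norm <- utils::modifyList(def_norm, normalization)
  for (m in names(cov)) {
    bad <- setdiff(cov[[m]], c("age", "sex", "icv"))
    if (length(bad) > 0)
      stop("unknown covariate(s) for ", m, ": ", paste(bad, collapse = ", "))
  }
  for (m in names(norm))
    norm[[m]] <- match.arg(norm[[m]],
                           c("unit_interval", "max_divide", "zscore", "none"))
  structure(list(covariates = cov, normalization = norm),
            class = "preprocess_spec")
}

with_values <- function(table, values, preprocessed = table$preprocessed) {
  modality_table(values, table$subject_ids, table$features,
                 modality_id = table$modality_id, preprocessed = preprocessed)
}

#' Center every feature column at zero
#'
#' @param table a [modality_table()] with at least 2 subjects.
#' @return The table with each column mean-subtracted. A constant column
#'   becomes all-zero, with a warning.
#' @export
mean_center <- function(table) {
  stopifnot(inherits(table, "modality_table"), nrow(table$values) >= 2)
  v <- table$values
  const <- apply(v, 2, function(x) diff(range(x)) == 0)
  if (any(const))
    warning("constant column(s) in modality '", table$modality_id, "': ",
            paste(table$features[const], collapse = ", "))
  with_values(table, sweep(v, 2, colMeans(v)))
}

#' Regress covariates out of every feature
#'
#' Each feature column is replaced by the residual of an ordinary
#' least-squares regression on an intercept plus the requested covariates
#' (raw scale). With an empty covariate set this reduces to mean centering.
#'
#' @param table a [modality_table()].
#' @param covs a `covariate_table` covering (at least) the table's subjects,
#'   in any order.
#' @param which character vector drawn from `c("age", "sex", "icv")`.
#' @return The residualized table. Residuals are orthogonal to the intercept
#'   and to every covariate used.
#' @export
residualize <- function(table, covs, which = character(0)) {
  stopifnot(inherits(table, "modality_table"))
  idx <- match(table$subject_ids, covs$subject_id)
  if (anyNA(idx))
    stop("covariate table does not cover subject(s): ",
         paste(table$subject_ids[is.na(idx)], collapse = ", "))
  n <- length(table$subject_ids)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  for (cv in which) {
    if (is.null(covs[[cv]]) || anyNA(covs[[cv]][idx]))
      stop("covariate '", cv, "' missing for this cohort")
    X <- cbind(X, covs[[cv]][idx])
    colnames(X)[ncol(X)] <- cv
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  with_values(table, qr.resid(qx, table$values))
}

#' Scale feature columns for similarity computation
#'
#' `unit_interval` (the default used for all modalities except genetics) maps
#' each column affinely onto \[0, 1\] via `(x - min) / (max - min)`.
#' `max_divide` divides by the maximum absolute value instead, leaving
#' centered data in \[-1, 1\]; it is kept as a literal "divide by the max"
#' option. Constant columns map to 0.5 (or 0), with a warning.
#'
#' @param table a [modality_table()].
#' @param mode `"unit_interval"` or `"max_divide"`.
#' @return The rescaled table.
#' @export
scale_unit_interval <- function(table, mode = c("unit_interval", "max_divide")) {
  stopifnot(inherits(table, "modality_table"))
  mode <- match.arg(mode)
  v <- table$values
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (mode == "unit_interval") {
      rng <- range(x)
      if (diff(rng) == 0) {
        warning("constant column '", table$features[j], "' mapped to 0.5")
        out[, j] <- 0.5
      } else out[, j] <- (x - rng[1]) / diff(rng)
    } else {
      mx <- max(abs(x))
      if (mx == 0) {
        warning("all-zero column '", table$features[j], "' left at 0")
        out[, j] <- 0
      } else out[, j] <- x / mx
    }
  }
  with_values(table, out)
}

#' Z-score feature columns
#'
#' Columns are centered and divided by the sample standard deviation
#' (denominator n - 1). Zero-variance columns become all-zero, with a warning.
#'
#' @param table a [modality_table()].
#' @return The standardized table.
#' @export
zscore <- function(table) {
  stopifnot(inherits(table, "modality_table"))
  v <- table$values
  s <- apply(v, 2, stats::sd)
  if (any(s == 0))
    warning("zero-variance column(s) set to 0: ",
            paste(table$features[s == 0], collapse = ", "))
  s[s == 0] <- 1
  with_values(table, sweep(sweep(v, 2, colMeans(v)), 2, s, "/"))
}

#' Apply the full preprocessing chain to one modality
#'
#' Composition, in order: mean centering, covariate residualization,
#' normalization. The covariate set and normalization mode come from the
#' [preprocess_spec()]. The result is flagged `preprocessed`; running
#' [preprocess_modality()] on an already-processed table is an error, since
#' rescaling is not idempotent.
#'
#' @param table a [modality_table()].
#' @param covs a `covariate_table`.
#' @param spec a [preprocess_spec()].
#' @return The preprocessed [modality_table()] (flag set).
#' @export
preprocess_modality <- function(table, covs, spec = preprocess_spec()) {
  stopifnot(inherits(table, "modality_table"), inherits(spec, "preprocess_spec"))
  if (table$preprocessed)
    stop("modality '", table$modality_id, "' is already preprocessed")
  m <- table$modality_id
  if (is.null(spec$covariates[[m]]) || is.null(spec$normalization[[m]]))
    stop("preprocess spec does not cover modality '", m, "'")
  out <- mean_center(table)
  out <- residualize(out, covs, spec$covariates[[m]])
  out <- switch(spec$normalization[[m]],
                unit_interval = scale_unit_interval(out, "unit_interval"),
                max_divide = scale_unit_interval(out, "max_divide"),
                zscore = zscore(out),
                none = out)
  out$preprocessed <- TRUE
  out
}
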