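#' Run the full multilayer subtyping pipeline
#'
#' Composes the analysis stages in order: load (or take in-memory) modality
#' tables, covariates and labels; restrict to complete cases; preprocess each
#' modality (center, residualize, normalize); build per-modality correlation
#' similarity layers; assemble the multilayer network; maximize multilayer
#' modularity with iterative generalized Louvain; collapse to per-subject
#' consensus communities; and evaluate against diagnoses (contingency tables,
#' sensitivity/specificity with exact binomial CIs, transition breakdown,
#' amyloid split). Deterministic given `config$seed`. Every stage is logged
#' with its parameters.
#'
#' @param config a [run_config()].
#' @param inputs either a named list of file paths (one per modality id in
#'   `config$modalities`, plus `covariates` and `labels`), or an in-memory
#'   cohort list with elements `tables`, `covariates`, `labels` as returned
#'   by [generate_cohort()].
#' @param out_dir optional directory; when given, writes `partition.csv`,
#'   `contingency.csv` and `metrics.json` there.
#' @param quiet suppress stage log messages.
#' @return list of class `multinet_result`: `partition`
#'   ([multilayer_partition()]), `network`, `layers`, `contingency_baseline`,
#'   `contingency_final`, `community_labels`, `metrics`, `transitions`,
#'   `amyloid`, `dropped`, `log`.
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
  }

  # -- load ------------------------------------------------------------
  if (!is.null(inputs$tables)) {
    tables <- inputs$tables[config$modalities]
    missing_mod <- config$modalities[vapply(tables, is.null, TRUE)]
    if (length(missing_mod) > 0)
      stop("stage 'load': no table for modality: ",
           paste(missing_mod, collapse = ", "), call. = FALSE)
    covs <- inputs$covariates
    labels <- inputs$labels
    say("load", "in-memory cohort: %d modalities, %d subjects",
        length(tables), length(tables[[1]]$subject_ids))
  } else {
    missing_mod <- setdiff(config$modalities, names(inputs))
    if (length(missing_mod) > 0)
      stop("stage 'load': no input path for modality: ",
           paste(missing_mod, collapse = ", "), call. = FALSE)
    tables <- run_stage("load", lapply(config$modalities, function(m)
      read_modality_table(inputs[[m]], m)))
    names(tables) <- config$modalities
    covs <- run_stage("load", read_covariate_table(inputs$covariates))
    labels <- run_stage("load", read_cohort_labels(inputs$labels))
    say("load", "read %d modality tables from disk", length(tables))
  }

  # -- align -----------------------------------------------------------
  aligned <- run_stage("align", align_complete_cases(tables, covs, labels,
                                                     quiet = quiet))
  say("align", "complete cases: %d subjects (%d dropped)",
      length(aligned$tables[[1]]$subject_ids), nrow(aligned$dropped))

  # -- preprocess ------------------------------------------------------
  pre <- run_stage("preprocess", lapply(aligned$tables, function(tb) {
    say("preprocess", "%s: covariates {%s}, normalization %s",
        tb$modality_id,
        paste(config$preprocess$covariates[[tb$modality_id]], collapse = ","),
        config$preprocess$normalization[[tb$modality_id]])
    preprocess_modality(tb, aligned$covariates, config$preprocess)
  }))

  # -- similarity ------------------------------------------------------
  layers <- run_stage("similarity", lapply(pre, function(tb)
    sanitize_layer(build_similarity_layer(tb, config$similarity_method),
                   config$sanitize_mode)))
  say("similarity", "%s correlation, sanitize mode %s",
      config$similarity_method, config$sanitize_mode)

  # -- community detection --------------------------------------------
  net <- run_stage("assemble",
                   assemble_multilayer(layers, gamma = config$gamma,
                                       omega = config$omega,
                                       coupling = config$coupling))
  say("assemble", "%d layers, gamma %s, omega %g (%s), 2mu = %.4g",
      net$n_layers, paste(format(net$gamma), collapse = "/"),
      net$omega, net$coupling, net$two_mu)
  part <- run_stage("genlouvain",
                    genlouvain(net, restarts = config$restarts,
                               seed = config$seed, tol = config$tol))
  say("genlouvain", "%d communities, Q = %.6f (restarts %d, seed %d)",
      part$n_communities, part$q, config$restarts, config$seed)

  # -- evaluation ------------------------------------------------------
  ct_base <- run_stage("evaluate",
                       crosstab(part$consensus, aligned$labels, "baseline"))
  ct_final <- run_stage("evaluate", suppressMessages(
    crosstab(part$consensus, aligned$labels, "final")))
  metrics <- list(q = part$q, n_communities = part$n_communities,
                  n_subjects = net$n)
  comm_labels <- NULL
  if (part$n_communities >= 2) {
    eval_one <- function(ct, tag) {
      labs <- label_communities(ct)
      ss <- sensitivity_specificity(ct, labs)
      ci_sens <- clopper_pearson_ci(ss$ad_hit, ss$ad_total)
      ci_spec <- clopper_pearson_ci(ss$cn_hit, ss$cn_total)
      say("evaluate", "%s: sensitivity %.1f%% (95%% CI %.2f-%.2f), specificity %.1f%% (95%% CI %.2f-%.2f)",
          tag, ss$sensitivity, ci_sens[1], ci_sens[2],
          ss$specificity, ci_spec[1], ci_spec[2])
      list(labels = labs, sensitivity = ss$sensitivity,
           specificity = ss$specificity,
           sensitivity_ci = unname(ci_sens), specificity_ci = unname(ci_spec))
    }
    ev_final <- run_stage("evaluate", eval_one(ct_final, "final diagnosis"))
    ev_base <- run_stage("evaluate", eval_one(ct_base, "baseline diagnosis"))
    comm_labels <- ev_final$labels
    metrics <- c(metrics, list(final = ev_final[-1], baseline = ev_base[-1]))
  } else {
    say("evaluate", "single community; sensitivity/specificity undefined")
  }
  transitions <- run_stage("evaluate",
                           transition_breakdown(part$consensus, aligned$labels))
  amyloid <- run_stage("evaluate",
                       amyloid_split(aligned$labels, config$amyloid_cutoff))
  say("evaluate", "amyloid split at %.2f: %d positive, %d negative",
      config$amyloid_cutoff, length(amyloid$positive), length(amyloid$negative))

  result <- structure(list(partition = part, network = net, layers = layers,
                           contingency_baseline = ct_base,
                           contingency_final = ct_final,
                           community_labels = comm_labels,
                           metrics = metrics, transitions = transitions,
                           amyloid = amyloid, dropped = aligned$dropped,
                           log = log),
                      class = "multinet_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.multinet_result <- function(x, ...) {
  print(x$partition)
  if (!is.null(x$community_labels)) {
    cat("community labels:",
        paste(sprintf("%s=%s", names(x$community_labels), x$community_labels),
              collapse = ", "), "\n")
    cat(sprintf("final diagnosis: sensitivity %.1f%%, specificity %.1f%%\n",
                x$metrics$final$sensitivity, x$metrics$final$specificity))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' `partition.csv` holds one row per (subject, layer) node with its community
#' and the subject's consensus community; `contingency.csv` the final- and
#' baseline-diagnosis count tables with within-diagnosis percentages;
#' `metrics.json` the machine-readable metric bundle.
#'
#' @param result a `multinet_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  part <- result$partition
  pdf_ <- data.frame(
    subject_id = rep(rownames(part$g), times = ncol(part$g)),
    layer = rep(colnames(part$g), each = nrow(part$g)),
    community = as.vector(part$g),
    consensus_community = rep(unname(part$consensus), times = ncol(part$g)))
  utils::write.csv(pdf_, file.path(out_dir, "partition.csv"), row.names = FALSE)

  cont <- do.call(rbind, lapply(c("final", "baseline"), function(tag) {
    ct <- if (tag == "final") result$contingency_final else result$contingency_baseline
    m <- ct$counts
    do.call(rbind, lapply(colnames(m), function(dx) {
      tot <- sum(m[, dx])
      data.frame(denominator = tag, diagnosis = dx,
                 community = rownames(m), count = m[, dx],
                 percent_within_diagnosis =
                   if (tot > 0) round(100 * m[, dx] / tot, 1) else NA_real_)
    }))
  }))
  utils::write.csv(cont, file.path(out_dir, "contingency.csv"), row.names = FALSE)

  metrics <- result$metrics
  metrics$transitions <- result$transitions
  metrics$community_labels <- as.list(result$community_labels)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' One CSV per modality plus `covariates.csv`, `labels.csv` and `truth.csv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (m in names(cohort$tables)) {
    paths[[m]] <- file.path(out_dir, paste0(m, ".csv"))
    write_modality_table(cohort$tables[[m]], paths[[m]])
  }
  paths$covariates <- file.path(out_dir, "covariates.csv")
  utils::write.csv(cohort$covariates, paths$covariates, row.names = FALSE)
  paths$labels <- file.path(out_dir, "labels.csv")
  utils::write.csv(cohort$labels, paths$labels, row.names = FALSE)
  paths$truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$truth, paths$truth, row.names = FALSE)
  invisible(paths)
}
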