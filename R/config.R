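#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis: the modalities to load, the
#' preprocessing spec, similarity settings, the resolution and coupling
#' parameters of the multilayer modularity, optimizer settings, and the
#' amyloid positivity cutoff. Serialized field-for-field as YAML (see
#' [read_run_config()]).
#'
#' @param modalities character vector of modality ids to include.
#' @param covariates,normalization per-modality overrides, passed to
#'   [preprocess_spec()].
#' @param similarity_method `"pearson"` or `"spearman"`.
#' @param sanitize_mode weight sanitization mode for the pipeline, see
#'   [sanitize_layer()]. The pipeline default is `"shift_rescale"`: on
#'   correlation layers the total signed weight can sit arbitrarily close to
#'   zero, which makes the configuration-model null ill-conditioned;
#'   `"keep_signed"` is fully supported and feeds signed weights straight
#'   into the modularity core.
#' @param gamma per-layer structural resolution (scalar recycled), `> 0`.
#' @param omega interlayer coupling strength, `>= 0`.
#' @param coupling `"categorical"` (all layer pairs) or `"ordinal"`.
#' @param restarts,seed,tol optimizer settings, see [genlouvain()].
#' @param amyloid_cutoff SUVR positivity cutoff (default 1.11).
#' @return list of class `run_config`.
#' @export
run_config <- function(modalities = c("mri", "pet", "csf", "cognition", "genetics"),
                       covariates = list(), normalization = list(),
                       similarity_method = c("pearson", "spearman"),
                       sanitize_mode = c("shift_rescale", "keep_signed", "clip_negative"),
                       gamma = 1, omega = 1,
                       coupling = c("categorical", "ordinal"),
                       restarts = 20, seed = 1, tol = 1e-10,
                       amyloid_cutoff = 1.11) {
  similarity_method <- match.arg(similarity_method)
  sanitize_mode <- match.arg(sanitize_mode)
  coupling <- match.arg(coupling)
  stopifnot(all(gamma > 0), omega >= 0, restarts >= 1, tol >= 0,
            amyloid_cutoff > 0, length(modalities) >= 1)
  structure(list(modalities = modalities,
                 preprocess = preprocess_spec(covariates, normalization),
                 similarity_method = similarity_method,
                 sanitize_mode = sanitize_mode,
                 gamma = gamma, omega = omega, coupling = coupling,
                 restarts = restarts, seed = as.integer(seed), tol = tol,
                 amyloid_cutoff = amyloid_cutoff),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()] field-for-field; absent fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("unknown config field(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> modalities: %s | similarity: %s/%s | gamma: %s, omega: %g (%s) | restarts: %d, seed: %d | amyloid cutoff: %g\n",
              paste(x$modalities, collapse = ","), x$similarity_method,
              x$sanitize_mode, paste(format(x$gamma), collapse = "/"),
              x$omega, x$coupling, x$restarts, x$seed, x$amyloid_cutoff))
  invisible(x)
}
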