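#' Configuration for the synthetic multimodal cohort generator
#'
#' The generator emulates the statistical structure a multilayer
#' subject-similarity analysis assumes: a shared latent subtype expressed —
#' with per-layer probability `rho` — across five modalities, modality-
#' specific Gaussian noise, linear covariate confounds (age, sex,
#' intracranial volume), diagnosis labels tied to the subtype with flip rate
#' `epsilon`, longitudinal conversion/reversion, and amyloid SUVRs drawn
#' around the 1.11 positivity boundary.
#'
#' Defaults mirror a typical amyloid-cohort layout: 90 regional volumes,
#' 68 regional SUVRs, 3 CSF analytes, 6 cognitive scores and 3 genetics
#' features (an APOE-e4-like allele count plus two continuous polygenic
#' scores; at least 3 so pairwise correlation is not degenerate), with a
#' 1-SD subtype shift on half of each modality's features.
#'
#' @param n_subjects cohort size (>= 2 * n_subtypes).
#' @param n_subtypes number of planted subtypes (default 2: a CN-like and an
#'   AD-like subtype; 3 mirrors amyloid-stratified analyses).
#' @param n_features named list of per-modality feature counts.
#' @param delta subtype effect size: mean shift, in noise-SD units, per
#'   affected feature per subtype step (default 1).
#' @param affected_fraction fraction of each modality's features carrying
#'   the subtype shift (default 0.5).
#' @param rho layer-consistency: probability that a subject's latent subtype
#'   expresses in a given layer (default 0.9).
#' @param covariate_effects named numeric: per-year age slope, sex offset
#'   and per-mm^3 ICV slope, in noise-SD units.
#' @param noise_sd residual feature noise SD (default 1).
#' @param epsilon diagnosis label-flip rate (default 0.1): models clinically
#'   mismatched cases; flipped subjects are recorded in the truth table.
#' @param conversion_prob probability that an MCI subject of the AD-like
#'   subtype converts to AD by final diagnosis (default 0.7).
#' @param reversion_prob probability that an MCI subject of the CN-like
#'   subtype reverts to CN (default 0.3).
#' @param dropout_rate fraction of subjects lost to follow-up (final
#'   diagnosis missing; default 0.05).
#' @param suvr_means,suvr_sd per-subtype amyloid SUVR means (linearly
#'   interpolated for intermediate subtypes) and common SD; defaults
#'   straddle the 1.11 cutoff.
#' @param seed integer seed; every random draw flows from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 200,
                             n_subtypes = 2,
                             n_features = list(mri = 90, pet = 68, csf = 3,
                                               cognition = 6, genetics = 3),
                             delta = 1,
                             affected_fraction = 0.5,
                             rho = 0.9,
                             covariate_effects = c(age = 0.02, sex = 0.3,
                                                   icv = 2e-6),
                             noise_sd = 1,
                             epsilon = 0.1,
                             conversion_prob = 0.7,
                             reversion_prob = 0.3,
                             dropout_rate = 0.05,
                             suvr_means = c(1.00, 1.35),
                             suvr_sd = 0.10,
                             seed = 1) {
  stopifnot(n_subtypes >= 2, n_subjects >= 2 * n_subtypes,
            delta >= 0, rho >= 0, rho <= 1, epsilon >= 0, epsilon <= 1,
            affected_fraction > 0, affected_fraction <= 1,
            conversion_prob >= 0, conversion_prob <= 1,
            reversion_prob >= 0, reversion_prob <= 1,
            noise_sd > 0, suvr_sd > 0, all(suvr_means > 0))
  if (is.null(n_features$genetics) || n_features$genetics < 3)
    stop("genetics needs >= 3 features to keep pairwise correlation non-degenerate")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic multimodal cohort with planted subtypes
#'
#' See [synthetic_config()] for the generative model. Deterministic given
#' the config seed; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return list with `tables` (named list of [modality_table()]),
#'   `covariates` (`covariate_table`), `labels` (`cohort_labels`) and
#'   `truth` (data.frame: subject_id, subtype, flipped, severity).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    n <- cf$n_subjects
    K <- cf$n_subtypes
    ids <- sprintf("s%03d", seq_len(n))
    z <- sample.int(K, n, replace = TRUE)
    sev_code <- (z - 1) / (K - 1)                    # 0 = CN-like, 1 = AD-like

    age <- stats::rnorm(n, 72, 7)
    age <- pmin(pmax(age, 55), 91)
    sex <- stats::rbinom(n, 1, 0.47)
    icv <- stats::rnorm(n, 1.5e6, 1.5e5)
    covs <- covariate_table(data.frame(subject_id = ids, age = age,
                                       sex = sex, icv = icv))

    ce <- cf$covariate_effects
    cov_off <- cf$noise_sd *
      (ce[["age"]] * (age - mean(age)) + ce[["sex"]] * sex +
         ce[["icv"]] * (icv - mean(icv)))

    modalities <- names(cf$n_features)
    tables <- list()
    for (m in modalities) {
      p <- cf$n_features[[m]]
      feats <- sprintf("%s_f%02d", m, seq_len(p))
      expressed <- stats::rbinom(n, 1, cf$rho)       # subtype visible in this layer?
      # per-feature covariate loading so the confound survives correlation
      loading <- stats::runif(p, 0.5, 1.5)
      if (m == "genetics") {
        # e4-like allele count with subtype-dependent frequency, plus
        # continuous polygenic scores shifted by the expressed subtype
        pfreq <- 0.15 + 0.30 * sev_code
        e4 <- stats::rbinom(n, 2, ifelse(expressed == 1, pfreq, 0.15))
        scores <- vapply(seq_len(p - 1), function(j) {
          (-1)^(j - 1) * cf$delta * sev_code * expressed +
            stats::rnorm(n, 0, cf$noise_sd)
        }, numeric(n))
        vals <- cbind(e4, scores + outer(cov_off, loading[-1]))
      } else {
        n_aff <- max(1, round(cf$affected_fraction * p))
        # signs alternate: disease shifts some markers up, others down
        # (e.g. CSF tau rises while amyloid-beta falls), which is what makes
        # few-feature correlation profiles informative
        sgn <- rep_len(c(1, -1), n_aff)
        shift <- matrix(0, n, p)
        shift[, seq_len(n_aff)] <- outer(cf$delta * cf$noise_sd * sev_code *
                                           expressed, sgn)
        base <- matrix(stats::rnorm(n * p, 0, cf$noise_sd), n, p)
        vals <- base + shift + outer(cov_off, loading)
      }
      tables[[m]] <- modality_table(vals, ids, feats, modality_id = m)
    }

    flipped <- stats::rbinom(n, 1, cf$epsilon) == 1
    w <- ifelse(flipped, K + 1 - z, z)               # label-subtype after flip
    w_code <- (w - 1) / (K - 1)
    severity <- w_code + stats::rnorm(n, 0, 0.3)
    baseline <- ifelse(severity < 0.25, "CN",
                       ifelse(severity < 0.75, "MCI", "AD"))
    mci <- baseline == "MCI"
    if (any(mci)) {
      med <- stats::median(severity[mci])
      baseline[mci] <- ifelse(severity[mci] < med, "EMCI", "LMCI")
    }

    base3 <- ifelse(baseline %in% c("EMCI", "LMCI"), "MCI", baseline)
    final <- base3
    is_adlike <- w == K
    is_cnlike <- w == 1
    conv <- base3 == "MCI" & is_adlike &
      stats::runif(n) < cf$conversion_prob
    rev <- base3 == "MCI" & is_cnlike &
      stats::runif(n) < cf$reversion_prob
    final[conv] <- "AD"
    final[rev] <- "CN"
    prog <- base3 == "CN" & is_adlike & stats::runif(n) < cf$conversion_prob
    final[prog] <- "MCI"
    final[stats::runif(n) < cf$dropout_rate] <- NA

    suvr_mu <- cf$suvr_means[1] +
      (cf$suvr_means[length(cf$suvr_means)] - cf$suvr_means[1]) * sev_code
    suvr <- pmax(stats::rnorm(n, suvr_mu, cf$suvr_sd), 0.5)
    fup <- pmin(pmax(stats::rnorm(n, 4.5, 2.5), 0.5), 12)

    labels <- cohort_labels(data.frame(
      subject_id = ids, baseline_dx = baseline, final_dx = final,
      amyloid_suvr = suvr, follow_up_years = fup,
      stringsAsFactors = FALSE))
    truth <- data.frame(subject_id = ids, subtype = z, flipped = flipped,
                        severity = severity)
    list(tables = tables, covariates = covs, labels = labels, truth = truth)
  })
}

#' Adjusted Rand index between recovered and planted partitions
#'
#' Chance-corrected agreement between the consensus community labels and the
#' planted subtypes: 1 iff identical up to relabeling, about 0 at chance.
#'
#' @param consensus per-subject community labels (named or plain vector).
#' @param truth planted subtype vector of the same length/subjects.
#' @return Scalar ARI in \[-1, 1\].
#' @export
recovery_score <- function(consensus, truth) {
  if (length(consensus) != length(truth))
    stop("consensus and truth cover different numbers of subjects (",
         length(consensus), " vs ", length(truth), ")")
  mclust::adjustedRandIndex(as.vector(consensus), as.vector(truth))
}
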