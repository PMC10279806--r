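#' Cross-tabulate community membership against diagnosis
#'
#' Counts subjects per (community, diagnosis) cell. Baseline EMCI/LMCI are
#' collapsed to MCI in the main table and kept separate in an auxiliary
#' table. In `denominator = "final"` mode the final diagnosis is used and
#' subjects lacking one are dropped (the drop count is reported).
#'
#' @param consensus named integer vector of per-subject community labels
#'   (names = subject IDs), e.g. the `consensus` field of a
#'   [multilayer_partition()].
#' @param labels a `cohort_labels` table covering all subjects.
#' @param denominator `"baseline"` or `"final"`.
#' @return list of class `community_crosstab`: `counts` (integer matrix,
#'   communities x c(CN, MCI, AD)), `aux_counts` (communities x baseline
#'   codes, baseline mode only), `denominator`, `n_dropped`.
#' @export
crosstab <- function(consensus, labels, denominator = c("baseline", "final")) {
  denominator <- match.arg(denominator)
  stopifnot(!is.null(names(consensus)))
  idx <- match(names(consensus), labels$subject_id)
  if (anyNA(idx))
    stop("label table does not cover subject(s): ",
         paste(names(consensus)[is.na(idx)], collapse = ", "))
  lab <- labels[idx, , drop = FALSE]
  if (denominator == "baseline") {
    dx_raw <- lab$baseline_dx
    dx <- ifelse(dx_raw %in% c("EMCI", "LMCI"), "MCI", dx_raw)
    keep <- rep(TRUE, length(dx))
  } else {
    dx <- lab$final_dx
    keep <- !is.na(dx)
    if (any(!keep))
      message("crosstab: dropped ", sum(!keep),
              " subject(s) without a final diagnosis")
  }
  bad <- setdiff(unique(dx[keep]), c("CN", "MCI", "AD"))
  if (length(bad) > 0)
    stop("unknown diagnosis code(s): ", paste(bad, collapse = ", "))
  comm <- factor(consensus[keep], levels = sort(unique(consensus)))
  dxf <- factor(dx[keep], levels = c("CN", "MCI", "AD"))
  counts <- table(community = comm, diagnosis = dxf)
  counts <- matrix(as.integer(counts), nrow = nlevels(comm),
                   dimnames = list(levels(comm), levels(dxf)))
  aux <- NULL
  if (denominator == "baseline") {
    dxa <- factor(lab$baseline_dx, levels = c("CN", "EMCI", "LMCI", "AD"))
    aux <- table(community = comm, diagnosis = dxa)
    aux <- matrix(as.integer(aux), nrow = nlevels(comm),
                  dimnames = list(levels(comm), levels(dxa)))
  }
  structure(list(counts = counts, aux_counts = aux,
                 denominator = denominator, n_dropped = sum(!keep)),
            class = "community_crosstab")
}

#' Label communities by diagnostic composition
#'
#' The community holding the largest share of AD subjects is labeled
#' `AD-dominant`; the one holding the largest share of CN subjects
#' `CN-dominant`; all others `intermediate`, ordered by decreasing AD share.
#' The two dominant labels must land on different communities; a coinciding
#' argmax is an error demanding manual labels.
#'
#' @param counts a `community_crosstab` or a communities x c(CN, MCI, AD)
#'   count matrix.
#' @return Named character vector (community id -> label).
#' @export
label_communities <- function(counts) {
  m <- if (inherits(counts, "community_crosstab")) counts$counts else as.matrix(counts)
  if (nrow(m) < 2)
    stop("community labeling needs at least 2 communities, got ", nrow(m))
  ad_share <- m[, "AD"] / sum(m[, "AD"])
  cn_share <- m[, "CN"] / sum(m[, "CN"])
  ad_dom <- which.max(ad_share)
  cn_dom <- which.max(cn_share)
  if (ad_dom == cn_dom)
    stop("AD-dominant and CN-dominant coincide (community ",
         rownames(m)[ad_dom], "); supply manual labels")
  out <- rep("intermediate", nrow(m))
  names(out) <- rownames(m)
  out[ad_dom] <- "AD-dominant"
  out[cn_dom] <- "CN-dominant"
  out
}

#' Sensitivity and specificity of the community assignment
#'
#' Sensitivity = percentage of AD subjects placed in the AD-dominant
#' community; specificity = percentage of CN subjects placed in the
#' CN-dominant community. MCI subjects enter neither metric; with more than
#' two communities, intermediate communities count as misses for both.
#' Values are exact percentages; round only at report time.
#'
#' @param counts a `community_crosstab` or count matrix (communities x
#'   c(CN, MCI, AD)).
#' @param labels community labels from [label_communities()]; recomputed
#'   when `NULL`.
#' @return list with `sensitivity`, `specificity` (percent) and the integer
#'   tallies `ad_hit`, `ad_total`, `cn_hit`, `cn_total`.
#' @export
sensitivity_specificity <- function(counts, labels = NULL) {
  m <- if (inherits(counts, "community_crosstab")) counts$counts else as.matrix(counts)
  if (is.null(labels)) labels <- label_communities(m)
  ad_dom <- names(labels)[labels == "AD-dominant"]
  cn_dom <- names(labels)[labels == "CN-dominant"]
  stopifnot(length(ad_dom) == 1, length(cn_dom) == 1)
  ad_total <- sum(m[, "AD"]); cn_total <- sum(m[, "CN"])
  if (ad_total == 0 || cn_total == 0)
    stop("zero AD or CN denominator; sensitivity/specificity undefined")
  list(sensitivity = unname(100 * m[ad_dom, "AD"] / ad_total),
       specificity = unname(100 * m[cn_dom, "CN"] / cn_total),
       ad_hit = unname(m[ad_dom, "AD"]), ad_total = ad_total,
       cn_hit = unname(m[cn_dom, "CN"]), cn_total = cn_total)
}

#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Bounds from beta-distribution quantiles:
#' `low = 100 * qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = 100 * qbeta(1 - alpha/2, x + 1, n - x)` (100 when `x = n`).
#'
#' @param successes number of successes `x`.
#' @param n number of trials.
#' @param level confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)` in percent.
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  stopifnot(length(successes) == 1, length(n) == 1,
            successes >= 0, successes <= n, n >= 1, level > 0, level < 1)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else
    100 * stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 100 else
    100 * stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

#' Split a cohort by amyloid status
#'
#' Positive iff composite SUVR >= `cutoff` (the boundary counts as positive;
#' set `inclusive = FALSE` for a strict threshold). Subjects without an SUVR
#' are excluded from both groups and reported.
#'
#' @param labels a `cohort_labels` table.
#' @param cutoff SUVR positivity cutoff, default 1.11.
#' @param inclusive whether SUVR equal to the cutoff counts as positive.
#' @return list with `positive`, `negative` (subject ID vectors) and
#'   `excluded` (IDs lacking SUVR).
#' @export
amyloid_split <- function(labels, cutoff = 1.11, inclusive = TRUE) {
  stopifnot(cutoff > 0)
  suvr <- labels$amyloid_suvr
  has <- !is.na(suvr)
  if (any(!has))
    message("amyloid_split: excluded ", sum(!has), " subject(s) without SUVR")
  pos <- if (inclusive) suvr >= cutoff else suvr > cutoff
  list(positive = labels$subject_id[has & pos],
       negative = labels$subject_id[has & !pos],
       excluded = labels$subject_id[!has])
}

transition_levels <- c("stable CN", "CN to MCI", "CN to AD", "stable MCI",
                       "MCI to AD", "MCI to CN", "stable AD", "other")

#' Longitudinal transition categories per community
#'
#' Each subject with both a baseline and a final diagnosis falls into one
#' category (stable CN, CN to MCI, CN to AD, stable MCI, MCI to AD
#' converter, MCI to CN reverter, stable AD; anything else lands in
#' `other`). Baseline EMCI/LMCI count as MCI. For each category the subject
#' count and percentage per community are reported; percentages within a
#' non-empty category sum to 100 across communities. Empty categories carry
#' zero counts and `NA` percentages (never a division by zero).
#'
#' @param consensus named per-subject community labels.
#' @param labels a `cohort_labels` table with baseline and final diagnoses.
#' @return data.frame of class `transition_breakdown` with columns
#'   `category`, `community`, `count`, `percent`.
#' @export
transition_breakdown <- function(consensus, labels) {
  idx <- match(names(consensus), labels$subject_id)
  if (anyNA(idx))
    stop("label table does not cover subject(s): ",
         paste(names(consensus)[is.na(idx)], collapse = ", "))
  lab <- labels[idx, , drop = FALSE]
  base <- ifelse(lab$baseline_dx %in% c("EMCI", "LMCI"), "MCI", lab$baseline_dx)
  fin <- lab$final_dx
  keep <- !is.na(fin)
  base <- base[keep]; fin <- fin[keep]; comm <- consensus[keep]
  cat_of <- function(b, f) {
    if (b == "CN" && f == "CN") "stable CN"
    else if (b == "CN" && f == "MCI") "CN to MCI"
    else if (b == "CN" && f == "AD") "CN to AD"
    else if (b == "MCI" && f == "MCI") "stable MCI"
    else if (b == "MCI" && f == "AD") "MCI to AD"
    else if (b == "MCI" && f == "CN") "MCI to CN"
    else if (b == "AD" && f == "AD") "stable AD"
    else "other"
  }
  categories <- mapply(cat_of, base, fin)
  comms <- sort(unique(consensus))
  out <- expand.grid(category = transition_levels, community = comms,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(ct, cm) sum(categories == ct & comm == cm),
                      out$category, out$community)
  totals <- stats::ave(out$count, out$category, FUN = sum)
  out$percent <- ifelse(totals > 0, 100 * out$count / totals, NA_real_)
  out <- out[order(match(out$category, transition_levels), out$community), ]
  rownames(out) <- NULL
  class(out) <- c("transition_breakdown", "data.frame")
  out
}

#' Scaled Mann-Whitney U map over features
#'
#' For every feature, a two-sided Mann-Whitney U test compares the two
#' subject groups; the reported statistic is `U = min(U_a, U_b)` (rank-sum
#' convention, ties handled by midranks), scaled by the maximum U across the
#' features of the call for ease of interpretation. Significance is assessed
#' at family-wise 0.05 after Bonferroni correction (family = the features
#' tested in this call) or at FDR 0.05 via Benjamini-Hochberg.
#'
#' @param feature_table a [modality_table()] (raw or preprocessed).
#' @param group_a,group_b disjoint subject ID vectors, each of size >= 2.
#' @param correction `"bonferroni"` or `"fdr"`.
#' @return data.frame with columns `feature`, `u`, `scaled_u`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
scaled_u_map <- function(feature_table, group_a, group_b,
                         correction = c("bonferroni", "fdr")) {
  stopifnot(inherits(feature_table, "modality_table"))
  correction <- match.arg(correction)
  ia <- match(group_a, feature_table$subject_ids)
  ib <- match(group_b, feature_table$subject_ids)
  if (anyNA(ia) || anyNA(ib))
    stop("group subject(s) absent from the feature table")
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 subjects")
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  na <- length(ia); nb <- length(ib)
  res <- lapply(seq_along(feature_table$features), function(j) {
    xa <- feature_table$values[ia, j]
    xb <- feature_table$values[ib, j]
    rk <- rank(c(xa, xb))
    ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
    ub <- na * nb - ua
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
    c(u = min(ua, ub), p = p)
  })
  u <- vapply(res, `[[`, 0, "u")
  p <- vapply(res, `[[`, 0, "p")
  p[is.na(p)] <- 1  # constant feature across both groups: no evidence
  method <- if (correction == "bonferroni") "bonferroni" else "BH"
  p_adj <- stats::p.adjust(p, method = method)
  max_u <- max(u)
  data.frame(feature = feature_table$features,
             u = u,
             scaled_u = if (max_u > 0) u / max_u else rep(0, length(u)),
             p = p, p_adjusted = p_adj,
             significant = p_adj < 0.05,
             row.names = NULL)
}
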