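# The final-diagnosis contingency used throughout: community 1 holds 123 CN,
# 113 MCI, 12 AD; community 2 holds 27 CN, 86 MCI, 123 AD.
final_counts <- matrix(c(123L, 27L, 113L, 86L, 12L, 123L), nrow = 2,
                       dimnames = list(c("1", "2"), c("CN", "MCI", "AD")))

test_that("crosstab regenerates the reference contingency from a cohort", {
  fx <- cohort_from_counts(final_counts)
  ct <- crosstab(fx$consensus, fx$labels, denominator = "final")
  expect_identical(ct$counts, final_counts)
  expect_equal(sum(ct$counts), 484)

  # permuting subject order leaves the table unchanged
  perm <- sample(length(fx$consensus))
  ct2 <- crosstab(fx$consensus[perm], fx$labels, denominator = "final")
  expect_identical(ct2$counts, final_counts)

  # single community: one row equal to the diagnosis totals
  one <- stats::setNames(rep(1L, length(fx$consensus)), names(fx$consensus))
  ct1 <- crosstab(one, fx$labels, denominator = "final")
  expect_equal(unname(ct1$counts[1, ]), unname(colSums(final_counts)))
})

test_that("crosstab collapses EMCI/LMCI at baseline and keeps them separate", {
  labels <- cohort_labels(data.frame(
    subject_id = sprintf("s%d", 1:6),
    baseline_dx = c("CN", "EMCI", "LMCI", "AD", "EMCI", "CN"),
    final_dx = c("CN", "MCI", "AD", "AD", NA, "CN")))
  cons <- stats::setNames(c(1L, 1L, 2L, 2L, 1L, 1L), sprintf("s%d", 1:6))
  ct <- crosstab(cons, labels, "baseline")
  expect_equal(sum(ct$counts), 6)                       # full cohort in baseline mode
  expect_equal(unname(ct$counts["1", "MCI"]), 2)        # EMCI + EMCI
  expect_equal(unname(ct$aux_counts["1", "EMCI"]), 2)   # kept separate
  expect_message(ctf <- crosstab(cons, labels, "final"), "dropped 1")
  expect_equal(ctf$n_dropped, 1)
  expect_equal(sum(ctf$counts), 5)
})

test_that("community labels follow diagnostic content, not ids", {
  labs <- label_communities(final_counts)
  expect_identical(unname(labs), c("CN-dominant", "AD-dominant"))
  # swap community ids: labels travel with the content
  swapped <- final_counts[c(2, 1), ]
  rownames(swapped) <- c("1", "2")
  expect_identical(unname(label_communities(swapped)),
                   c("AD-dominant", "CN-dominant"))
  # 3-community amyloid-negative-like pattern: all AD in community 3
  amyneg <- matrix(c(60, 33, 22, 20, 30, 52, 0, 0, 4), nrow = 3,
                   dimnames = list(1:3, c("CN", "MCI", "AD")))
  labs3 <- label_communities(amyneg)
  expect_identical(unname(labs3), c("CN-dominant", "intermediate", "AD-dominant"))
  expect_error(label_communities(final_counts[1, , drop = FALSE]), "at least 2")
  coinc <- matrix(c(90, 10, 50, 50, 20, 2), nrow = 2,
                  dimnames = list(1:2, c("CN", "MCI", "AD")))
  expect_error(label_communities(coinc), "coincide")
})

test_that("sensitivity and specificity come out as shares of AD and CN", {
  ss <- sensitivity_specificity(final_counts)
  expect_equal(ss$sensitivity, 100 * 123 / 135)
  expect_equal(ss$specificity, 100 * 123 / 150)
  expect_equal(round(ss$sensitivity, 1), 91.1)
  expect_equal(round(ss$specificity, 1), 82)

  perfect <- matrix(c(50, 0, 0, 0, 0, 40), nrow = 2,
                    dimnames = list(1:2, c("CN", "MCI", "AD")))
  sp <- sensitivity_specificity(perfect)
  expect_equal(sp$sensitivity, 100)
  expect_equal(sp$specificity, 100)

  # all AD in the CN-dominant community -> label_communities refuses the
  # coinciding argmax, so force labels to probe the 0% path
  zero <- matrix(c(50, 10, 5, 5, 9, 0), nrow = 2,
                 dimnames = list(1:2, c("CN", "MCI", "AD")))
  sz <- sensitivity_specificity(zero,
                                labels = c("1" = "CN-dominant", "2" = "AD-dominant"))
  expect_equal(sz$sensitivity, 0)

  # invariance to community id permutation
  swapped <- final_counts[c(2, 1), ]; rownames(swapped) <- c("1", "2")
  ss2 <- sensitivity_specificity(swapped)
  expect_equal(ss2$sensitivity, ss$sensitivity)
  expect_equal(ss2$specificity, ss$specificity)
})

test_that("Clopper-Pearson bounds agree with binomial-tail root finding", {
  # brute-force oracle: invert the exact binomial tails numerically
  cp_oracle <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    low <- if (x == 0) 0 else
      uniroot(function(p) 1 - pbinom(x - 1, n, p) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    high <- if (x == n) 1 else
      uniroot(function(p) pbinom(x, n, p) - a, c(1e-12, 1 - 1e-12),
              tol = 1e-12)$root
    100 * c(low, high)
  }
  for (case in list(c(3, 10), c(0, 10), c(10, 10), c(17, 30), c(25, 28))) {
    got <- clopper_pearson_ci(case[1], case[2])
    expect_equal(unname(got), cp_oracle(case[1], case[2]), tolerance = 1e-8)
  }
  expect_equal(unname(clopper_pearson_ci(0, 10))[1], 0)
  expect_equal(unname(clopper_pearson_ci(10, 10))[2], 100)
  expect_error(clopper_pearson_ci(11, 10), "successes")
})

test_that("amyloid_split applies the inclusive 1.11 cutoff", {
  labels <- cohort_labels(data.frame(
    subject_id = sprintf("s%d", 1:4), baseline_dx = "CN",
    amyloid_suvr = c(1.2, 1.0, 1.11, NA)))
  sp <- suppressMessages(amyloid_split(labels))
  expect_setequal(sp$positive, c("s1", "s3"))   # boundary counts as positive
  expect_setequal(sp$negative, "s2")
  expect_setequal(sp$excluded, "s4")
  strict <- suppressMessages(amyloid_split(labels, inclusive = FALSE))
  expect_setequal(strict$positive, "s1")
})

test_that("transition breakdown reports per-category community percentages", {
  # constructed cohort: 26 MCI-to-CN reverters, 23 of them in community 1
  # (88.5%); 65 MCI-to-AD converters, 59 in community 2 (90.8%)
  mk <- function(n, base, fin, comm) data.frame(
    baseline_dx = rep(base, n), final_dx = rep(fin, n), community = rep(comm, n))
  df <- rbind(mk(23, "LMCI", "CN", 1), mk(3, "EMCI", "CN", 2),
              mk(6, "LMCI", "AD", 1), mk(59, "LMCI", "AD", 2),
              mk(40, "CN", "CN", 1), mk(10, "AD", "AD", 2))
  df$subject_id <- sprintf("s%03d", seq_len(nrow(df)))
  labels <- cohort_labels(df[, c("subject_id", "baseline_dx", "final_dx")])
  cons <- stats::setNames(df$community, df$subject_id)
  tb <- transition_breakdown(cons, labels)
  pick <- function(cat, cm) tb$percent[tb$category == cat & tb$community == cm]
  expect_equal(round(pick("MCI to CN", 1), 1), 88.5)
  expect_equal(round(pick("MCI to AD", 2), 1), 90.8)
  expect_equal(pick("stable CN", 1), 100)
  # percentages within each non-empty category sum to 100
  for (cat in unique(tb$category[tb$count > 0]))
    expect_equal(sum(tb$percent[tb$category == cat]), 100)
  # empty categories carry NA percentages, not divisions by zero
  expect_true(all(is.na(tb$percent[tb$category == "CN to AD"])))
})

test_that("no-MCI cohorts yield empty MCI categories without errors", {
  labels <- cohort_labels(data.frame(
    subject_id = c("a", "b"), baseline_dx = c("CN", "AD"),
    final_dx = c("CN", "AD")))
  tb <- transition_breakdown(stats::setNames(c(1L, 2L), c("a", "b")), labels)
  expect_equal(sum(tb$count[tb$category == "stable MCI"]), 0)
  expect_true(all(is.na(tb$percent[tb$category == "MCI to AD"])))
})

test_that("scaled U map matches a rank-count oracle and normalizes by max U", {
  # 2 groups x 3 features with hand-enumerable rank sums
  vals <- rbind(c(1, 10, 5), c(2, 20, 6),  c(3, 30, 4),    # group a
                c(4, 1, 50), c(5, 2, 60), c(6, 3, 70))     # group b
  tb <- modality_table(vals, sprintf("s%d", 1:6), c("f1", "f2", "f3"), "csf")
  out <- scaled_u_map(tb, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  # f1: a = {1,2,3} all below b -> U_a = 0; f2: a all above -> U_b = 0;
  # f3: a = {5,6,4} vs b = {50,60,70} -> U_a = 0
  expect_equal(out$u, c(0, 0, 0))
  expect_equal(out$scaled_u, c(0, 0, 0))

  # mixed case: counts of (a > b) pairs enumerated by hand
  vals2 <- rbind(c(7), c(2), c(9), c(1), c(3), c(8))
  tb2 <- modality_table(cbind(vals2, vals2 * 2), sprintf("s%d", 1:6),
                        c("g1", "g2"), "csf")
  out2 <- scaled_u_map(tb2, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  # a = {7,2,9}, b = {1,3,8}: pairs with a > b: 7>(1,3), 2>1, 9>(1,3,8) = 6
  # U_a = 6, U_b = 3, min = 3; identical for the doubled feature
  expect_equal(out2$u, c(3, 3))
  expect_equal(out2$scaled_u, c(1, 1))

  # identical groups: p ~ 1, nothing significant under either correction
  same <- modality_table(rbind(vals, vals), sprintf("s%d", 1:12),
                         c("f1", "f2", "f3"), "csf")
  outs <- scaled_u_map(same, sprintf("s%d", 1:6), sprintf("s%d", 7:12))
  expect_true(all(outs$p > 0.9))
  expect_false(any(outs$significant))
  outf <- scaled_u_map(same, sprintf("s%d", 1:6), sprintf("s%d", 7:12),
                       correction = "fdr")
  expect_false(any(outf$significant))

  expect_error(scaled_u_map(tb, "s1", sprintf("s%d", 4:6)), "at least 2")
  expect_error(scaled_u_map(tb, sprintf("s%d", 1:3), sprintf("s%d", 3:5)),
               "disjoint")
})

test_that("a strong group difference survives Bonferroni correction", {
  set.seed(12)
  n <- 40
  vals <- cbind(c(rnorm(n/2, 0), rnorm(n/2, 3)), rnorm(n), rnorm(n))
  tb <- modality_table(vals, sprintf("s%d", 1:n), c("hit", "null1", "null2"),
                       "cognition")
  out <- scaled_u_map(tb, sprintf("s%d", 1:(n/2)), sprintf("s%d", (n/2+1):n))
  expect_true(out$significant[out$feature == "hit"])
  expect_false(any(out$significant[out$feature != "hit"]))
  expect_equal(max(out$scaled_u), 1)
})
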