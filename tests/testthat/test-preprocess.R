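test_that("mean_center zeroes column means and flags constant columns", {
  tb <- toy_table(cbind(c(2, 4, 6), c(1, 1, 1)))
  expect_warning(out <- mean_center(tb), "constant column")
  expect_equal(unname(out$values[, 1]), c(-2, 0, 2))
  expect_equal(unname(out$values[, 2]), c(0, 0, 0))
  # idempotent on centered data
  tb2 <- toy_table(cbind(c(-1, 0, 1), c(2, -1, -1)))
  expect_equal(mean_center(tb2)$values, tb2$values)
})

test_that("residualize matches the normal-equations solution and is orthogonal", {
  covs <- covariate_table(data.frame(subject_id = sprintf("s%d", 1:4),
                                     age = c(10, 20, 30, 40),
                                     sex = c(0, 0, 1, 1)))
  tb <- toy_table(matrix(c(1, 2, 3, 4), 4, 1))
  out <- residualize(tb, covs, c("age", "sex"))
  # oracle: solve the 3x3 normal equations X'X beta = X'y directly
  X <- cbind(1, c(10, 20, 30, 40), c(0, 0, 1, 1))
  beta <- solve(t(X) %*% X, t(X) %*% c(1, 2, 3, 4))
  expect_equal(unname(out$values[, 1]), c(1, 2, 3, 4) - as.vector(X %*% beta),
               tolerance = 1e-12)
  expect_lt(abs(sum(out$values[, 1] * covs$age)), 1e-8 * 4)
  expect_lt(abs(sum(out$values[, 1] * covs$sex)), 1e-8 * 4)

  # feature exactly linear in age: zero residuals
  tb2 <- toy_table(matrix(3 * c(10, 20, 30, 40) + 1, 4, 1))
  expect_equal(max(abs(residualize(tb2, covs, "age")$values)), 0,
               tolerance = 1e-10)

  # empty covariate set reduces to mean centering
  tb3 <- toy_table(matrix(c(5, 7, 9, 13), 4, 1))
  expect_equal(residualize(tb3, covs, character(0))$values,
               mean_center(tb3)$values)
})

test_that("residualize rejects rank-deficient designs, naming the culprit", {
  covs <- covariate_table(data.frame(subject_id = sprintf("s%d", 1:4),
                                     age = c(10, 20, 30, 40),
                                     sex = c(0, 1, 0, 1),
                                     icv = 2 * c(10, 20, 30, 40)))
  tb <- toy_table(matrix(rnorm(4), 4, 1))
  expect_error(residualize(tb, covs, c("age", "icv")), "collinear.*icv")
})

test_that("re-regressing residuals on the same covariates gives zero slopes", {
  set.seed(7)
  covs <- covariate_table(data.frame(subject_id = sprintf("s%d", 1:30),
                                     age = runif(30, 55, 90),
                                     sex = rbinom(30, 1, 0.5),
                                     icv = rnorm(30, 1.5e6, 1e5)))
  tb <- toy_table(matrix(rnorm(90), 30, 3))
  out <- residualize(tb, covs, c("age", "sex", "icv"))
  X <- cbind(1, covs$age, covs$sex, covs$icv)
  beta <- qr.coef(qr(X), out$values)
  expect_lt(max(abs(beta)), 1e-8)
})

test_that("scaling modes map ranges as documented", {
  tb <- toy_table(matrix(c(2, 4, 6), 3, 1))
  expect_equal(unname(scale_unit_interval(tb)$values[, 1]), c(0, 0.5, 1))
  tb2 <- toy_table(matrix(c(-1, 0, 1), 3, 1))
  expect_equal(unname(scale_unit_interval(tb2, "max_divide")$values[, 1]),
               c(-1, 0, 1))
  set.seed(1)
  tb3 <- toy_table(matrix(rnorm(40), 10, 4))
  out <- scale_unit_interval(tb3)
  expect_equal(unname(apply(out$values, 2, min)), rep(0, 4))
  expect_equal(unname(apply(out$values, 2, max)), rep(1, 4))
  expect_warning(scale_unit_interval(toy_table(matrix(5, 3, 1))), "0.5")
})

test_that("zscore standardizes with sample SD and handles edge cases", {
  expect_equal(unname(zscore(toy_table(matrix(1:3, 3, 1)))$values[, 1]),
               c(-1, 0, 1))
  # APOE e4 counts: mean 0.75, sample SD sqrt(sum((x - 0.75)^2) / 3) = 0.9574
  tb <- toy_table(matrix(c(0, 0, 1, 2), 4, 1), modality_id = "genetics")
  out <- zscore(tb)
  expect_equal(unname(out$values[, 1]), (c(0, 0, 1, 2) - 0.75) / 0.957427107756338,
               tolerance = 1e-12)
  expect_equal(mean(out$values), 0, tolerance = 1e-10)
  expect_equal(sd(out$values), 1, tolerance = 1e-10)
  expect_warning(z0 <- zscore(toy_table(matrix(4, 3, 1))), "zero-variance")
  expect_equal(unname(z0$values[, 1]), c(0, 0, 0))
})

test_that("preprocess_modality composes the steps per modality spec", {
  set.seed(11)
  n <- 20
  covs <- covariate_table(data.frame(subject_id = sprintf("s%d", 1:n),
                                     age = runif(n, 55, 90),
                                     sex = rbinom(n, 1, 0.5),
                                     icv = rnorm(n, 1.5e6, 1e5)))
  spec <- preprocess_spec()

  gen <- modality_table(matrix(rnorm(n * 3), n, 3), sprintf("s%d", 1:n),
                        c("e4", "phs", "prs"), "genetics")
  out <- preprocess_modality(gen, covs, spec)
  expect_true(out$preprocessed)
  # genetics branch: z-scored (unit sample SD), sex regressed out
  expect_equal(unname(apply(out$values, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(out$values, covs$sex - mean(covs$sex)))), 1e-6)

  mri <- modality_table(matrix(rnorm(n * 4), n, 4), sprintf("s%d", 1:n),
                        sprintf("roi%d", 1:4), "mri")
  outm <- preprocess_modality(mri, covs, spec)
  # mri branch: age+sex+icv regressed, then unit-interval scaled
  expect_equal(unname(apply(outm$values, 2, min)), rep(0, 4))
  expect_equal(unname(apply(outm$values, 2, max)), rep(1, 4))

  # running preprocessing twice is refused
  expect_error(preprocess_modality(outm, covs, spec), "already preprocessed")
})

test_that("empty covariates + no normalization equals plain mean centering", {
  set.seed(3)
  n <- 12
  covs <- covariate_table(data.frame(subject_id = sprintf("s%d", 1:n),
                                     age = runif(n, 55, 90),
                                     sex = rbinom(n, 1, 0.5)))
  spec <- preprocess_spec(covariates = list(csf = character(0)),
                          normalization = list(csf = "none"))
  tb <- modality_table(matrix(rnorm(n * 3), n, 3), sprintf("s%d", 1:n),
                       c("abeta", "tau", "ptau"), "csf")
  out <- preprocess_modality(tb, covs, spec)
  expect_equal(out$values, mean_center(tb)$values)
})
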