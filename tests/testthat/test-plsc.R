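test_that("confound residualization matches hand OLS and guards leakage", {
  conf <- matrix(1:4, 4, 1)
  M <- matrix(c(2, 4, 6, 9), 4, 1, dimnames = list(NULL, "m"))
  out <- residualize_and_standardize(M, conf)
  # hand OLS: slope 2.3, intercept -0.5, residuals (0.2,-0.1,-0.4,0.3),
  # residual SD sqrt(0.1)
  expect_equal(drop(out$matrix),
               c(0.2, -0.1, -0.4, 0.3) / sqrt(0.1), tolerance = 1e-9)
  expect_equal(unname(out$params$coefficients[, 1]), c(-0.5, 2.3),
               tolerance = 1e-9)

  # column orthogonal to the confound: residual = demeaned column
  set.seed(2)
  x <- rnorm(50); z <- rnorm(50)
  x <- residuals(lm(x ~ z))  # exactly orthogonal
  o2 <- residualize_and_standardize(matrix(x), matrix(z))
  expect_equal(drop(o2$matrix), as.numeric(scale(x)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # exactly collinear column is rejected with its name
  bad <- matrix(2 * (1:4), 4, 1, dimnames = list(NULL, "lin"))
  expect_error(residualize_and_standardize(bad, conf), "lin")

  # leakage guard: stored parameters are applied verbatim to new data
  tr <- matrix(rnorm(60), 20, 3)
  ctr <- matrix(rnorm(20), 20, 1)
  fit <- residualize_and_standardize(tr, ctr)
  te <- matrix(rnorm(30), 10, 3)
  cte <- matrix(rnorm(10), 10, 1)
  out_te <- residualize_and_standardize(te, cte, fit$params)$matrix
  manual <- sweep(sweep(te - cbind(1, cte) %*% fit$params$coefficients,
                        2, fit$params$center), 2, fit$params$sd, "/")
  expect_equal(out_te, manual, tolerance = 1e-12)

  expect_error(residualize_and_standardize(tr, cbind(ctr, ctr)),
               "rank deficient")
})

test_that("PLSC of single columns reduces to the correlation", {
  set.seed(11)
  x <- scale(rnorm(100))
  y <- scale(0.6 * x + rnorm(100, sd = 0.8))
  fit <- plsc_fit(x, y)
  expect_equal(fit$singular_values[1], abs(cor(x, y)[1]), tolerance = 1e-9)
  expect_equal(abs(fit$x_weights[1, 1]), 1)
  expect_equal(abs(fit$y_weights[1, 1]), 1)
})

test_that("PLSC satisfies its SVD identities", {
  set.seed(12)
  X <- scale(matrix(rnorm(300), 50, 6))
  Y <- scale(matrix(rnorm(200), 50, 4))
  fit <- plsc_fit(X, Y)
  R <- crossprod(X, Y) / 49
  expect_equal(sum(fit$singular_values^2), sum(R^2), tolerance = 1e-9)
  expect_equal(sum(fit$covariance_explained), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$y_weights), diag(4), tolerance = 1e-9)
  expect_equal(crossprod(fit$x_weights), diag(4), tolerance = 1e-9)
  # cross-side score orthogonality across dimensions
  cross <- crossprod(fit$x_scores, fit$y_scores)
  expect_equal(cross, diag(diag(cross)), tolerance = 1e-8)
  # SVs non-negative, non-increasing
  expect_true(all(fit$singular_values >= 0))
  expect_true(all(diff(fit$singular_values) <= 1e-12))
})

test_that("a column permutation of X yields a perfect first dimension", {
  set.seed(13)
  X <- scale(matrix(rnorm(240), 40, 6))
  Y <- X[, c(3, 1, 6, 2, 5, 4)]
  fit <- plsc_fit(X, Y)
  expect_equal(abs(cor(fit$x_scores[, 1], fit$y_scores[, 1])[1]), 1,
               tolerance = 1e-8)
})

test_that("planted rank-1 weights are recovered at n = 500", {
  coh <- simulate_cohort(planted_plsc_design(3, n = 500), timeseries = FALSE)
  m <- plsc_matrices(coh)
  fit <- plsc_fit(m$X, m$Y)
  expect_gt(abs(sum(fit$x_weights[, 1] * planted_x_direction())), 0.9)
  b <- seq(0.75, 0.3, length.out = 10)
  expect_gt(abs(sum(fit$y_weights[, 1] * b / sqrt(sum(b^2)))), 0.9)
})

test_that("permutation p-values hit the add-one floor for strong effects", {
  coh <- simulate_cohort(planted_plsc_design(5), timeseries = FALSE)
  m <- plsc_matrices(coh)
  pt <- permutation_test(m$X, m$Y, n_perm = 200, seed = 1)
  expect_equal(pt$p_values[1], 1 / 201)
  expect_true(all(pt$p_values >= 1 / 201 & pt$p_values <= 1))
})

test_that("permutation blocks never mix family members and ignore renaming", {
  fam <- c(1, 1, 2, 2, 3, 3, 4, 4)
  blocks <- leidaplsc:::permutation_blocks(fam)
  expect_equal(lengths(blocks), c(4L, 4L), ignore_attr = TRUE)
  for (b in blocks) expect_equal(anyDuplicated(fam[b]), 0L)

  coh <- simulate_cohort(cohort_design(n_subjects = 60,
                                       family_sizes = rep(2L, 30),
                                       confound_effect = 0, seed = 21),
                         timeseries = FALSE)
  m <- plsc_matrices(coh)
  p1 <- permutation_test(m$X, m$Y, coh$families$family_id,
                         n_perm = 150, seed = 9)
  renamed <- paste0("fam", coh$families$family_id)
  p2 <- permutation_test(m$X, m$Y, renamed, n_perm = 150, seed = 9)
  expect_identical(p1$p_values, p2$p_values)

  # singleton blocks are tolerated
  fam_single <- c(1, 1, 2, 3, 3, 4, 5, 5)
  X <- scale(matrix(rnorm(80), 8))
  Y <- scale(matrix(rnorm(40), 8))
  expect_no_error(permutation_test(X, Y, fam_single, n_perm = 100, seed = 2))
})

test_that("block bootstrap with singleton families equals the subject bootstrap", {
  set.seed(31)
  X <- scale(matrix(rnorm(400), 50, 8))
  Y <- scale(matrix(rnorm(150), 50, 3))
  a <- bootstrap_ratios(X, Y, NULL, n_boot = 120, seed = 5)
  b <- bootstrap_ratios(X, Y, seq_len(50), n_boot = 120, seed = 5)
  expect_equal(a$x_br, b$x_br)
})

test_that("split-half test SV equals the train SV in the degenerate case", {
  set.seed(17)
  X <- scale(matrix(rnorm(200), 40, 5))
  Y <- scale(matrix(rnorm(120), 40, 3))
  fit <- plsc_fit(X, Y)
  R <- crossprod(X, Y) / 39
  for (j in 1:3) {
    expect_equal(drop(t(fit$x_weights[, j]) %*% R %*% fit$y_weights[, j]),
                 fit$singular_values[j], tolerance = 1e-9)
  }
})

test_that("oversized families are rejected for split-half", {
  X <- scale(matrix(rnorm(100), 20, 5))
  Y <- scale(matrix(rnorm(60), 20, 3))
  fam <- c(rep(1, 12), 2:9)
  expect_error(splithalf_reproducibility(X, Y, fam, n_split = 100, seed = 1),
               "half the cohort")
})

test_that("cross-validation reduces to leave-one-out with singleton folds", {
  coh <- simulate_cohort(planted_plsc_design(23, n = 30), timeseries = FALSE)
  X <- as.matrix(coh$truth$params)
  Y <- as.matrix(coh$behavior[, -1])
  cv <- cross_validate(X, Y, NULL, NULL, n_folds = 30, seed = 3)
  expect_length(cv$oos_correlation, 6)
  expect_false(anyNA(cv$oos_x_scores))
  expect_gt(cv$oos_correlation[1], 0)
})

test_that("variance explained matches projection algebra and the PCA oracle", {
  set.seed(19)
  M <- matrix(rnorm(200), 40, 5)
  full <- qr.Q(qr(matrix(rnorm(200), 40, 5)))
  expect_equal(variance_explained(M, M %*% diag(5)), 1, tolerance = 1e-9)

  ortho <- qr.Q(qr(cbind(rnorm(40))))
  ortho <- ortho - M %*% qr.solve(crossprod(M), crossprod(M, ortho))
  expect_equal(variance_explained(M, ortho), 0, tolerance = 1e-9)

  Mc <- scale(M, scale = FALSE)
  pc <- prcomp(Mc, center = FALSE)
  ve <- variance_explained(Mc, pc$x[, 1, drop = FALSE])
  expect_equal(ve, pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-9)

  expect_error(variance_explained(matrix(0, 4, 2), matrix(rnorm(4))), "zero")
  expect_error(variance_explained(M, cbind(M[, 1], M[, 1])), "independent")
})
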