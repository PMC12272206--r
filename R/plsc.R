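# Partial Least Squares Correlation between a metric matrix and a behavior
# matrix: confound residualization, SVD of the cross-block correlation
# matrix, family-block-aware permutation significance, block bootstrap
# stability ratios, split-half reproducibility and cross-validation.

#' Residualize confounds and z-score columns
#'
#' Per column: ordinary least squares on the confounds (with intercept),
#' residuals divided by their SD. When `fitted_params` is supplied, the
#' stored coefficients, centers and SDs are applied instead of refitting —
#' the data-leakage guard used for test halves and cross-validation folds.
#'
#' @param M n x m numeric matrix (or data frame of numeric columns).
#' @param confounds n x c numeric matrix, full column rank, or `NULL` for
#'   plain standardization.
#' @param fitted_params Parameter list returned by a previous call, or `NULL`
#'   to fit.
#' @return List with `matrix` (transformed n x m) and `params`
#'   (`coefficients`, `center`, `sd`).
#' @export
residualize_and_standardize <- function(M, confounds = NULL,
                                        fitted_params = NULL) {
  M <- as.matrix(M)
  assert_finite_matrix(M, "M")
  n <- nrow(M)
  Z <- if (is.null(confounds)) matrix(1, n, 1L) else
    cbind(intercept = 1, as.matrix(confounds))
  if (!is.null(confounds) && n <= ncol(Z))
    stop("need n > number of confounds + 1", call. = FALSE)
  if (is.null(fitted_params)) {
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop("confounds are rank deficient", call. = FALSE)
    beta <- qr.coef(qz, M)
    resid <- M - Z %*% beta
    center <- colMeans(resid)
    resid <- sweep(resid, 2L, center)
    sds <- apply(resid, 2L, stats::sd)
    raw_sds <- apply(M, 2L, stats::sd)
    dead <- which(sds <= 1e-10 * pmax(raw_sds, 1))
    if (length(dead) > 0L) {
      nm <- colnames(M)[dead] %||% as.character(dead)
      stop("zero-variance residual column(s): ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
    out <- sweep(resid, 2L, sds, "/")
    params <- list(coefficients = beta, center = center, sd = sds)
  } else {
    resid <- M - Z %*% fitted_params$coefficients
    resid <- sweep(resid, 2L, fitted_params$center)
    out <- sweep(resid, 2L, fitted_params$sd, "/")
    params <- fitted_params
  }
  list(matrix = out, params = params)
}

# Deterministic sign convention for an SVD: the largest-|entry| element of
# each left singular vector is made positive.
fix_svd_signs <- function(u, v) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  list(u = u, v = v)
}

#' Fit a PLSC model
#'
#' Singular value decomposition of the cross-block matrix
#' `R = t(X) %*% Y / (n - 1)` of two column-standardized matrices. Each pair
#' of singular vectors defines a dimension: latent scores are the projections
#' `X %*% u_d` and `Y %*% v_d`, loadings are the Pearson correlations of each
#' original column with its own side's latent score, and the covariance
#' explained by dimension d is `S_d^2 / sum(S^2)`.
#'
#' @param X n x p matrix (preprocessed; see [residualize_and_standardize()]).
#' @param Y n x q matrix (same subjects, same treatment).
#' @return Object of class `plsc_result`: `singular_values`, `x_weights`,
#'   `y_weights`, `x_scores`, `y_scores`, `x_loadings`, `y_loadings`,
#'   `covariance_explained`, `latent_correlations` (Spearman, per dimension),
#'   `n`.
#' @export
plsc_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_finite_matrix(X, "X"); assert_finite_matrix(Y, "Y")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same rows", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  R <- crossprod(X, Y) / (n - 1)
  sv <- svd(R)
  d <- min(ncol(X), ncol(Y))
  u <- sv$u[, seq_len(d), drop = FALSE]
  v <- sv$v[, seq_len(d), drop = FALSE]
  s <- fix_svd_signs(u, v)
  u <- s$u; v <- s$v
  x_scores <- X %*% u
  y_scores <- Y %*% v
  lat <- vapply(seq_len(d), function(j)
    stats::cor(x_scores[, j], y_scores[, j], method = "spearman"), numeric(1))
  structure(list(
    singular_values = sv$d[seq_len(d)],
    x_weights = u, y_weights = v,
    x_scores = x_scores, y_scores = y_scores,
    x_loadings = stats::cor(X, x_scores),
    y_loadings = stats::cor(Y, y_scores),
    covariance_explained = sv$d[seq_len(d)]^2 / sum(sv$d^2),
    latent_correlations = lat,
    cross_block = R, n = n),
    class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  d <- length(x$singular_values)
  cat(sprintf("<plsc_result> %d dimensions, n = %d\n", d, x$n))
  for (j in seq_len(min(d, 5L))) {
    cat(sprintf("  dim %d: SV = %.4f, covariance explained = %.1f%%, latent rho = %.3f\n",
                j, x$singular_values[j], 100 * x$covariance_explained[j],
                x$latent_correlations[j]))
  }
  invisible(x)
}

# Exchangeability blocks from family labels: block b holds the b-th member of
# every family, so no block contains two related subjects. Singleton-family
# cohorts collapse to one block (unrestricted permutation).
permutation_blocks <- function(family_ids) {
  if (is.null(family_ids)) return(list())
  rank_in_family <- stats::ave(seq_along(family_ids), family_ids,
                               FUN = seq_along)
  split(seq_along(family_ids), rank_in_family)
}

permute_within_blocks <- function(n, blocks) {
  idx <- seq_len(n)
  if (length(blocks) == 0L) return(sample.int(n))
  for (b in blocks) {
    if (length(b) > 1L) idx[b] <- b[sample.int(length(b))]
  }
  idx
}

#' Permutation test of PLSC singular values
#'
#' Builds the null distribution of each dimension's singular value by
#' permuting subject rows within exchangeability blocks that never mix
#' related subjects (block b = the b-th member of every family). Per
#' dimension, `p = (1 + #[perm SV_d >= observed SV_d]) / (n_perm + 1)`.
#'
#' @param X,Y Preprocessed matrices as in [plsc_fit()].
#' @param family_ids Family labels (length n), or `NULL` for unrestricted
#'   permutation.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed.
#' @param sides `"y"` (default): permute rows of Y only; `"both"`: permute
#'   both matrices independently.
#' @return List with `p_values` (d-vector), `observed` singular values and
#'   the `null` matrix (n_perm x d).
#' @export
permutation_test <- function(X, Y, family_ids = NULL, n_perm = 500L, seed = 1L,
                             sides = c("y", "both")) {
  sides <- match.arg(sides)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fit <- plsc_fit(X, Y)
  d <- length(fit$singular_values)
  blocks <- permutation_blocks(family_ids)
  null_sv <- matrix(NA_real_, n_perm, d)
  set.seed(derive_seed(seed, 41L))
  for (b in seq_len(n_perm)) {
    yi <- permute_within_blocks(n, blocks)
    Xp <- if (sides == "both") X[permute_within_blocks(n, blocks), ,
                                 drop = FALSE] else X
    Rp <- crossprod(Xp, Y[yi, , drop = FALSE]) / (n - 1)
    null_sv[b, ] <- svd(Rp, nu = 0L, nv = 0L)$d[seq_len(d)]
  }
  p <- vapply(seq_len(d), function(j) {
    (1 + sum(null_sv[, j] >= fit$singular_values[j])) / (n_perm + 1)
  }, numeric(1))
  list(p_values = p, observed = fit$singular_values, null = null_sv)
}

# Draw whole families with replacement until at least n subjects are
# accumulated; returns subject indices.
sample_family_block <- function(fam_index_list, n) {
  idx <- integer(0)
  nf <- length(fam_index_list)
  while (length(idx) < n) {
    take <- sample.int(nf, nf, replace = TRUE)
    for (f in take) {
      idx <- c(idx, fam_index_list[[f]])
      if (length(idx) >= n) break
    }
  }
  idx
}

# Greedy alignment of a resampled SVD to a reference: for each reference
# dimension in order, pick the unused resample dimension with the largest
# |weight dot product| and flip its sign to match.
align_svd <- function(u_ref, u_new, v_new) {
  d <- ncol(u_ref)
  sim <- abs(crossprod(u_ref, u_new))   # d x d
  perm <- integer(d)
  used <- rep(FALSE, ncol(u_new))
  for (j in seq_len(d)) {
    cand <- which(!used)
    perm[j] <- cand[which.max(sim[j, cand])]
    used[perm[j]] <- TRUE
  }
  signs <- vapply(seq_len(d), function(j)
    sign(sum(u_ref[, j] * u_new[, perm[j]])), numeric(1))
  signs[signs == 0] <- 1
  list(u = sweep(u_new[, perm, drop = FALSE], 2L, signs, "*"),
       v = sweep(v_new[, perm, drop = FALSE], 2L, signs, "*"))
}

#' Bootstrap ratios of PLSC loadings
#'
#' Resamples whole families with replacement (block bootstrap; singleton
#' families reduce to the ordinary subject bootstrap), re-standardizes each
#' resample, refits the PLSC, aligns its dimensions to the original solution
#' by greedy sign-and-order matching of the weight vectors, and recomputes
#' loadings. The bootstrap ratio of a loading is the original loading divided
#' by the SD of its bootstrap distribution; |BR| > 2.5 conventionally flags a
#' stable contributor.
#'
#' @param X,Y Preprocessed matrices as in [plsc_fit()].
#' @param family_ids Family labels, or `NULL` for subject-level bootstrap.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed.
#' @return List with `x_br` (p x d), `y_br` (q x d), the original loadings
#'   and the bootstrap loading SDs. Zero-SD entries yield infinite ratios.
#' @export
bootstrap_ratios <- function(X, Y, family_ids = NULL, n_boot = 500L, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(family_ids)) family_ids <- seq_len(n)
  fam_index_list <- split(seq_len(n), family_ids)
  fit <- plsc_fit(X, Y)
  d <- length(fit$singular_values)
  p <- ncol(X); q <- ncol(Y)
  xl <- array(NA_real_, c(n_boot, p, d))
  yl <- array(NA_real_, c(n_boot, q, d))
  set.seed(derive_seed(seed, 42L))
  for (b in seq_len(n_boot)) {
    idx <- sample_family_block(fam_index_list, n)
    Xb <- scale(X[idx, , drop = FALSE])
    Yb <- scale(Y[idx, , drop = FALSE])
    if (anyNA(Xb) || anyNA(Yb)) next   # degenerate resample (constant column)
    nb <- length(idx)
    sv <- svd(crossprod(Xb, Yb) / (nb - 1))
    al <- align_svd(fit$x_weights, sv$u[, seq_len(d), drop = FALSE],
                    sv$v[, seq_len(d), drop = FALSE])
    xl[b, , ] <- stats::cor(Xb, Xb %*% al$u)
    yl[b, , ] <- stats::cor(Yb, Yb %*% al$v)
  }
  sd_x <- apply(xl, c(2L, 3L), stats::sd, na.rm = TRUE)
  sd_y <- apply(yl, c(2L, 3L), stats::sd, na.rm = TRUE)
  res <- list(x_br = fit$x_loadings / sd_x,
              y_br = fit$y_loadings / sd_y,
              x_loadings = fit$x_loadings, y_loadings = fit$y_loadings,
              x_sd = sd_x, y_sd = sd_y)
  dimnames(res$x_br) <- dimnames(fit$x_loadings)
  dimnames(res$y_br) <- dimnames(fit$y_loadings)
  res
}

sub_rows <- function(m, idx) if (is.null(m)) NULL else m[idx, , drop = FALSE]

# Random family-respecting half split balancing subject counts: families are
# shuffled and assigned, largest first, to the currently smaller half.
split_families <- function(fam_index_list) {
  ord <- sample(length(fam_index_list))
  h1 <- integer(0); h2 <- integer(0)
  for (f in ord) {
    if (length(h1) <= length(h2)) h1 <- c(h1, fam_index_list[[f]])
    else h2 <- c(h2, fam_index_list[[f]])
  }
  list(h1, h2)
}

#' Split-half reproducibility of PLSC dimensions
#'
#' Families are randomly divided into two halves. Preprocessing (confound
#' regression if `confounds` is given, standardization otherwise) is fitted
#' on the train half and applied to the test half. The test singular value of
#' dimension d is `u_d' R_test v_d` with train-half weights; weight
#' reproducibility is the |dot product| between train and (aligned)
#' test-half weight vectors. Each quantity's reproducibility Z-score is its
#' mean across splits divided by its SD; Z > 1.95 conventionally indicates a
#' reproducible dimension.
#'
#' @param X,Y Raw (or preprocessed, if `confounds = NULL`) matrices.
#' @param family_ids Family labels, or `NULL` for singleton families.
#' @param n_split Number of random splits (>= 100).
#' @param seed Integer RNG seed.
#' @param confounds Optional confound matrix; fitted on train halves only.
#' @return List with `z_sv`, `z_xweights`, `z_yweights` (d-vectors),
#'   plus the per-split test SV matrix.
#' @export
splithalf_reproducibility <- function(X, Y, family_ids = NULL, n_split = 500L,
                                      seed = 1L, confounds = NULL) {
  if (n_split < 100L) stop("n_split must be >= 100", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(family_ids)) family_ids <- seq_len(n)
  fam_index_list <- split(seq_len(n), family_ids)
  if (max(lengths(fam_index_list)) > n / 2)
    stop("a family larger than half the cohort cannot be split", call. = FALSE)
  d <- min(ncol(X), ncol(Y))
  sv_mat <- matrix(NA_real_, n_split, d)
  xw_mat <- matrix(NA_real_, n_split, d)
  yw_mat <- matrix(NA_real_, n_split, d)
  set.seed(derive_seed(seed, 43L))
  for (s in seq_len(n_split)) {
    halves <- split_families(fam_index_list)
    tr <- halves[[1L]]; te <- halves[[2L]]
    ptr_x <- residualize_and_standardize(X[tr, , drop = FALSE],
                                         sub_rows(confounds, tr))
    ptr_y <- residualize_and_standardize(Y[tr, , drop = FALSE],
                                         sub_rows(confounds, tr))
    Xte <- residualize_and_standardize(X[te, , drop = FALSE],
                                       sub_rows(confounds, te),
                                       ptr_x$params)$matrix
    Yte <- residualize_and_standardize(Y[te, , drop = FALSE],
                                       sub_rows(confounds, te),
                                       ptr_y$params)$matrix
    ftr <- plsc_fit(ptr_x$matrix, ptr_y$matrix)
    R_te <- crossprod(Xte, Yte) / (length(te) - 1)
    sv_mat[s, ] <- vapply(seq_len(d), function(j)
      drop(t(ftr$x_weights[, j]) %*% R_te %*% ftr$y_weights[, j]), numeric(1))
    fte <- svd(R_te)
    al <- align_svd(ftr$x_weights, fte$u[, seq_len(d), drop = FALSE],
                    fte$v[, seq_len(d), drop = FALSE])
    xw_mat[s, ] <- abs(colSums(ftr$x_weights * al$u))
    yw_mat[s, ] <- abs(colSums(ftr$y_weights * al$v))
  }
  zs <- function(m) colMeans(m) / apply(m, 2L, stats::sd)
  list(z_sv = zs(sv_mat), z_xweights = zs(xw_mat), z_yweights = zs(yw_mat),
       test_sv = sv_mat)
}

#' Cross-validated out-of-sample PLSC association
#'
#' Folds respect family blocks. Per fold, preprocessing and PLSC are fitted
#' on the training subjects; test subjects are projected with the training
#' parameters and weights (aligned to the full-data fit). The pooled
#' out-of-fold score pairs give the out-of-sample Spearman correlation per
#' dimension; consistency is the Spearman correlation between pooled
#' out-of-fold scores and the in-sample scores.
#'
#' @param X_raw,Y_raw Raw matrices (n rows).
#' @param confounds Optional confound matrix.
#' @param family_ids Family labels, or `NULL`.
#' @param n_folds Number of folds (>= 2; default 10).
#' @param seed Integer RNG seed.
#' @return List with `oos_correlation` (d-vector), `consistency_x`,
#'   `consistency_y`, `insample_correlation`, and the pooled out-of-fold
#'   scores.
#' @export
cross_validate <- function(X_raw, Y_raw, confounds = NULL, family_ids = NULL,
                           n_folds = 10L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  X_raw <- as.matrix(X_raw); Y_raw <- as.matrix(Y_raw)
  n <- nrow(X_raw)
  if (is.null(family_ids)) family_ids <- seq_len(n)
  fam_index_list <- split(seq_len(n), family_ids)
  full_x <- residualize_and_standardize(X_raw, confounds)
  full_y <- residualize_and_standardize(Y_raw, confounds)
  full_fit <- plsc_fit(full_x$matrix, full_y$matrix)
  d <- length(full_fit$singular_values)
  set.seed(derive_seed(seed, 44L))
  fold_of_family <- rep(seq_len(n_folds),
                        length.out = length(fam_index_list))[
                          sample(length(fam_index_list))]
  fold <- integer(n)
  for (f in seq_along(fam_index_list))
    fold[fam_index_list[[f]]] <- fold_of_family[f]
  oos_x <- matrix(NA_real_, n, d)
  oos_y <- matrix(NA_real_, n, d)
  for (fd in seq_len(n_folds)) {
    te <- which(fold == fd)
    tr <- which(fold != fd)
    if (length(te) == 0L) next
    ptr_x <- residualize_and_standardize(X_raw[tr, , drop = FALSE],
                                         sub_rows(confounds, tr))
    ptr_y <- residualize_and_standardize(Y_raw[tr, , drop = FALSE],
                                         sub_rows(confounds, tr))
    fit <- plsc_fit(ptr_x$matrix, ptr_y$matrix)
    al <- align_svd(full_fit$x_weights, fit$x_weights, fit$y_weights)
    Xte <- residualize_and_standardize(X_raw[te, , drop = FALSE],
                                       sub_rows(confounds, te),
                                       ptr_x$params)$matrix
    Yte <- residualize_and_standardize(Y_raw[te, , drop = FALSE],
                                       sub_rows(confounds, te),
                                       ptr_y$params)$matrix
    oos_x[te, ] <- Xte %*% al$u
    oos_y[te, ] <- Yte %*% al$v
  }
  sp <- function(a, b) stats::cor(a, b, method = "spearman")
  list(oos_correlation = vapply(seq_len(d), function(j)
         sp(oos_x[, j], oos_y[, j]), numeric(1)),
       consistency_x = vapply(seq_len(d), function(j)
         sp(oos_x[, j], full_fit$x_scores[, j]), numeric(1)),
       consistency_y = vapply(seq_len(d), function(j)
         sp(oos_y[, j], full_fit$y_scores[, j]), numeric(1)),
       insample_correlation = full_fit$latent_correlations,
       oos_x_scores = oos_x, oos_y_scores = oos_y)
}

#' Variance of a matrix explained by latent scores
#'
#' Fraction of the squared Frobenius norm of `M` captured by its orthogonal
#' projection onto the column space of `scores`.
#'
#' @param M n x m matrix.
#' @param scores n x d matrix of latent scores (full column rank).
#' @return Scalar fraction in \[0, 1\].
#' @export
variance_explained <- function(M, scores) {
  M <- as.matrix(M); scores <- as.matrix(scores)
  if (sum(M^2) == 0) stop("M has zero norm", call. = FALSE)
  qs <- qr(scores)
  if (qs$rank < ncol(scores))
    stop("scores are not column-independent", call. = FALSE)
  fitted <- qr.fitted(qs, M)
  1 - sum((M - fitted)^2) / sum(M^2)
}
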