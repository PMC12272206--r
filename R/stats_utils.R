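# Shared statistics utilities: two-session ICC, BH-FDR, Spearman correlation.

#' Intraclass correlation between two sessions
#'
#' Test-retest reliability of a per-subject metric measured in two sessions.
#' Default is ICC(2,1): two-way random effects, absolute agreement, single
#' measurement, from the standard ANOVA decomposition. `model = "icc3"`
#' gives ICC(3,1) (two-way mixed, consistency).
#'
#' @param session1,session2 Paired numeric vectors (one value per subject).
#' @param model `"icc2"` (default) or `"icc3"`.
#' @return Scalar ICC in \[-1, 1\]; `NA` when the between-subject variance is
#'   zero (undefined).
#' @export
icc_two_session <- function(session1, session2, model = c("icc2", "icc3")) {
  model <- match.arg(model)
  if (length(session1) != length(session2))
    stop("sessions must be paired", call. = FALSE)
  ok <- is.finite(session1) & is.finite(session2)
  x <- cbind(session1[ok], session2[ok])
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 paired subjects", call. = FALSE)
  k <- 2L
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  if (stats::var(row_means) == 0) return(NA_real_)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (model == "icc2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Per-metric ICC table between two session-level metric tables
#'
#' @param metrics1,metrics2 Data frames with a `subject_id` column and
#'   identical metric columns (session-level run averages).
#' @param model Passed to [icc_two_session()].
#' @return Data frame with columns `metric` and `icc`.
#' @export
icc_table <- function(metrics1, metrics2, model = "icc2") {
  stopifnot(identical(names(metrics1), names(metrics2)),
            identical(metrics1$subject_id, metrics2$subject_id))
  cols <- setdiff(names(metrics1), "subject_id")
  icc <- vapply(cols, function(j)
    icc_two_session(metrics1[[j]], metrics2[[j]], model = model), numeric(1))
  data.frame(metric = cols, icc = icc, row.names = NULL)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with a rejection mask at level `alpha`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns `NA`
#' when either vector has zero rank variance.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Scalar rho, or `NA`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}
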