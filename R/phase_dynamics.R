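# Phase-coherence dynamics: instantaneous phases, cosine coherence matrices,
# and their leading-eigenvector time series.

#' Remove the temporal mean of every region
#'
#' Subtracts the within-row (region) mean from a region-by-time matrix so that
#' the analytic-signal phase is well defined around zero.
#'
#' @param ts Numeric matrix, regions in rows, timepoints in columns.
#' @return Matrix of the same shape with every row mean zero.
#' @examples
#' demean_rows(rbind(c(1, 2, 3), c(5, 5, 5)))
#' @export
demean_rows <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts))
    stop("ts must be a numeric matrix", call. = FALSE)
  if (ncol(ts) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  assert_finite_matrix(ts, "ts")
  ts - rowMeans(ts)
}

# Analytic signal of one real series via the frequency-domain construction:
# zero out negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude by the Hilbert transform
#'
#' Computes the analytic signal of each (demeaned) regional timeseries and
#' returns its argument (phase, radians in (-pi, pi]) and modulus (amplitude).
#' The amplitude is retained for diagnostics only; all downstream coherence
#' computations use the phase.
#'
#' @param ts Numeric region-by-time matrix with (approximately) zero-mean rows.
#' @return An object of class `phase_series`: list with elements `theta` and
#'   `amplitude`, both region-by-time matrices.
#' @export
hilbert_phase <- function(ts) {
  if (!is.matrix(ts)) stop("ts must be a matrix", call. = FALSE)
  if (ncol(ts) < 8L) stop("need at least 8 timepoints", call. = FALSE)
  assert_finite_matrix(ts, "ts")
  zero <- which(rowSums(abs(ts)) == 0)
  if (length(zero) > 0L)
    stop("all-zero row(s) ", paste(zero, collapse = ", "),
         ": phase undefined", call. = FALSE)
  theta <- matrix(NA_real_, nrow(ts), ncol(ts))
  amp <- matrix(NA_real_, nrow(ts), ncol(ts))
  for (i in seq_len(nrow(ts))) {
    a <- analytic_signal(ts[i, ])
    theta[i, ] <- Arg(a)
    amp[i, ] <- Mod(a)
  }
  dimnames(theta) <- dimnames(ts)
  dimnames(amp) <- dimnames(ts)
  structure(list(theta = theta, amplitude = amp), class = "phase_series")
}

#' Instantaneous phase-coherence matrix at one timepoint
#'
#' Entry (i, j) is the cosine of the phase difference between regions i and j:
#' 1 for identical phases (0 degrees), 0 at 90 degrees, -1 at 180 degrees.
#'
#' @param theta_t Numeric vector of phase angles (radians) at one timepoint.
#' @return Symmetric N x N matrix with unit diagonal, entries in \[-1, 1\].
#' @examples
#' phase_coherence_at(c(0, pi / 2, pi))
#' @export
phase_coherence_at <- function(theta_t) {
  if (!is.numeric(theta_t) || any(!is.finite(theta_t)))
    stop("theta_t must be a finite numeric vector", call. = FALSE)
  C <- cos(outer(theta_t, theta_t, "-"))
  C <- (C + t(C)) / 2   # enforce exact symmetry against rounding
  diag(C) <- 1
  C
}

#' Leading eigenvector of a coherence matrix with sign convention
#'
#' Returns the unit-norm eigenvector of the largest eigenvalue. The sign is
#' fixed so that the coherent majority is negative: if strictly more entries
#' are positive than negative the vector is negated; on a tie, the orientation
#' with negative entry-sum is kept (solver orientation if the sum is zero).
#'
#' @param C Symmetric numeric matrix (a phase-coherence matrix).
#' @return List with `vector` (unit N-vector) and `share`, the leading
#'   eigenvalue divided by the sum of absolute eigenvalues.
#' @export
leading_eigenvector <- function(C) {
  if (!is.matrix(C) || !isSymmetric(unname(C), tol = 1e-8))
    stop("C must be a symmetric matrix", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1L]
  npos <- sum(v > 0)
  nneg <- sum(v < 0)
  if (npos > nneg) {
    v <- -v
  } else if (npos == nneg && sum(v) > 0) {
    v <- -v
  }
  share <- e$values[1L] / sum(abs(e$values))
  list(vector = v, share = share)
}

#' Leading-eigenvector series of a regional timeseries
#'
#' Full per-run pipeline stage: demean rows, Hilbert phases, per-timepoint
#' cosine phase-coherence matrix, per-timepoint leading eigenvector. The first
#' and last timepoints are dropped to exclude transform boundary artifacts, so
#' a run of T timepoints yields T - 2 eigenvectors.
#'
#' @param ts Numeric region-by-time matrix (raw signals; demeaned internally).
#' @param filter_fun Optional function applied to the demeaned matrix before
#'   the Hilbert transform (e.g. a bandpass); default `NULL` applies none.
#' @return Object of class `le_series`: list with `vectors` (T-2 by N matrix,
#'   unit rows, majority-nonpositive sign convention), `eigenvalue_share`
#'   (length T-2), and `n_regions`.
#' @export
compute_le_series <- function(ts, filter_fun = NULL) {
  if (!is.matrix(ts)) stop("ts must be a matrix", call. = FALSE)
  if (ncol(ts) < 10L) stop("need at least 10 timepoints", call. = FALSE)
  x <- demean_rows(ts)
  if (!is.null(filter_fun)) x <- filter_fun(x)
  ph <- hilbert_phase(x)
  tt <- ncol(ts)
  keep <- 2L:(tt - 1L)
  n <- nrow(ts)
  vecs <- matrix(NA_real_, length(keep), n)
  share <- numeric(length(keep))
  for (j in seq_along(keep)) {
    le <- leading_eigenvector(phase_coherence_at(ph$theta[, keep[j]]))
    vecs[j, ] <- le$vector
    share[j] <- le$share
  }
  colnames(vecs) <- rownames(ts)
  structure(list(vectors = vecs, eigenvalue_share = share, n_regions = n),
            class = "le_series")
}

#' @export
print.le_series <- function(x, ...) {
  cat(sprintf("<le_series> %d timepoints x %d regions (boundary-trimmed)\n",
              nrow(x$vectors), x$n_regions))
  cat(sprintf("  mean leading-eigenvalue share: %.3f\n",
              mean(x$eigenvalue_share)))
  invisible(x)
}
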