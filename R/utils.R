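#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: keeps every stochastic routine on its own
# stream while remaining a pure function of the master seed. Values stay well
# below 2^31 (R integer range).
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629
  as.integer(s)
}

# Lower median: for even counts take the smaller of the two central order
# statistics, so cluster medians stay on the data lattice.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}

col_lower_medians <- function(m) {
  apply(m, 2L, lower_median)
}

# L1 (Manhattan) distances from each row of `points` to a single vector.
l1_to_point <- function(points, v) {
  rowSums(abs(sweep(points, 2L, v, "-")))
}

assert_finite_matrix <- function(m, what = deparse(substitute(m))) {
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s contains a non-finite value at row %d, column %d",
                 what, bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  invisible(m)
}

# FNV-1a hash of a deparsed R object; used only for provenance stamps in
# pipeline logs, not for cryptographic purposes.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
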