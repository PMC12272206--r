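# Shared test helpers: brute-force oracles and small fixture builders.

# Exhaustive k-medians optimum by enumerating set partitions into at most k
# blocks (restricted-growth strings). Independent of the kmedians()
# implementation: costs are recomputed from scratch with sort()-based lower
# medians.
enum_kmedians_cost <- function(points, k) {
  m <- nrow(points)
  best <- Inf
  labels <- integer(m)
  partition_cost <- function() {
    cost <- 0
    for (j in unique(labels)) {
      cl <- points[labels == j, , drop = FALSE]
      med <- apply(cl, 2L, function(x) sort(x)[(length(x) + 1L) %/% 2L])
      cost <- cost + sum(abs(sweep(cl, 2L, med)))
    }
    cost
  }
  rec <- function(i, maxl) {
    if (i > m) {
      c <- partition_cost()
      if (c < best) best <<- c
      return(invisible(NULL))
    }
    for (l in seq_len(min(maxl + 1L, k))) {
      labels[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  best
}

# Expected leading eigenvector of a planted two-community pattern under the
# majority-negative sign convention.
planted_le <- function(pattern) {
  v <- cos(pattern$offsets)
  -v / sqrt(sum(v^2))
}

# Planted state labels aligned with a boundary-trimmed LE series.
trimmed_true_labels <- function(cohort) {
  unlist(lapply(unlist(cohort$truth$labels, recursive = FALSE),
                function(l) l[2:(length(l) - 1L)]))
}

flat_runs <- function(cohort) unlist(cohort$runs, recursive = FALSE)

run_subject_ids <- function(cohort) {
  rep(names(cohort$runs), lengths(cohort$runs))
}

# Small single-state noiseless cohort whose Hilbert phases recover the
# planted offsets exactly (identity chain, integer carrier cycles).
switch_free_design <- function(n_subjects = 8L, k_true = 3L, seed = 11L,
                               noise_sd = 0, n_runs = 2L) {
  cohort_design(n_subjects = n_subjects, n_runs = n_runs, n_regions = 20L,
                n_timepoints = 150L, k_true = k_true,
                markov_matrix = diag(k_true), noise_sd = noise_sd,
                idio_sd_range = c(0, 0),
                family_sizes = rep(1L, n_subjects), family_sd = 0,
                seed = seed)
}

# Subject-level design-matrix cohorts for the PLSC suites (no timeseries).
null_plsc_design <- function(seed, n = 150L) {
  cohort_design(n_subjects = n, k_true = 4L,
                behavior_weights = matrix(0, 10L, 6L),
                family_sizes = rep(1L, n), family_sd = 0,
                confound_effect = 0, seed = seed)
}

planted_plsc_design <- function(seed, n = 300L) {
  cohort_design(n_subjects = n, k_true = 4L,
                family_sizes = rep(1L, n), family_sd = 0,
                confound_effect = 0, seed = seed)
}

planted_x_direction <- function(n_noise = 4L) {
  alpha <- c(1, 0.8, rep(0, n_noise))
  alpha / sqrt(sum(alpha^2))
}

plsc_matrices <- function(cohort) {
  list(X = scale(cohort$truth$params),
       Y = scale(as.matrix(cohort$behavior[, -1L])))
}
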