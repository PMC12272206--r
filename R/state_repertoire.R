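# Recurring-state identification: k-medians clustering of pooled
# leading-eigenvector series with Manhattan distance.

# L1 k-means++-style seeding: first center uniform, subsequent centers drawn
# with probability proportional to the L1 distance to the nearest chosen
# center.
kmedians_init <- function(points, k) {
  m <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  idx <- sample.int(m, 1L)
  centers[1L, ] <- points[idx, ]
  if (k > 1L) {
    d <- l1_to_point(points, centers[1L, ])
    for (j in 2L:k) {
      if (all(d == 0)) {
        idx <- sample.int(m, 1L)
      } else {
        idx <- sample.int(m, 1L, prob = d)
      }
      centers[j, ] <- points[idx, ]
      if (j < k) d <- pmin(d, l1_to_point(points, centers[j, ]))
    }
  }
  centers
}

kmedians_single <- function(points, k, max_iter) {
  m <- nrow(points)
  medians <- kmedians_init(points, k)
  labels <- integer(m)
  dist_mat <- matrix(NA_real_, m, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) dist_mat[, j] <- l1_to_point(points, medians[j, ])
    new_labels <- max.col(-dist_mat, ties.method = "first")
    # Empty-cluster rule: reseed with the point farthest (L1) from the empty
    # cluster's current median; deterministic (first index on ties).
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(dist_mat[, j])
        new_labels[far] <- j
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      medians[j, ] <- col_lower_medians(points[labels == j, , drop = FALSE])
    }
  }
  cost <- sum(dist_mat[cbind(seq_len(m), labels)])
  list(labels = labels, medians = medians, cost = cost)
}

#' k-medians clustering with Manhattan distance
#'
#' Alternates assignment of points to the nearest median (L1) and
#' coordinate-wise median updates until the labels reach a fixpoint, restarted
#' `n_restarts` times from L1 k-means++-style seeds; the lowest-cost solution
#' is returned. Coordinate medians use the lower median for even counts, so
#' medians stay on the data lattice. Deterministic given `seed`.
#'
#' @param points M x N numeric matrix, one observation per row.
#' @param k Number of clusters (M >= k).
#' @param n_restarts Number of random restarts (default 500, matching the
#'   reference analysis profile).
#' @param max_iter Iteration cap per restart (default 200).
#' @param seed Integer RNG seed.
#' @return List with `labels` (M-vector in 1..k), `medians` (k x N), `cost`
#'   (summed L1 distance of points to their median) and `restart_costs`.
#' @export
kmedians <- function(points, k, n_restarts = 500L, max_iter = 200L, seed = 1L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  assert_finite_matrix(points, "points")
  if (nrow(points) < k)
    stop("need at least k points (M = ", nrow(points), ", k = ", k, ")",
         call. = FALSE)
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  best <- NULL
  restart_costs <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    sol <- kmedians_single(points, k, max_iter)
    restart_costs[r] <- sol$cost
    if (is.null(best) || sol$cost < best$cost) best <- sol
  }
  best$restart_costs <- restart_costs
  best
}

#' Fit a cohort-level state model
#'
#' Pools the leading-eigenvector rows of every run of every subject,
#' clusters them once at cohort level with [kmedians()], and maps the labels
#' back to runs. The per-state coordinate-wise medians are the LE states.
#'
#' @param le_list List of `le_series` objects (or plain T x N matrices), one
#'   per run, in a fixed run order. All runs must share the region count.
#' @param k Number of states.
#' @param n_restarts,max_iter,seed Passed to [kmedians()].
#' @return Object of class `state_model`: `k`, `medians` (k x N),
#'   `total_cost`, `assignments` (list of per-run label vectors, parallel to
#'   `le_list`), `occupancy` (pooled fraction per state), `restart_costs`.
#' @export
fit_state_model <- function(le_list, k, n_restarts = 500L, max_iter = 200L,
                            seed = 1L) {
  mats <- lapply(le_list, function(x) {
    if (inherits(x, "le_series")) x$vectors else as.matrix(x)
  })
  ncols <- vapply(mats, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("region-count mismatch across runs: ",
         paste(unique(ncols), collapse = ", "), call. = FALSE)
  pooled <- do.call(rbind, mats)
  fit <- kmedians(pooled, k, n_restarts = n_restarts, max_iter = max_iter,
                  seed = seed)
  lens <- vapply(mats, nrow, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  assignments <- mapply(function(s, e) fit$labels[s:e], starts, ends,
                        SIMPLIFY = FALSE)
  names(assignments) <- names(le_list)
  structure(list(k = k, medians = fit$medians, total_cost = fit$cost,
                 assignments = assignments,
                 occupancy = as.numeric(table(factor(fit$labels,
                                                     levels = seq_len(k)))) /
                   length(fit$labels),
                 restart_costs = fit$restart_costs),
            class = "state_model")
}

#' Within-cluster cost across a range of k (elbow diagnostics)
#'
#' @param le_list As in [fit_state_model()].
#' @param k_range Integer vector of cluster counts to evaluate.
#' @param n_restarts,seed Passed to [kmedians()].
#' @return Data frame with columns `k` and `cost`, rows in `k_range` order.
#' @export
elbow_curve <- function(le_list, k_range, n_restarts = 20L, seed = 1L) {
  costs <- vapply(seq_along(k_range), function(i) {
    fit_state_model(le_list, k_range[i], n_restarts = n_restarts,
                    seed = derive_seed(seed, 100L + i))$total_cost
  }, numeric(1))
  data.frame(k = k_range, cost = costs)
}

#' Renumber the states of a fitted model
#'
#' By default states are renumbered by descending pooled occurrence, so state
#' 1 is the most frequent (typically the uniform, globally coherent pattern).
#' A user permutation `perm` lists, for each new label, the old label it
#' replaces.
#'
#' @param model A `state_model`.
#' @param order_rule `"occurrence"` or an explicit permutation of `1:k`.
#' @return The relabeled `state_model`.
#' @export
relabel_states <- function(model, order_rule = "occurrence") {
  stopifnot(inherits(model, "state_model"))
  k <- model$k
  if (identical(order_rule, "occurrence")) {
    perm <- order(model$occupancy, decreasing = TRUE)
  } else {
    perm <- as.integer(order_rule)
    if (length(perm) != k || !setequal(perm, seq_len(k)))
      stop("order_rule must be 'occurrence' or a permutation of 1:k",
           call. = FALSE)
  }
  inv <- integer(k)
  inv[perm] <- seq_len(k)   # old label -> new label
  model$medians <- model$medians[perm, , drop = FALSE]
  model$occupancy <- model$occupancy[perm]
  model$assignments <- lapply(model$assignments, function(l) inv[l])
  model
}

#' Per-state mean coherence patterns (dFC states)
#'
#' Recomputes the instantaneous phase-coherence matrices of every run and
#' averages them over the member timepoints of each state, yielding the mean
#' dFC pattern per state.
#'
#' @param runs List of region x time matrices, parallel to the `le_list` used
#'   to fit `model` (same order, full untrimmed runs).
#' @param model Fitted `state_model`.
#' @return Array k x N x N of state-average coherence matrices.
#' @export
state_mean_dfc <- function(runs, model) {
  stopifnot(inherits(model, "state_model"))
  k <- model$k
  n <- nrow(runs[[1L]])
  acc <- array(0, c(k, n, n))
  cnt <- integer(k)
  for (r in seq_along(runs)) {
    ts <- demean_rows(runs[[r]])
    th <- hilbert_phase(ts)$theta
    keep <- 2L:(ncol(ts) - 1L)
    lab <- model$assignments[[r]]
    if (length(lab) != length(keep))
      stop("assignment length does not match trimmed run length", call. = FALSE)
    for (j in seq_along(keep)) {
      s <- lab[j]
      acc[s, , ] <- acc[s, , ] + phase_coherence_at(th[, keep[j]])
      cnt[s] <- cnt[s] + 1L
    }
  }
  for (s in seq_len(k)) {
    acc[s, , ] <- if (cnt[s] > 0L) acc[s, , ] / cnt[s] else NA_real_
  }
  acc
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, total L1 cost = %.3f\n", x$k, x$total_cost))
  cat("  occupancy:", paste(sprintf("%.3f", x$occupancy), collapse = " "), "\n")
  invisible(x)
}
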