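# Per-subject state reconfiguration metrics: frequency (occurrence, dwell,
# transition number, transition probabilities), Manhattan transition
# distances, and idiosyncrasy. Metrics undefined in a run (state never
# visited, switch never observed) are NA and excluded from run averages.

#' State occurrences
#'
#' Fraction of timepoints assigned to each state.
#'
#' @param labels Integer state sequence (values in 1..k).
#' @param k Number of states.
#' @return k-vector summing to 1.
#' @examples
#' occurrences(c(1, 1, 2, 2, 2, 1), 2)
#' @export
occurrences <- function(labels, k) {
  if (length(labels) < 1L) stop("empty label sequence", call. = FALSE)
  if (any(labels < 1L | labels > k)) stop("labels must be in 1..k", call. = FALSE)
  as.numeric(table(factor(labels, levels = seq_len(k)))) / length(labels)
}

#' Mean dwell times
#'
#' Average length (in timepoints) of uninterrupted visits to each state.
#' Visits truncated by run boundaries count as complete visits. States never
#' visited are `NA`.
#'
#' @inheritParams occurrences
#' @return k-vector of mean run lengths (timepoints).
#' @examples
#' dwell_times(c(1, 1, 2, 2, 2, 1), 2)  # 1.5, 3
#' @export
dwell_times <- function(labels, k) {
  if (length(labels) < 1L) stop("empty label sequence", call. = FALSE)
  r <- rle(labels)
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    len <- r$lengths[r$values == s]
    if (length(len) > 0L) out[s] <- mean(len)
  }
  out
}

#' Number of state switches
#'
#' @param labels Integer state sequence of length >= 2.
#' @return Count of consecutive pairs with different labels.
#' @export
transition_number <- function(labels) {
  if (length(labels) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  sum(labels[-1L] != labels[-length(labels)])
}

#' Transition probability matrix
#'
#' Entry (a, b) is the proportion of consecutive pairs starting in state a
#' that move to state b, self-transitions included. Rows of states with no
#' outgoing pair are `NA`.
#'
#' @inheritParams occurrences
#' @return k x k row-stochastic matrix (on defined rows).
#' @export
transition_probabilities <- function(labels, k) {
  if (length(labels) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  from <- factor(labels[-length(labels)], levels = seq_len(k))
  to <- factor(labels[-1L], levels = seq_len(k))
  counts <- table(from, to)
  out <- matrix(NA_real_, k, k)
  rs <- rowSums(counts)
  for (a in seq_len(k)) if (rs[a] > 0L) out[a, ] <- counts[a, ] / rs[a]
  out
}

#' Mean Manhattan distances of state switches
#'
#' Every consecutive pair of leading eigenvectors is categorized by its
#' (from, to) state pair; entry (a, b) is the mean L1 distance over all
#' pairs labeled (a, b). Unobserved switches are `NA`.
#'
#' @param le_vectors T x N matrix of leading eigenvectors (one run, trimmed).
#' @param labels State labels, same length as `nrow(le_vectors)`.
#' @param k Number of states.
#' @return k x k matrix of mean step distances.
#' @export
transition_distances <- function(le_vectors, labels, k) {
  if (inherits(le_vectors, "le_series")) le_vectors <- le_vectors$vectors
  if (nrow(le_vectors) != length(labels))
    stop("le_vectors and labels length mismatch", call. = FALSE)
  tt <- length(labels)
  if (tt < 2L) stop("need at least 2 timepoints", call. = FALSE)
  d <- rowSums(abs(le_vectors[-1L, , drop = FALSE] -
                     le_vectors[-tt, , drop = FALSE]))
  from <- labels[-tt]
  to <- labels[-1L]
  out <- matrix(NA_real_, k, k)
  agg <- tapply(d, list(factor(from, seq_len(k)), factor(to, seq_len(k))), mean)
  out[] <- agg
  out
}

#' State idiosyncrasy
#'
#' Mean Manhattan distance between a subject's leading eigenvectors and the
#' cohort median pattern of the state each timepoint belongs to. States the
#' subject never visits are `NA`.
#'
#' @param le_vectors T x N matrix (one run, trimmed).
#' @param labels State labels for the run.
#' @param group_medians k x N matrix of cohort state medians (from a fitted
#'   [fit_state_model()]).
#' @return k-vector of mean distances.
#' @export
idiosyncrasy <- function(le_vectors, labels, group_medians) {
  if (inherits(le_vectors, "le_series")) le_vectors <- le_vectors$vectors
  if (ncol(le_vectors) != ncol(group_medians))
    stop("region-count mismatch between eigenvectors and medians",
         call. = FALSE)
  k <- nrow(group_medians)
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    member <- labels == s
    if (any(member)) {
      out[s] <- mean(l1_to_point(le_vectors[member, , drop = FALSE],
                                 group_medians[s, ]))
    }
  }
  out
}

#' Reconfiguration profile of a single run
#'
#' @param le_vectors T x N leading-eigenvector matrix for the run (trimmed).
#' @param labels State labels for the run.
#' @param k Number of states.
#' @param group_medians Cohort state medians, for the idiosyncrasy block.
#' @return Object of class `reconfig_profile` with elements `occurrence`,
#'   `dwell`, `transition_number`, `transition_prob`, `transition_dist`,
#'   `idiosyncrasy`. Undefined entries are `NA`.
#' @export
reconfig_profile <- function(le_vectors, labels, k, group_medians) {
  if (inherits(le_vectors, "le_series")) le_vectors <- le_vectors$vectors
  structure(list(
    k = k,
    occurrence = occurrences(labels, k),
    dwell = dwell_times(labels, k),
    transition_number = as.numeric(transition_number(labels)),
    transition_prob = transition_probabilities(labels, k),
    transition_dist = transition_distances(le_vectors, labels, k),
    idiosyncrasy = idiosyncrasy(le_vectors, labels, group_medians)),
    class = "reconfig_profile")
}

#' Average reconfiguration profiles across runs
#'
#' Element-wise mean over the runs in which each metric is defined; a metric
#' undefined in every run stays `NA`.
#'
#' @param profiles Non-empty list of `reconfig_profile` objects (one subject).
#' @return A run-averaged `reconfig_profile`.
#' @export
run_average <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least one run", call. = FALSE)
  if (length(profiles) == 1L) return(profiles[[1L]])
  k <- profiles[[1L]]$k
  avg_field <- function(name) {
    vals <- lapply(profiles, `[[`, name)
    arr <- simplify2array(vals)   # adds a trailing run dimension
    if (is.null(dim(arr))) return(mean(arr, na.rm = TRUE))
    nd <- length(dim(arr))
    out <- apply(arr, seq_len(nd - 1L), function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
    out
  }
  structure(list(
    k = k,
    occurrence = avg_field("occurrence"),
    dwell = avg_field("dwell"),
    transition_number = avg_field("transition_number"),
    transition_prob = avg_field("transition_prob"),
    transition_dist = avg_field("transition_dist"),
    idiosyncrasy = avg_field("idiosyncrasy")),
    class = "reconfig_profile")
}

#' Flatten a profile to the canonical metric vector
#'
#' Canonical order: occurrences (1..k), dwell times (1..k), transition
#' number, transition probabilities (row-major), transition distances
#' (row-major), idiosyncrasy (1..k); total length (2k + 1 + k^2) + k^2 + k.
#' With k = 6 this is 91 metrics, of which 49 are frequency metrics.
#'
#' @param profile A `reconfig_profile` (normally run-averaged).
#' @param k Number of states (defaults to `profile$k`).
#' @return Named numeric vector.
#' @export
metric_vector <- function(profile, k = profile$k) {
  stopifnot(inherits(profile, "reconfig_profile"))
  grid <- expand.grid(to = seq_len(k), from = seq_len(k))[, 2:1]
  v <- c(profile$occurrence,
         profile$dwell,
         profile$transition_number,
         as.vector(t(profile$transition_prob)),
         as.vector(t(profile$transition_dist)),
         profile$idiosyncrasy)
  names(v) <- c(paste0("occ_", seq_len(k)),
                paste0("dwell_", seq_len(k)),
                "trans_number",
                paste0("tp_", grid$from, "_", grid$to),
                paste0("td_", grid$from, "_", grid$to),
                paste0("idio_", seq_len(k)))
  v
}

#' Per-subject reconfiguration metric table
#'
#' Computes per-run profiles from a fitted state model, run-averages them per
#' subject, and flattens to the canonical metric vector. Metrics undefined
#' for a subject across all runs are `NA` (see [impute_metrics()]).
#'
#' @param model Fitted `state_model` whose `assignments` are parallel to
#'   `le_list`.
#' @param le_list The same list of `le_series`/matrices used in the fit.
#' @param subject_ids Character/factor vector, one entry per run, grouping
#'   runs into subjects (order preserved).
#' @return Data frame: `subject_id` plus one column per metric.
#' @export
subject_metric_table <- function(model, le_list, subject_ids) {
  stopifnot(inherits(model, "state_model"))
  if (length(subject_ids) != length(le_list))
    stop("subject_ids must have one entry per run", call. = FALSE)
  k <- model$k
  subjects <- unique(subject_ids)
  rows <- lapply(subjects, function(s) {
    idx <- which(subject_ids == s)
    profs <- lapply(idx, function(r) {
      reconfig_profile(le_list[[r]], model$assignments[[r]], k, model$medians)
    })
    metric_vector(run_average(profs), k)
  })
  tab <- do.call(rbind, rows)
  data.frame(subject_id = subjects, tab, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Impute all-run-missing metrics at the cohort median
#'
#' Metrics a subject never realized in any run (e.g. an unobserved switch)
#' are imputed at the cohort median of that metric, preserving rank
#' structure. Columns missing for every subject are left `NA`.
#'
#' @param metric_table Data frame from [subject_metric_table()].
#' @return Same data frame with an `imputed` attribute counting imputations
#'   per column.
#' @export
impute_metrics <- function(metric_table) {
  num_cols <- names(metric_table)[vapply(metric_table, is.numeric, logical(1))]
  counts <- integer(length(num_cols))
  names(counts) <- num_cols
  for (j in num_cols) {
    miss <- is.na(metric_table[[j]])
    if (any(miss) && !all(miss)) {
      metric_table[[j]][miss] <- stats::median(metric_table[[j]][!miss])
      counts[j] <- sum(miss)
    }
  }
  attr(metric_table, "imputed") <- counts
  metric_table
}

#' Functional connectivity strength and variability
#'
#' Concatenates the instantaneous coherence matrices of all runs and, per
#' upper-triangle connection, computes the mean across time (FC strength) and
#' the standard deviation across time (FC variability), plus their Spearman
#' rank correlation.
#'
#' @param runs List of region x time matrices (raw signals; each run is
#'   demeaned, phase-transformed and boundary-trimmed internally).
#' @return Object of class `strength_variability`: list with `strength`,
#'   `variability` (length N(N-1)/2, upper triangle column-major) and `rho`
#'   (Spearman correlation; `NA` if every connection has zero variance).
#' @export
fc_strength_variability <- function(runs) {
  if (!is.list(runs)) runs <- list(runs)
  n <- nrow(runs[[1L]])
  ut <- upper.tri(matrix(0, n, n))
  s1 <- 0; s2 <- 0; total <- 0L
  for (ts in runs) {
    x <- demean_rows(ts)
    th <- hilbert_phase(x)$theta
    for (t in 2L:(ncol(ts) - 1L)) {
      v <- phase_coherence_at(th[, t])[ut]
      s1 <- s1 + v
      s2 <- s2 + v^2
      total <- total + 1L
    }
  }
  if (total < 2L) stop("need at least 2 timepoints", call. = FALSE)
  mu <- s1 / total
  var_hat <- pmax(0, (s2 - total * mu^2) / (total - 1L))
  sdev <- sqrt(var_hat)
  rho <- if (all(sdev == 0)) NA_real_ else
    stats::cor(mu, sdev, method = "spearman")
  structure(list(strength = mu, variability = sdev, rho = rho),
            class = "strength_variability")
}
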