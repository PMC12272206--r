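# Synthetic cohort generator: planted phase-locking Markov state dynamics,
# subject idiosyncrasy, family blocks, confounds, and behavioral scores with a
# known low-rank association to the subjects' true dynamics parameters.

#' Construct planted two-community phase-locking patterns
#'
#' Each state pattern assigns every region a phase offset of 0 (coherent
#' majority) or pi (anticoherent minority). The minority size is
#' `floor(fraction * n_regions)` (rule: floor, so the minority is always
#' strictly smaller than half). Minority memberships are sampled without
#' replacement across patterns, so different states flag disjoint communities.
#'
#' @param k Number of states.
#' @param n_regions Number of regions.
#' @param minority_fractions Numeric vector of length `k`, each in \[0, 0.5).
#'   A fraction of 0 yields a uniform (all-coherent) pattern.
#' @param seed Integer RNG seed.
#' @return List of `k` objects of class `state_phase_pattern`, each with
#'   `pattern_id`, `offsets` (radians, 0 or pi), `minority` (region indices)
#'   and `minority_fraction`.
#' @export
make_state_phase_patterns <- function(k, n_regions, minority_fractions, seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(minority_fractions) != k)
    stop("minority_fractions must have length k", call. = FALSE)
  if (any(minority_fractions < 0) || any(minority_fractions >= 0.5))
    stop("each minority_fraction must be in [0, 0.5)", call. = FALSE)
  sizes <- floor(minority_fractions * n_regions)
  if (sum(sizes) > n_regions)
    stop("minority communities cannot be disjoint: total minority size ",
         sum(sizes), " exceeds n_regions", call. = FALSE)
  set.seed(derive_seed(seed, 1L))
  pool <- sample.int(n_regions)
  out <- vector("list", k)
  used <- 0L
  for (i in seq_len(k)) {
    offsets <- rep(0, n_regions)
    minority <- integer(0)
    if (sizes[i] > 0L) {
      minority <- sort(pool[(used + 1L):(used + sizes[i])])
      used <- used + sizes[i]
      offsets[minority] <- pi
    }
    out[[i]] <- structure(
      list(pattern_id = i, offsets = offsets, minority = minority,
           minority_fraction = minority_fractions[i]),
      class = "state_phase_pattern")
  }
  out
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
# Reducible chains (e.g. the identity, used for switch-free runs) have no
# unique stationary law; the maximum-entropy uniform start is used then.
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-10)
  if (length(unit) != 1L) return(rep(1 / nrow(P), nrow(P)))
  v <- Re(e$vectors[, unit])
  v / sum(v)
}

check_markov_matrix <- function(P, k = nrow(P)) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || nrow(P) != k)
    stop("markov_matrix must be a k x k matrix", call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("markov_matrix rows must be non-negative and sum to 1", call. = FALSE)
  invisible(P)
}

#' Sample a Markov state-label sequence
#'
#' The chain starts at its stationary distribution.
#'
#' @param P Row-stochastic k x k transition matrix.
#' @param n_timepoints Sequence length.
#' @param seed Integer RNG seed.
#' @return Integer vector of labels in `1..k`.
#' @export
simulate_markov_labels <- function(P, n_timepoints, seed = 1L) {
  check_markov_matrix(P)
  k <- nrow(P)
  set.seed(seed)
  labels <- integer(n_timepoints)
  labels[1L] <- sample.int(k, 1L, prob = stationary_distribution(P))
  for (t in 2L:n_timepoints) {
    labels[t] <- sample.int(k, 1L, prob = P[labels[t - 1L], ])
  }
  labels
}

#' Simulate one run of phase-locked oscillatory signals
#'
#' Region n at timepoint t emits
#' `sin(2 pi f t + offset_state(t)[n] + perturbation[n]) + noise`, with the
#' hidden state sequence drawn from the Markov chain started at its stationary
#' distribution. State labels switch at sample resolution.
#'
#' @param patterns List from [make_state_phase_patterns()].
#' @param markov_matrix Row-stochastic transition matrix over the patterns.
#' @param n_timepoints Run length (>= 10).
#' @param carrier_freq Carrier frequency in cycles per sample, in (0, 0.5).
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param subject_perturbation Per-region phase perturbation (radians); the
#'   planted idiosyncrasy of the simulated subject. Default all zero.
#' @param seed Integer RNG seed.
#' @return List with `timeseries` (region x time matrix) and `labels`.
#' @export
simulate_run <- function(patterns, markov_matrix, n_timepoints, carrier_freq,
                         noise_sd = 0, subject_perturbation = NULL, seed = 1L) {
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10", call. = FALSE)
  if (carrier_freq <= 0 || carrier_freq >= 0.5)
    stop("carrier_freq must be in (0, 0.5) cycles/sample", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  k <- length(patterns)
  n_regions <- length(patterns[[1L]]$offsets)
  if (is.null(subject_perturbation)) subject_perturbation <- rep(0, n_regions)
  if (length(subject_perturbation) != n_regions)
    stop("subject_perturbation length must equal n_regions", call. = FALSE)
  labels <- simulate_markov_labels(markov_matrix, n_timepoints,
                                   seed = derive_seed(seed, 1L))
  offsets <- vapply(patterns, `[[`, numeric(n_regions), "offsets")  # N x k
  tgrid <- seq_len(n_timepoints) - 1L
  phase <- 2 * pi * carrier_freq * matrix(tgrid, n_regions, n_timepoints,
                                          byrow = TRUE)
  phase <- phase + offsets[, labels] + subject_perturbation
  ts <- sin(phase)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 2L))
    ts <- ts + matrix(stats::rnorm(n_regions * n_timepoints, sd = noise_sd),
                      n_regions, n_timepoints)
  }
  rownames(ts) <- paste0("region_", seq_len(n_regions))
  list(timeseries = ts, labels = labels)
}

#' Cohort design for the synthetic generator
#'
#' Bundles and validates every parameter of the synthetic cohort. Defaults
#' describe the reference study conditions used throughout the test suite:
#' 200 subjects in families of two, four runs each (two per session), 20
#' regions, 150 timepoints per run, four planted states on a sticky uniform
#' chain, and ten behavioral scores carrying a rank-1 association with the
#' subjects' true stickiness and idiosyncrasy parameters.
#'
#' @param n_subjects,n_runs,n_regions,n_timepoints Cohort dimensions.
#' @param k_true Number of planted states.
#' @param markov_matrix Base transition matrix; default sticky-uniform with
#'   stay probability 0.95 (mean dwell 20 samples), so that the 1-2 sample
#'   phase transients around state switches occupy a small fraction of a run.
#' @param minority_fractions Per-state anticoherent minority fractions;
#'   default: state 1 uniform, remaining states equal disjoint minorities.
#' @param carrier_freq Carrier in cycles/sample (default 0.04, an integer
#'   number of cycles over the default run length).
#' @param noise_sd Additive signal noise SD (default 0.2).
#' @param idio_sd_range Bounds (radians) of the per-subject phase-perturbation
#'   scale (default `c(0.05, 0.5)`).
#' @param stick_range Bounds of the per-subject mixing weight `w` in the
#'   subject transition matrix `(1 - w) P + w I`; negative values de-stick.
#'   Default `c(-0.4, 0.6)`, spanning subject stay-probabilities of about
#'   0.93-0.98 under the default chain, so dwell and switch-count metrics
#'   vary substantially across subjects while every run still realizes
#'   switches.
#' @param family_sizes Integer block sizes partitioning the cohort; default
#'   families of two.
#' @param family_sd SD of the family-shared random effect on true parameters
#'   (default 0.5; 0 makes subjects exchangeable).
#' @param n_noise_params Number of planted pure-noise subject parameters
#'   appended to the truth matrix (default 4).
#' @param behavior_weights q x m matrix mapping true subject parameters to
#'   behavioral scores. Default: rank-1 weights on (stickiness, idiosyncrasy)
#'   across 10 behaviors. Pass a zero matrix for a null cohort.
#' @param behavior_noise_sd Behavioral noise SD (default 0.5: a strong,
#'   clearly identifiable planted association for recovery testing).
#' @param confound_effect Scalar coefficient of (standardized) age and gender
#'   on both the true parameters and the behaviors (default 0.2).
#' @param seed Master RNG seed.
#' @return Object of class `cohort_design` (a validated list).
#' @export
cohort_design <- function(n_subjects = 200L, n_runs = 4L, n_regions = 20L,
                          n_timepoints = 150L, k_true = 4L,
                          markov_matrix = NULL, minority_fractions = NULL,
                          carrier_freq = 0.04, noise_sd = 0.2,
                          idio_sd_range = c(0.05, 0.5),
                          stick_range = c(-0.4, 0.6),
                          family_sizes = NULL, family_sd = 0.5,
                          n_noise_params = 4L, behavior_weights = NULL,
                          behavior_noise_sd = 0.5, confound_effect = 0.2,
                          seed = 1L) {
  if (is.null(markov_matrix)) {
    p_stay <- 0.95
    markov_matrix <- matrix((1 - p_stay) / (k_true - 1), k_true, k_true)
    diag(markov_matrix) <- p_stay
  }
  check_markov_matrix(markov_matrix, k_true)
  if (is.null(minority_fractions)) {
    f <- floor(n_regions / (2 * max(1L, k_true - 1L))) / n_regions
    f <- min(f, 0.45)
    minority_fractions <- c(0, rep(f, k_true - 1L))
  }
  if (is.null(family_sizes)) {
    n_pairs <- n_subjects %/% 2L
    family_sizes <- c(rep(2L, n_pairs), rep(1L, n_subjects - 2L * n_pairs))
  }
  if (sum(family_sizes) != n_subjects)
    stop("family_sizes must partition the cohort: sum is ", sum(family_sizes),
         ", expected ", n_subjects, call. = FALSE)
  m <- 2L + n_noise_params
  if (is.null(behavior_weights)) {
    b <- seq(0.75, 0.3, length.out = 10L)
    alpha <- c(1, 0.8, rep(0, n_noise_params))
    alpha <- alpha / sqrt(sum(alpha^2))
    behavior_weights <- outer(b, alpha)
  }
  if (ncol(behavior_weights) != m)
    stop("behavior_weights must have ", m, " columns (2 real + ",
         n_noise_params, " noise parameters)", call. = FALSE)
  if (length(idio_sd_range) != 2L || idio_sd_range[1L] > idio_sd_range[2L] ||
      any(idio_sd_range < 0))
    stop("idio_sd_range must be nondecreasing and non-negative", call. = FALSE)
  if (length(stick_range) != 2L || stick_range[1L] > stick_range[2L] ||
      stick_range[2L] >= 1)
    stop("stick_range must be nondecreasing with upper bound < 1",
         call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    k_true = as.integer(k_true), markov_matrix = markov_matrix,
    minority_fractions = minority_fractions, carrier_freq = carrier_freq,
    noise_sd = noise_sd, idio_sd_range = idio_sd_range,
    stick_range = stick_range,
    family_sizes = as.integer(family_sizes), family_sd = family_sd,
    n_noise_params = as.integer(n_noise_params),
    behavior_weights = behavior_weights,
    behavior_noise_sd = behavior_noise_sd,
    confound_effect = confound_effect, seed = as.integer(seed)),
    class = "cohort_design")
}

#' Simulate a full synthetic cohort
#'
#' Generates, per subject: true dynamics parameters (stickiness of the state
#' chain and idiosyncrasy scale, plus planted pure-noise parameters) with a
#' family-shared Gaussian random effect; confounds (age, gender) that
#' linearly shift both the true parameters and the behaviors; behavioral
#' scores `B = params %*% t(behavior_weights) + confounds + noise`; and,
#' optionally, the oscillatory run timeseries driven by each subject's own
#' transition matrix and phase perturbation.
#'
#' A subject's transition matrix is `(1 - w) P + w I`, where `w` is mapped
#' from the subject's stickiness parameter into `stick_range` by a logistic
#' link; mixing toward (or away from) the identity leaves the stationary
#' distribution unchanged, so stickiness moves dwell times and transition
#' counts but not occurrences.
#'
#' @param design A [cohort_design()].
#' @param timeseries If `FALSE`, skip generating run timeseries (subject-level
#'   truth and behavior only); used for statistical calibration studies.
#' @return Object of class `synthetic_cohort`: list with `runs` (per subject,
#'   list of region x time matrices, or `NULL`), `behavior`, `confounds`,
#'   `families` (data frames keyed by `subject_id`), `patterns`, and `truth`
#'   (list with `params` matrix, `idio_scale`, `stickiness_w`, `latent`,
#'   `labels` nested per subject/run).
#' @export
simulate_cohort <- function(design, timeseries = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  n <- d$n_subjects
  m <- 2L + d$n_noise_params
  patterns <- make_state_phase_patterns(d$k_true, d$n_regions,
                                        d$minority_fractions,
                                        seed = derive_seed(d$seed, 11L))

  family_id <- rep(seq_along(d$family_sizes), d$family_sizes)
  set.seed(derive_seed(d$seed, 12L))
  fam_effect <- matrix(stats::rnorm(length(d$family_sizes) * m,
                                    sd = d$family_sd),
                       length(d$family_sizes), m)
  indiv <- matrix(stats::rnorm(n * m), n, m)
  params <- (indiv + fam_effect[family_id, , drop = FALSE]) /
    sqrt(1 + d$family_sd^2)

  # Confounds: HCP-like age range, Bernoulli gender; standardized age enters
  # linearly on both sides.
  set.seed(derive_seed(d$seed, 13L))
  age <- sample(22:36, n, replace = TRUE)
  gender <- stats::rbinom(n, 1L, 0.5)
  std <- function(v) {
    sv <- stats::sd(v)
    if (is.na(sv) || sv == 0) rep(0, length(v)) else (v - mean(v)) / sv
  }
  conf_std <- cbind(age = std(age), gender = gender - mean(gender))
  params <- params + d$confound_effect * (conf_std[, 1L] + conf_std[, 2L])

  colnames(params) <- c("stickiness", "idiosyncrasy",
                        if (d$n_noise_params > 0L)
                          paste0("noise_", seq_len(d$n_noise_params)))

  stick_w <- d$stick_range[1L] +
    diff(d$stick_range) * stats::plogis(params[, "stickiness"])
  idio_scale <- d$idio_sd_range[1L] +
    diff(d$idio_sd_range) * stats::plogis(params[, "idiosyncrasy"])

  set.seed(derive_seed(d$seed, 14L))
  behavior <- params %*% t(d$behavior_weights) +
    d$confound_effect * (conf_std[, 1L] + conf_std[, 2L]) +
    matrix(stats::rnorm(n * nrow(d$behavior_weights),
                        sd = d$behavior_noise_sd),
           n, nrow(d$behavior_weights))
  colnames(behavior) <- paste0("behav_", seq_len(ncol(behavior)))

  latent <- as.numeric(params %*% colSums(d$behavior_weights))

  subject_id <- sprintf("sub_%03d", seq_len(n))
  runs <- NULL
  labels <- NULL
  perturbations <- NULL
  if (timeseries) {
    set.seed(derive_seed(d$seed, 15L))
    perturbations <- matrix(stats::rnorm(n * d$n_regions), n, d$n_regions) *
      idio_scale
    runs <- vector("list", n)
    labels <- vector("list", n)
    names(runs) <- subject_id
    names(labels) <- subject_id
    I_k <- diag(d$k_true)
    for (i in seq_len(n)) {
      P_i <- (1 - stick_w[i]) * d$markov_matrix + stick_w[i] * I_k
      if (any(P_i < 0))
        stop("stick_range incompatible with markov_matrix: negative entries",
             call. = FALSE)
      runs[[i]] <- vector("list", d$n_runs)
      labels[[i]] <- vector("list", d$n_runs)
      for (r in seq_len(d$n_runs)) {
        sim <- simulate_run(patterns, P_i, d$n_timepoints, d$carrier_freq,
                            d$noise_sd, perturbations[i, ],
                            seed = derive_seed(d$seed, 1000L + i * 10L + r))
        runs[[i]][[r]] <- sim$timeseries
        labels[[i]][[r]] <- sim$labels
      }
    }
  }

  structure(list(
    design = d,
    patterns = patterns,
    runs = runs,
    behavior = data.frame(subject_id = subject_id, behavior,
                          stringsAsFactors = FALSE),
    confounds = data.frame(subject_id = subject_id, age = age,
                           gender = gender, stringsAsFactors = FALSE),
    families = data.frame(subject_id = subject_id, family_id = family_id,
                          stringsAsFactors = FALSE),
    truth = list(params = params, stickiness_w = stick_w,
                 idio_scale = idio_scale, latent = latent,
                 labels = labels, perturbations = perturbations)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  d <- x$design
  cat(sprintf("<synthetic_cohort> %d subjects x %d runs, %d regions x %d timepoints, k_true = %d\n",
              d$n_subjects, d$n_runs, d$n_regions, d$n_timepoints, d$k_true))
  cat(sprintf("  timeseries generated: %s\n", !is.null(x$runs)))
  invisible(x)
}
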