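lab6 <- c(1L, 1L, 2L, 2L, 2L, 1L)

test_that("frequency metrics match hand enumeration", {
  expect_equal(occurrences(lab6, 2), c(0.5, 0.5))
  expect_equal(occurrences(rep(1L, 5), 3), c(1, 0, 0))
  expect_error(occurrences(integer(0), 2), "empty")

  expect_equal(dwell_times(lab6, 2), c(1.5, 3))
  expect_equal(dwell_times(rep(2L, 7), 2), c(NA_real_, 7))
  expect_equal(dwell_times(c(1L, 2L, 1L, 2L), 2), c(1, 1))

  expect_equal(transition_number(lab6), 2)
  expect_equal(transition_number(rep(1L, 9)), 0)
  expect_equal(transition_number(c(1L, 2L, 1L, 2L)), 3)
  expect_error(transition_number(1L), "at least 2")

  tp <- transition_probabilities(lab6, 2)
  expect_equal(tp[1, ], c(0.5, 0.5))
  expect_equal(tp[2, ], c(1 / 3, 2 / 3))
  tp3 <- transition_probabilities(rep(1L, 5), 3)
  expect_equal(tp3[1, 1], 1)
  expect_true(all(is.na(tp3[2:3, ])))
  rs <- rowSums(tp)
  expect_equal(rs[!is.na(rs)], c(1, 1))
})

test_that("occurrence times T equals summed run lengths (integer identity)", {
  set.seed(6)
  for (i in 1:20) {
    lab <- sample.int(3, 60, replace = TRUE)
    occ <- occurrences(lab, 3)
    r <- rle(lab)
    for (s in 1:3) {
      expect_equal(occ[s] * 60, sum(r$lengths[r$values == s]))
    }
  }
})

test_that("transition distances average L1 steps by switch type", {
  le <- rbind(c(0, 1), c(1, 0))
  td <- transition_distances(le, c(1L, 2L), 2)
  expect_equal(td[1, 2], 2)
  expect_true(is.na(td[1, 1]))

  le2 <- matrix(1, 5, 3)
  td2 <- transition_distances(le2, rep(1L, 5), 2)
  expect_equal(td2[1, 1], 0)
  expect_error(transition_distances(le, c(1L, 2L, 1L), 2), "mismatch")
})

test_that("idiosyncrasy is the mean L1 distance to the state median", {
  med <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(idiosyncrasy(rbind(c(0, 1, 0)), 1L, med), c(2, NA))
  same <- matrix(rep(c(0, 0, 1), 4), 4, byrow = TRUE)
  expect_equal(idiosyncrasy(same, rep(2L, 4), med), c(NA, 0))
  expect_error(idiosyncrasy(matrix(0, 2, 4), c(1L, 1L), med), "mismatch")
})

test_that("run averaging respects masks", {
  med <- matrix(0, 2, 2)
  mk <- function(le, lab) reconfig_profile(le, lab, 2, med)
  p1 <- mk(rbind(c(0, 1), c(1, 0), c(1, 0)), c(1L, 2L, 2L))
  p2 <- mk(rbind(c(0, 1), c(0, 1), c(1, 0)), c(1L, 1L, 2L))

  expect_identical(run_average(list(p1)), p1)

  avg <- run_average(list(p1, p2))
  expect_equal(avg$transition_number, mean(c(p1$transition_number,
                                             p2$transition_number)))
  # switch 2->2 observed only in run 1; mask excludes run 2 from its average
  expect_equal(avg$transition_dist[2, 2], p1$transition_dist[2, 2])
  # switch 2->1 never observed: stays masked
  expect_true(is.na(avg$transition_dist[2, 1]))

  two <- list(p1, p1)
  two[[1]]$transition_number <- 2; two[[2]]$transition_number <- 4
  expect_equal(run_average(two)$transition_number, 3)
  expect_error(run_average(list()), "at least one")
})

test_that("metric vector has the canonical length and naming", {
  med <- matrix(0, 6, 4)
  lab <- rep(1:6, each = 3)
  le <- matrix(rnorm(18 * 4), 18, 4)
  prof <- reconfig_profile(le, lab, 6, med)
  v <- metric_vector(prof)
  expect_length(v, 91)
  freq_names <- grep("^(occ|dwell|trans_number|tp)", names(v))
  expect_length(freq_names, 49)
  expect_length(grep("^td", names(v)), 36)
  expect_length(grep("^idio", names(v)), 6)
  expect_equal(anyDuplicated(names(v)), 0L)

  prof2 <- reconfig_profile(le[1:6, ], rep(1:2, 3), 2, matrix(0, 2, 4))
  expect_length(metric_vector(prof2), 15)
})

test_that("all 91 metrics are finite when every switch is realized", {
  set.seed(9)
  lab <- sample.int(6, 400, replace = TRUE)
  # guarantee every ordered pair occurs
  pairs <- expand.grid(1:6, 1:6)
  lab <- c(lab, as.integer(t(as.matrix(pairs))))
  le <- matrix(rnorm(length(lab) * 5), length(lab), 5)
  prof <- reconfig_profile(le, lab, 6, matrix(0, 6, 5))
  expect_true(all(is.finite(metric_vector(prof))))
})

test_that("cohort-median imputation fills only all-run-missing metrics", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    m1 = c(1, NA, 3), m2 = c(NA, NA, NA))
  out <- impute_metrics(tab)
  expect_equal(out$m1, c(1, 2, 3))
  expect_true(all(is.na(out$m2)))
  expect_equal(attr(out, "imputed")[["m1"]], 1L)
})

test_that("reciprocal transition distances agree in the cohort mean", {
  des <- cohort_design(n_subjects = 30, n_runs = 2, k_true = 3,
                       n_regions = 20, seed = 37)
  coh <- simulate_cohort(des)
  le <- lapply(flat_runs(coh), compute_le_series)
  model <- fit_state_model(le, 3, n_restarts = 10, seed = 2)
  tabs <- lapply(seq_along(le), function(r)
    transition_distances(le[[r]], model$assignments[[r]], 3))
  arr <- simplify2array(tabs)
  mean_td <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  offdiag <- which(upper.tri(mean_td), arr.ind = TRUE)
  for (i in seq_len(nrow(offdiag))) {
    a <- offdiag[i, 1]; b <- offdiag[i, 2]
    expect_lt(abs(mean_td[a, b] - mean_td[b, a]),
              0.2 * max(mean_td[a, b], mean_td[b, a]))
  }
})

test_that("FC strength and variability behave at the distribution's edges", {
  des <- switch_free_design(n_subjects = 1, k_true = 1, seed = 41,
                            n_runs = 1)
  coh <- simulate_cohort(des)
  sv <- fc_strength_variability(coh$runs[[1]])
  expect_lt(max(sv$variability), 1e-6)
  expect_true(is.na(sv$rho))
  expect_equal(sv$strength, rep(1, 20 * 19 / 2), tolerance = 1e-6)
})

test_that("two-state mixtures give a negative strength-variability correlation", {
  des <- cohort_design(n_subjects = 6, n_runs = 1, k_true = 2,
                       n_regions = 16, minority_fractions = c(0, 0.4),
                       noise_sd = 0.1, idio_sd_range = c(0, 0),
                       family_sizes = rep(1L, 6), family_sd = 0, seed = 53)
  coh <- simulate_cohort(des)
  sv <- fc_strength_variability(flat_runs(coh))
  expect_lt(sv$rho, -0.5)
})
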