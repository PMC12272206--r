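# End-to-end orchestration: simulate or load a cohort, compute
# leading-eigenvector series, fit the state repertoire, derive per-subject
# reconfiguration metrics, and run the full PLSC inference suite.

profile_defaults <- function(profile) {
  switch(profile,
         full = list(n_restarts = 500L, n_perm = 10000L, n_boot = 10000L,
                     n_split = 10000L, n_folds = 10L),
         test = list(n_restarts = 20L, n_perm = 500L, n_boot = 500L,
                     n_split = 500L, n_folds = 5L),
         stop("profile must be 'full' or 'test'", call. = FALSE))
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `design` (arguments for [cohort_design()], or a ready
#' `cohort_design`) and `input_dir` (a directory readable by
#' [read_cohort()]) must be given. The `profile` sets resampling defaults:
#' `"full"` uses 500 clustering restarts and 10,000 permutations /
#' bootstraps / splits with 10 folds; `"test"` scales these to 20 / 500 /
#' 500 / 500 / 5 for desk runtime. Individual counts can be overridden.
#'
#' @param design,input_dir Data source (exactly one non-NULL).
#' @param k Number of states to fit.
#' @param profile `"full"` or `"test"`.
#' @param seed Master seed; every stage derives its own substream.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param ... Overrides for `n_restarts`, `n_perm`, `n_boot`, `n_split`,
#'   `n_folds`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, input_dir = NULL, k = 4L,
                            profile = c("test", "full"), seed = 1L,
                            out_dir = NULL, ...) {
  profile <- match.arg(profile)
  if (is.null(design) == is.null(input_dir))
    stop("exactly one of design / input_dir must be given", call. = FALSE)
  cfg <- profile_defaults(profile)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L)
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  if (any(unlist(cfg) < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (!is.null(design) && !inherits(design, "cohort_design"))
    design <- do.call(cohort_design, design)
  structure(c(list(design = design, input_dir = input_dir, k = as.integer(k),
                   profile = profile, seed = as.integer(seed),
                   out_dir = out_dir), cfg),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `design`
#' mapping holds [cohort_design()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate or load the cohort; per-run leading-eigenvector
#' series; cohort-level k-medians state model, relabeled by descending
#' occurrence; per-subject reconfiguration metric table with cohort-median
#' imputation of all-run-missing metrics; PLSC of metrics vs behavior with
#' age/gender residualization, block permutation test, block bootstrap
#' ratios, split-half reproducibility and cross-validation; per-metric
#' two-session ICC when the run count is even (first half of runs = session
#' 1). Results are returned as a bundle and, when `out_dir` is set, written
#' as delimited-text tables with a provenance log.
#'
#' @param config A `pipeline_config`, or a YAML path.
#' @return List bundle with `model`, `metrics`, `plsc`, `permutation`,
#'   `bootstrap`, `splithalf`, `cv`, `variance_explained`, `icc`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  say("pipeline start: profile=%s seed=%d config_hash=%s", config$profile,
      config$seed, config_hash(config[setdiff(names(config), "out_dir")]))

  # --- stage 1: data -------------------------------------------------------
  if (!is.null(config$design)) {
    cohort <- simulate_cohort(config$design)
    runs_by_subject <- cohort$runs
    behavior <- cohort$behavior
    confounds <- cohort$confounds
    families <- cohort$families
  } else {
    loaded <- read_cohort(config$input_dir)
    cohort <- NULL
    runs_by_subject <- loaded$runs
    behavior <- loaded$behavior
    confounds <- loaded$confounds
    families <- loaded$families
  }
  subject_ids_run <- rep(names(runs_by_subject),
                         lengths(runs_by_subject))
  runs_flat <- unlist(runs_by_subject, recursive = FALSE)
  run_index <- unlist(lapply(runs_by_subject, seq_along))
  say("stage data: %d subjects, %d runs", length(runs_by_subject),
      length(runs_flat))

  # --- stage 2: leading-eigenvector series ---------------------------------
  le_list <- lapply(runs_flat, compute_le_series)
  say("stage le_series: %d vectors x %d regions",
      sum(vapply(le_list, function(x) nrow(x$vectors), integer(1))),
      le_list[[1L]]$n_regions)

  # --- stage 3: state model ------------------------------------------------
  model <- fit_state_model(le_list, config$k, n_restarts = config$n_restarts,
                           seed = derive_seed(config$seed, 3L))
  model <- relabel_states(model, "occurrence")
  say("stage states: k=%d cost=%.3f occupancy=%s", config$k, model$total_cost,
      paste(sprintf("%.3f", model$occupancy), collapse = ","))

  # --- stage 4: reconfiguration metrics ------------------------------------
  metrics <- subject_metric_table(model, le_list, subject_ids_run)
  metrics <- impute_metrics(metrics)
  n_imputed <- sum(attr(metrics, "imputed"))
  say("stage metrics: %d metric columns, %d values imputed at cohort median",
      ncol(metrics) - 1L, n_imputed)

  # --- stage 5: PLSC suite -------------------------------------------------
  stopifnot(identical(metrics$subject_id, behavior$subject_id))
  X_raw <- as.matrix(metrics[, -1L])
  Y_raw <- as.matrix(behavior[, -1L])
  conf <- cbind(age = as.numeric(confounds$age),
                gender = as.numeric(confounds$gender))
  fam <- families$family_id
  sds <- apply(X_raw, 2L, stats::sd)
  keep <- which(!is.na(sds) & sds > 0)
  if (length(keep) < ncol(X_raw))
    say("dropping %d constant or never-observed metric column(s)",
        ncol(X_raw) - length(keep))
  X_raw <- X_raw[, keep, drop = FALSE]
  px <- residualize_and_standardize(X_raw, conf)
  py <- residualize_and_standardize(Y_raw, conf)
  fit <- plsc_fit(px$matrix, py$matrix)
  perm <- permutation_test(px$matrix, py$matrix, fam,
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 51L))
  boot <- bootstrap_ratios(px$matrix, py$matrix, fam,
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, 52L))
  sh <- splithalf_reproducibility(X_raw, Y_raw, fam,
                                  n_split = config$n_split,
                                  seed = derive_seed(config$seed, 53L),
                                  confounds = conf)
  cv <- cross_validate(X_raw, Y_raw, conf, fam, n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 54L))
  ve <- list(x = variance_explained(px$matrix, fit$x_scores[, 1L, drop = FALSE]),
             y = variance_explained(py$matrix, fit$y_scores[, 1L, drop = FALSE]))
  say("stage plsc: dim1 SV=%.4f p=%.4g covexp=%.1f%%",
      fit$singular_values[1L], perm$p_values[1L],
      100 * fit$covariance_explained[1L])

  # --- stage 6: test-retest ICC (even run counts only) ---------------------
  icc <- NULL
  n_runs <- max(run_index)
  if (n_runs >= 2L && n_runs %% 2L == 0L) {
    half <- n_runs %/% 2L
    sess <- function(sel) {
      model_s <- model
      model_s$assignments <- model$assignments[sel]
      subject_metric_table(model_s, le_list[sel], subject_ids_run[sel])
    }
    s1 <- sess(run_index <= half)
    s2 <- sess(run_index > half)
    s1 <- impute_metrics(s1); s2 <- impute_metrics(s2)
    icc <- icc_table(s1, s2)
    say("stage icc: median ICC %.3f over %d metrics",
        stats::median(icc$icc, na.rm = TRUE), nrow(icc))
  }

  bundle <- list(config = config, cohort = cohort, model = model,
                 metrics = metrics, plsc = fit, permutation = perm,
                 bootstrap = boot, splithalf = sh, cv = cv,
                 variance_explained = ve, icc = icc, log = log_lines)

  if (!is.null(config$out_dir)) write_pipeline_bundle(bundle, config$out_dir)
  bundle
}

write_pipeline_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(bundle$metrics, "metrics.tsv")
  med <- data.frame(state = seq_len(bundle$model$k), bundle$model$medians)
  tsv(med, "state_medians.tsv")
  fit <- bundle$plsc
  d <- length(fit$singular_values)
  tsv(data.frame(dimension = seq_len(d),
                 singular_value = fit$singular_values,
                 covariance_explained = fit$covariance_explained,
                 latent_spearman = fit$latent_correlations,
                 perm_p = bundle$permutation$p_values,
                 splithalf_z_sv = bundle$splithalf$z_sv,
                 cv_oos_spearman = bundle$cv$oos_correlation),
      "plsc_summary.tsv")
  tsv(data.frame(metric = rownames(bundle$bootstrap$x_br) %||%
                   seq_len(nrow(bundle$bootstrap$x_br)),
                 bundle$bootstrap$x_br), "bootstrap_ratios_x.tsv")
  tsv(data.frame(behavior = rownames(bundle$bootstrap$y_br) %||%
                   seq_len(nrow(bundle$bootstrap$y_br)),
                 bundle$bootstrap$y_br), "bootstrap_ratios_y.tsv")
  if (!is.null(bundle$icc)) tsv(bundle$icc, "icc.tsv")
  writeLines(bundle$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
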