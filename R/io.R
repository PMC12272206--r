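# Delimited-text serialization of cohorts and result tables. All artifacts
# are plain text: one TSV matrix per run (regions x time, region ids in the
# first column), subject-keyed tables for behavior/confounds/families.

#' Write a synthetic cohort to a directory of delimited-text files
#'
#' Layout: `runs/<subject>_run<r>.tsv` (region x time matrices),
#' `behavior.tsv`, `confounds.tsv`, `families.tsv`, and a structured-text
#' `truth.tsv` sidecar with the per-subject true parameters.
#'
#' @param cohort A `synthetic_cohort` with generated timeseries.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$runs))
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$runs)) {
    for (r in seq_along(cohort$runs[[s]])) {
      write_run_matrix(cohort$runs[[s]][[r]],
                       file.path(dir, "runs", sprintf("%s_run%d.tsv", s, r)))
    }
  }
  tsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cohort$behavior, "behavior.tsv")
  tsv(cohort$confounds, "confounds.tsv")
  tsv(cohort$families, "families.tsv")
  truth <- data.frame(subject_id = cohort$behavior$subject_id,
                      cohort$truth$params,
                      stickiness_w = cohort$truth$stickiness_w,
                      idio_scale = cohort$truth$idio_scale,
                      latent = cohort$truth$latent)
  tsv(truth, "truth.tsv")
  invisible(dir)
}

#' Write one run matrix as delimited text
#'
#' @param ts Region x time numeric matrix with region-id rownames.
#' @param path Output file.
#' @export
write_run_matrix <- function(ts, path) {
  df <- data.frame(region = rownames(ts) %||% paste0("region_", seq_len(nrow(ts))),
                   ts, check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(ts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read one run matrix written by [write_run_matrix()]
#'
#' @param path Input file.
#' @return Region x time numeric matrix with region-id rownames.
#' @export
read_run_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Region identifiers must agree across runs (checked).
#'
#' @param dir Directory path.
#' @return List with `runs` (named per subject, list of matrices),
#'   `behavior`, `confounds`, `families` data frames.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(file.path(dir, "runs"), full.names = TRUE))
  parse <- regmatches(basename(files),
                      regexec("^(.*)_run(\\d+)\\.tsv$", basename(files)))
  subjects <- vapply(parse, `[`, character(1), 2L)
  runs <- list()
  region_ids <- NULL
  for (i in seq_along(files)) {
    m <- read_run_matrix(files[i])
    if (is.null(region_ids)) region_ids <- rownames(m)
    if (!identical(rownames(m), region_ids))
      stop("region ids differ across runs (", basename(files[i]), ")",
           call. = FALSE)
    runs[[subjects[i]]] <- c(runs[[subjects[i]]], list(m))
  }
  list(runs = runs,
       behavior = utils::read.delim(file.path(dir, "behavior.tsv")),
       confounds = utils::read.delim(file.path(dir, "confounds.tsv")),
       families = utils::read.delim(file.path(dir, "families.tsv")))
}
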