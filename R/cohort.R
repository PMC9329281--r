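#' Apply study exclusion criteria to a screening table
#'
#' Retains participants with no cardiovascular disease (`cvd_flag` FALSE)
#' and from White ethnic backgrounds (`ethnicity_white` TRUE), the inclusion
#' rule of the study sample. Counts removed per criterion are reported via
#' `message()`; an empty result is returned with a warning, never an error.
#' The operation is idempotent.
#'
#' @param raw A data frame with at least `cvd_flag` (logical) and
#'   `ethnicity_white` (logical) columns.
#' @return The retained rows, invisibly carrying attributes
#'   `n_excluded_cvd` and `n_excluded_ethnicity`.
#' @export
apply_exclusions <- function(raw) {
  stopifnot(is.data.frame(raw))
  missing <- setdiff(c("cvd_flag", "ethnicity_white"), names(raw))
  if (length(missing)) {
    stop("screening table is missing flag column(s): ",
         paste(missing, collapse = ", "))
  }
  cvd <- as.logical(raw$cvd_flag)
  nonwhite <- !as.logical(raw$ethnicity_white)
  n_cvd <- sum(cvd)
  # sequential accounting: ethnicity exclusions counted among CVD-free rows
  n_eth <- sum(nonwhite & !cvd)
  keep <- !cvd & !nonwhite
  message(sprintf(
    "apply_exclusions: removed %d with cardiovascular disease, %d non-White; %d retained",
    n_cvd, n_eth, sum(keep)))
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all participants excluded; cohort is empty")
  attr(out, "n_excluded_cvd") <- n_cvd
  attr(out, "n_excluded_ethnicity") <- n_eth
  out
}

#' Split a cohort into female and male strata
#'
#' All modelling is sex-stratified; this partitions a cohort table on its
#' `sex` column. The strata are disjoint and exhaustive. An empty stratum
#' is returned (with a warning) so callers can skip fitting for it.
#'
#' @param cohort A data frame with a `sex` column coded `"female"`/`"male"`.
#' @return A named list `list(female = ..., male = ...)` of data frames.
#' @export
split_by_sex <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$sex)) stop("cohort has no 'sex' column")
  sex <- as.character(cohort$sex)
  bad <- setdiff(unique(sex), c("female", "male"))
  if (length(bad)) {
    stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  }
  out <- list(
    female = cohort[sex == "female", , drop = FALSE],
    male = cohort[sex == "male", , drop = FALSE]
  )
  for (s in names(out)) {
    rownames(out[[s]]) <- NULL
    if (nrow(out[[s]]) == 0L) {
      warning("stratum '", s, "' is empty; downstream fitting should skip it")
    }
  }
  out
}

#' Validate a cohort table
#'
#' Checks the per-participant table used throughout the pipeline: unique
#' ids, finite positive ages, strictly positive height (cm) and weight (kg).
#'
#' @param cohort A data frame with columns `participant_id`, `sex`, `age`,
#'   `height`, `weight`.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  required <- c("participant_id", "sex", "age", "height", "weight")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cohort$participant_id)) {
    stop("participant ids are not unique")
  }
  if (!all(is.finite(cohort$age)) || any(cohort$age <= 0)) {
    stop("ages must be finite and positive")
  }
  if (any(!is.finite(cohort$height) | cohort$height <= 0) ||
      any(!is.finite(cohort$weight) | cohort$weight <= 0)) {
    stop("height and weight must be finite and strictly positive")
  }
  invisible(cohort)
}

#' Validate a feature matrix against a cohort and manifest
#'
#' Checks row alignment to the cohort ids and column alignment to the
#' manifest, and drops zero-variance columns with a warning (they carry no
#' information and break standardization).
#'
#' @param features Numeric matrix, rows = participants, columns = features.
#' @param cohort Cohort table whose `participant_id` order the rows follow.
#' @param manifest Optional `feature_manifest`; if supplied, column names
#'   must match its `feature_id`s exactly and in order.
#' @return The (possibly column-reduced) feature matrix.
#' @export
validate_features <- function(features, cohort, manifest = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(cohort)) {
    stop("feature matrix has ", nrow(features), " rows but cohort has ",
         nrow(cohort))
  }
  if (!is.null(manifest)) {
    if (!identical(colnames(features), manifest$feature_id)) {
      stop("feature columns do not align with the manifest")
    }
  }
  v <- apply(features, 2L, stats::var)
  zero <- !is.finite(v) | v <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature column(s): ",
            paste(utils::head(colnames(features)[zero], 5L), collapse = ", "))
    features <- features[, !zero, drop = FALSE]
  }
  features
}
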