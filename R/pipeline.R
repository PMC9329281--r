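#' Run the full heart-age analysis pipeline
#'
#' Orchestrates generate/ingest -> exclusion filtering -> sex
#' stratification -> cross-validated heart-age estimation with bias
#' correction -> feature-age profiling -> PheWAS, writing every stage
#' output plus a run manifest. A single master seed fans out to named
#' sub-seeds (generation = seed, folds = seed + 1) so stages are
#' individually reproducible.
#'
#' @param config A named list, or path to a YAML/JSON file holding one,
#'   with elements:
#'   \describe{
#'     \item{generator}{arguments for [cohort_config()] (synthetic run),
#'       or \code{NULL} when input paths are given;}
#'     \item{cohort,features,exposures,manifest,catalogue}{CSV paths for an
#'       ingest run (features/exposures with a `participant_id` first
#'       column);}
#'     \item{k}{folds (default 10);}
#'     \item{seed}{master seed (default 1);}
#'     \item{mode}{`"paper"` or `"strict"` (default `"paper"`);}
#'     \item{feature_confounds}{default `c("height", "weight")`;}
#'     \item{association_confounds}{default `c("height", "weight", "age")`;}
#'     \item{alpha}{significance level (default 0.05);}
#'     \item{output_dir}{directory for results.}
#'   }
#' @return The run manifest (list), invisibly; written as
#'   `manifest.json` along with `heart_age_results.csv`, `metrics.json`,
#'   `feature_profile_<sex>.csv` and `phewas_<sex>.csv` in `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  k <- config$k %||% 10L
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "paper"
  alpha <- config$alpha %||% 0.05
  stopifnot(alpha > 0, alpha < 1)
  feature_confounds <- config$feature_confounds %||% c("height", "weight")
  assoc_confounds <- config$association_confounds %||%
    c("height", "weight", "age")
  out_dir <- config$output_dir %||% stop("config needs an output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$generator)) {
    sim <- stage("generate", {
      gen <- config$generator
      gen$seed <- gen$seed %||% seed
      sim <- simulate_cohort(do.call(cohort_config, gen))
      message("generated cohort: ", nrow(sim$cohort), " participants")
      sim
    })
    cohort <- sim$cohort
    features <- sim$features
    exposures <- sim$exposures
    manifest <- sim$manifest
    catalogue <- sim$catalogue
  } else if (!is.null(config$cohort)) {
    read_mat <- function(path) {
      df <- utils::read.csv(path, check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      m
    }
    cohort <- stage("ingest", utils::read.csv(config$cohort))
    features <- stage("ingest", read_mat(config$features))
    exposures <- if (!is.null(config$exposures)) {
      stage("ingest", read_mat(config$exposures))
    }
    manifest <- if (!is.null(config$manifest)) {
      stage("ingest", read_manifest(config$manifest))
    } else {
      NULL
    }
    catalogue <- if (!is.null(config$catalogue)) {
      stage("ingest", validate_catalogue(utils::read.csv(config$catalogue)))
    } else {
      default_exposure_catalogue()
    }
  } else {
    stop("config must provide either 'generator' or input paths")
  }

  if (all(c("cvd_flag", "ethnicity_white") %in% names(cohort))) {
    kept <- stage("exclusions", apply_exclusions(cohort))
    i <- match(kept$participant_id, rownames(features))
    features <- features[i, , drop = FALSE]
    if (!is.null(exposures)) exposures <- exposures[i, , drop = FALSE]
    cohort <- kept
  }
  validate_cohort(cohort)

  fit <- stage("heart_age", {
    heart_age(cohort, features, confounds = feature_confounds, k = k,
              seed = seed + 1L, mode = mode)
  })
  message("heart age model fitted: ", nrow(fit$results), " participants")

  utils::write.csv(fit$results,
                   file.path(out_dir, "heart_age_results.csv"),
                   row.names = FALSE)
  metrics_out <- lapply(fit$metrics, function(m) {
    list(corrected = as.list(m$corrected),
         uncorrected = as.list(m$uncorrected), n = m$n)
  })
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  strata <- split_by_sex(cohort)
  counts <- list()
  for (s in names(strata)) {
    st <- strata[[s]]
    counts[[s]] <- nrow(st)
    if (nrow(st) == 0L) next
    idx <- match(st$participant_id, cohort$participant_id)
    res_s <- fit$results[match(st$participant_id,
                               fit$results$participant_id), ]
    prof <- stage(paste0("profile_", s), {
      profile_feature_age(features[idx, , drop = FALSE], res_s$cpha,
                          st[, assoc_confounds, drop = FALSE],
                          manifest = manifest, alpha = alpha)
    })
    utils::write.csv(prof,
                     file.path(out_dir, paste0("feature_profile_", s, ".csv")),
                     row.names = FALSE)
    if (!is.null(exposures)) {
      ph <- stage(paste0("phewas_", s), {
        phewas(res_s$delta, exposures[idx, , drop = FALSE], catalogue,
               st[, assoc_confounds, drop = FALSE], sex = s, alpha = alpha)
      })
      utils::write.csv(ph, file.path(out_dir, paste0("phewas_", s, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest_json <- list(
    config = list(k = k, seed = seed, mode = mode, alpha = alpha,
                  feature_confounds = feature_confounds,
                  association_confounds = assoc_confounds),
    sub_seeds = list(generation = seed, folds = seed + 1L),
    n_participants = nrow(cohort),
    strata = counts,
    n_features = ncol(features),
    n_exposures = if (is.null(exposures)) 0L else ncol(exposures),
    metrics = metrics_out
  )
  jsonlite::write_json(manifest_json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_json)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
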