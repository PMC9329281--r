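# Seed hygiene: run code under a fixed seed without clobbering the caller's
# RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical structure of a simulated study population:
#' sex-stratified cohorts over a configurable age range, a latent aging
#' offset delta (the ground-truth heart-age delta), a radiomics-like
#' feature matrix with age-, sex- and body-size-dependent structure plus
#' low-rank correlated noise, and an exposure table with planted
#' correlations to delta alongside pure nulls.
#'
#' The generative model: biological age `B_i = age_i + delta_i` with
#' `delta_i ~ N(0, sigma_delta^2)`; feature
#' `x_ij = mu_j(sex) + s_j * B_i + h_j * height_i + w_j * weight_i + noise`,
#' where the noise has `latent_rank` shared factors inducing feature
#' intercorrelation plus independent noise; planted exposure
#' `e_ik = c_k * delta_i / sigma_delta + sqrt(1 - c_k^2) * z`, so its
#' population correlation with delta is exactly `c_k`. Null exposures are
#' independent standard normals. Exposures are standardized at generation
#' and planted on delta (not age) because the downstream association study
#' deconfounds age, leaving only the age-orthogonal component as signal.
#'
#' @param n_women,n_men Stratum sizes (defaults: the study's 15,920 women
#'   and 14,076 men).
#' @param age_range Two-element numeric, years (default `c(45, 82)`).
#' @param sigma_delta Standard deviation of the latent aging offset, years.
#' @param manifest Feature manifest defining the feature count and ids.
#' @param latent_rank Number of shared noise factors.
#' @param feature_age_loading_range Uniform range for per-feature loadings
#'   on biological age (per year, on the feature scale).
#' @param confound_loading_range Uniform range for per-feature loadings on
#'   height (per cm) and weight (per kg).
#' @param catalogue Exposure catalogue; defines the exposure table columns.
#' @param planted_effects Named numeric vector mapping catalogue variable
#'   ids to target correlations with delta (in (-1, 1)). Variables absent
#'   from the map are nulls.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_women = 15920L, n_men = 14076L,
                          age_range = c(45, 82), sigma_delta = 5,
                          manifest = default_manifest(),
                          latent_rank = 10L,
                          feature_age_loading_range = c(-0.06, 0.06),
                          confound_loading_range = c(-0.03, 0.03),
                          catalogue = default_exposure_catalogue(),
                          planted_effects = default_planted_effects(catalogue),
                          seed = 1L) {
  stopifnot(n_women >= 0, n_men >= 0, n_women + n_men > 0)
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2],
            age_range[1] > 0)
  stopifnot(sigma_delta >= 0)
  stopifnot(latent_rank >= 0)
  if (diff(feature_age_loading_range) < 0 || diff(confound_loading_range) < 0) {
    stop("loading ranges must be increasing")
  }
  manifest <- validate_manifest(manifest)
  catalogue <- validate_catalogue(catalogue)
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects)))) {
      stop("planted_effects must be a named vector")
    }
    unknown <- setdiff(names(planted_effects), catalogue$variable_id)
    if (length(unknown)) {
      stop("planted effects reference unknown variable(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    if (any(abs(planted_effects) >= 1)) {
      stop("planted target correlations must lie in (-1, 1)")
    }
  }
  structure(list(
    n_women = as.integer(n_women), n_men = as.integer(n_men),
    age_range = as.numeric(age_range), sigma_delta = sigma_delta,
    manifest = manifest, latent_rank = as.integer(latent_rank),
    feature_age_loading_range = feature_age_loading_range,
    confound_loading_range = confound_loading_range,
    catalogue = catalogue, planted_effects = planted_effects,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default planted exposure effects
#'
#' A deterministic map of planted correlations: every fifth catalogue
#' variable carries a correlation with the latent aging offset, with
#' magnitudes cycling through 0.05, 0.10, 0.20, 0.30 and alternating sign,
#' so the generated exposure table mixes clear signals, weak signals and
#' nulls across every category.
#'
#' @param catalogue An `exposure_catalogue`.
#' @return Named numeric vector of target correlations.
#' @export
default_planted_effects <- function(catalogue = default_exposure_catalogue()) {
  idx <- seq(1L, nrow(catalogue), by = 5L)
  mags <- rep_len(c(0.05, 0.10, 0.20, 0.30), length(idx))
  signs <- rep_len(c(1, -1), length(idx))
  stats::setNames(mags * signs, catalogue$variable_id[idx])
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a cohort (demographics + confounds), a feature matrix with the
#' configured age/sex/body-size structure and low-rank correlated noise,
#' and an exposure table with planted and null variables, together with a
#' truth record (`delta_true`, feature age-loadings, planted variable ids)
#' used only by validation code, never by the analysis pipeline.
#'
#' Ages are truncated normal within `age_range` (women: mean 62.7, sd 7.3;
#' men: mean 63.8, sd 7.6); height and weight are sex-specific Gaussians
#' (women 163.7 +/- 6.3 cm, 68 +/- 12.7 kg; men 177.4 +/- 6.6 cm,
#' 83.1 +/- 13.2 kg). Sex-specific exposure variables are `NA` for the
#' non-applicable sex.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_sim` with elements `cohort` (data
#'   frame), `features` (numeric matrix), `exposures` (numeric matrix with
#'   `NA`s where not sex-applicable), `manifest`, `catalogue`, and `truth`
#'   (list: `delta_true`, `feature_age_loadings`, `planted_exposure_ids`,
#'   `planted_targets`).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_women = 50, n_men = 50, seed = 1))
#' dim(sim$features)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_w <- config$n_women
    n_m <- config$n_men
    n <- n_w + n_m
    sex <- c(rep("female", n_w), rep("male", n_m))
    lo <- config$age_range[1]
    hi <- config$age_range[2]
    age <- numeric(n)
    age[sex == "female"] <- rnorm_trunc(n_w, 62.7, 7.3, lo, hi)
    age[sex == "male"] <- rnorm_trunc(n_m, 63.8, 7.6, lo, hi)
    height <- ifelse(sex == "female", stats::rnorm(n, 163.7, 6.3),
                     stats::rnorm(n, 177.4, 6.6))
    weight <- ifelse(sex == "female", stats::rnorm(n, 68, 12.7),
                     stats::rnorm(n, 83.1, 13.2))
    height <- pmax(height, 120)
    weight <- pmax(weight, 35)

    delta <- if (config$sigma_delta > 0) {
      stats::rnorm(n, 0, config$sigma_delta)
    } else {
      numeric(n)
    }
    b_age <- age + delta

    p <- nrow(config$manifest)
    s <- stats::runif(p, config$feature_age_loading_range[1],
                      config$feature_age_loading_range[2])
    h <- stats::runif(p, config$confound_loading_range[1],
                      config$confound_loading_range[2])
    w <- stats::runif(p, config$confound_loading_range[1],
                      config$confound_loading_range[2])
    mu <- stats::rnorm(p, 0, 1)
    sex_shift <- stats::rnorm(p, 0, 0.5)
    r <- config$latent_rank
    noise <- matrix(stats::rnorm(n * p, 0, 1.5), n, p)
    if (r > 0) {
      fac <- matrix(stats::rnorm(n * r), n, r)
      load <- matrix(stats::rnorm(p * r, 0, 0.8), p, r)
      noise <- noise + fac %*% t(load)
    }
    features <- outer(b_age, s) + outer(height, h) + outer(weight, w) +
      matrix(mu, n, p, byrow = TRUE) +
      outer(as.numeric(sex == "male"), sex_shift) + noise
    colnames(features) <- config$manifest$feature_id

    cat_tab <- config$catalogue
    q <- nrow(cat_tab)
    exposures <- matrix(stats::rnorm(n * q), n, q)
    colnames(exposures) <- cat_tab$variable_id
    delta_std <- if (config$sigma_delta > 0) delta / config$sigma_delta else delta
    for (v in names(config$planted_effects)) {
      ck <- config$planted_effects[[v]]
      exposures[, v] <- ck * delta_std + sqrt(1 - ck^2) * exposures[, v]
    }
    exposures[sex == "male", cat_tab$sex_applicability == "female"] <- NA_real_
    exposures[sex == "female", cat_tab$sex_applicability == "male"] <- NA_real_

    ids <- sprintf("P%06d", seq_len(n))
    rownames(features) <- ids
    rownames(exposures) <- ids
    cohort <- data.frame(
      participant_id = ids, sex = sex, age = age,
      height = height, weight = weight,
      cvd_flag = FALSE, ethnicity_white = TRUE,
      stringsAsFactors = FALSE
    )
    validate_cohort(cohort)
    structure(list(
      cohort = cohort, features = features, exposures = exposures,
      manifest = config$manifest, catalogue = cat_tab,
      truth = list(
        delta_true = stats::setNames(delta, ids),
        feature_age_loadings = stats::setNames(s, config$manifest$feature_id),
        planted_exposure_ids = names(config$planted_effects),
        planted_targets = config$planted_effects
      ),
      config = config
    ), class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "participants (",
      sum(x$cohort$sex == "female"), "women /",
      sum(x$cohort$sex == "male"), "men ),",
      ncol(x$features), "features,", ncol(x$exposures), "exposures\n")
  invisible(x)
}

#' Generate a raw screening table for exclusion-filter testing
#'
#' Builds a screening table with exactly the requested number of
#' cardiovascular-disease-flagged and non-White-flagged rows (the flag sets
#' are disjoint, so sequential exclusion counts reconcile exactly) and a
#' sex column. The sex split among rows that survive both exclusions can be
#' fixed so that published stratum sizes are reproducible.
#'
#' @param n_total Total rows.
#' @param n_cvd Rows flagged with cardiovascular disease.
#' @param n_nonwhite Rows flagged non-White (disjoint from the CVD set).
#' @param seed Integer seed.
#' @param n_women_included Number of women among the rows with neither
#'   flag; default splits that group as evenly as possible.
#' @return A data frame with `participant_id`, `sex`, `age`, `height`,
#'   `weight`, `cvd_flag`, `ethnicity_white`.
#' @examples
#' scr <- simulate_screening(100, 5, 3, seed = 1)
#' sum(scr$cvd_flag); sum(!scr$ethnicity_white)
#' @export
simulate_screening <- function(n_total, n_cvd, n_nonwhite, seed = 1L,
                               n_women_included = NULL) {
  stopifnot(n_total >= 0, n_cvd >= 0, n_nonwhite >= 0)
  if (n_cvd + n_nonwhite > n_total) {
    stop("n_cvd + n_nonwhite exceeds n_total")
  }
  n_keep <- n_total - n_cvd - n_nonwhite
  if (is.null(n_women_included)) n_women_included <- n_keep %/% 2L
  if (n_women_included > n_keep) {
    stop("n_women_included exceeds the number of unflagged rows")
  }
  with_seed(seed, {
    cvd <- c(rep(TRUE, n_cvd), rep(FALSE, n_total - n_cvd))
    nonwhite <- c(rep(FALSE, n_cvd), rep(TRUE, n_nonwhite),
                  rep(FALSE, n_keep))
    sex <- character(n_total)
    flagged <- cvd | nonwhite
    sex[flagged] <- sample(c("female", "male"), sum(flagged), replace = TRUE)
    sex[!flagged] <- sample(c(rep("female", n_women_included),
                              rep("male", n_keep - n_women_included)))
    ord <- sample.int(n_total)
    data.frame(
      participant_id = sprintf("S%06d", seq_len(n_total)),
      sex = sex[ord],
      age = round(stats::runif(n_total, 45, 82), 1),
      height = round(stats::rnorm(n_total, 170, 9), 1),
      weight = round(stats::rnorm(n_total, 75, 14), 1),
      cvd_flag = cvd[ord],
      ethnicity_white = !nonwhite[ord],
      stringsAsFactors = FALSE
    )
  })
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `cohort.csv`, `features.csv`, `exposures.csv`, `manifest.csv`,
#' `catalogue.csv` and a `truth.json` sidecar into `dir`.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "features.csv", "exposures.csv",
                            "manifest.csv", "catalogue.csv", "truth.json"))
  utils::write.csv(sim$cohort, paths[1], row.names = FALSE)
  utils::write.csv(data.frame(participant_id = rownames(sim$features),
                              sim$features, check.names = FALSE),
                   paths[2], row.names = FALSE)
  utils::write.csv(data.frame(participant_id = rownames(sim$exposures),
                              sim$exposures, check.names = FALSE),
                   paths[3], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$manifest), paths[4], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$catalogue), paths[5], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[6], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
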