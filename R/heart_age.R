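#' Assign participants to cross-validation folds
#'
#' Seeded uniform random partition into `k` folds with sizes differing by
#' at most one.
#'
#' @param ids Vector of participant ids.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector mapping each id to a fold in `1..k`.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k participants (n = ", n, ", k = ", k, ")")
  if (anyDuplicated(ids)) stop("ids must be unique")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
    stats::setNames(fold, ids)
  })
}

#' Fit the regression-dilution bias correction
#'
#' Age-gap estimators systematically overestimate young ages and
#' underestimate old ones (regression dilution). The correction fits an
#' ordinary-least-squares line of the training-set heart-age delta `D` on
#' actual age `Omega`, `D = alpha * Omega + beta`, whose parameters are
#' later subtracted from held-out predictions.
#'
#' @param delta_train Training-set heart-age deltas (predicted minus
#'   actual age), years.
#' @param age_train Actual ages, years; needs at least 2 distinct values.
#' @return An object of class `bias_correction`: list with `alpha` (slope,
#'   years of delta per year of age) and `beta` (intercept, years).
#' @examples
#' fit_bias_correction(c(2, 0, -2), c(50, 60, 70))  # alpha -0.2, beta 12
#' @export
fit_bias_correction <- function(delta_train, age_train) {
  if (length(delta_train) != length(age_train)) {
    stop("delta and age vectors differ in length")
  }
  if (!all(is.finite(delta_train)) || !all(is.finite(age_train))) {
    stop("inputs must be finite")
  }
  if (length(unique(age_train)) < 2L) {
    stop("ages are constant; bias-correction slope is undefined")
  }
  age_c <- age_train - mean(age_train)
  alpha <- sum(age_c * (delta_train - mean(delta_train))) / sum(age_c^2)
  beta <- mean(delta_train) - alpha * mean(age_train)
  structure(list(alpha = alpha, beta = beta), class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf("Bias correction: delta = %.4f * age + %.4f\n", x$alpha, x$beta))
  invisible(x)
}

#' Apply the bias correction to predictions
#'
#' Corrected predicted heart age:
#' `CPHA = predicted - (alpha * age + beta)`, elementwise.
#'
#' @param predicted Uncorrected predicted heart ages, years.
#' @param age Actual ages, years.
#' @param bc A `bias_correction` fitted on the corresponding training data.
#' @return Corrected predicted heart ages, years.
#' @export
apply_bias_correction <- function(predicted, age, bc) {
  stopifnot(inherits(bc, "bias_correction"))
  if (length(predicted) != length(age)) {
    stop("predicted and age vectors differ in length")
  }
  predicted - (bc$alpha * age + bc$beta)
}

#' Performance metrics for an age-prediction model
#'
#' Computes, for both the corrected (`cpha`) and uncorrected (`predicted`)
#' predictions: mean absolute error (years), coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, Pearson correlation with actual age, and
#' the Pearson correlation of the delta (prediction minus actual age) with
#' actual age — near zero after successful bias correction. Correlations
#' that are undefined (a constant vector) are returned as `NA` with a
#' warning.
#'
#' @param predicted Uncorrected predictions, years.
#' @param cpha Corrected predictions, years.
#' @param actual Actual ages, years.
#' @return A list with elements `corrected` and `uncorrected`, each a named
#'   numeric vector `c(mae, r2, r_pred_age, r_delta_age)`, plus `n`.
#' @export
heart_age_metrics <- function(predicted, cpha, actual) {
  stopifnot(length(predicted) == length(actual),
            length(cpha) == length(actual))
  if (!all(is.finite(actual))) stop("actual ages must be finite")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("correlation undefined for constant vector; returning NA")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  one <- function(pred) {
    ss_tot <- sum((actual - mean(actual))^2)
    r2 <- if (ss_tot == 0) {
      warning("R^2 undefined: actual ages constant")
      NA_real_
    } else {
      1 - sum((actual - pred)^2) / ss_tot
    }
    c(mae = mean(abs(pred - actual)),
      r2 = r2,
      r_pred_age = safe_cor(pred, actual),
      r_delta_age = safe_cor(pred - actual, actual))
  }
  list(corrected = one(cpha), uncorrected = one(predicted),
       n = length(actual))
}

# Cross-validated heart-age estimation for a single sex stratum.
# mode "paper": features arrive residualized+standardized on the full
# stratum (as the published analysis did); mode "strict": raw features,
# residualizer refit inside each training fold (no leakage).
run_cv_stratum <- function(cohort, features, confounds = c("height", "weight"),
                           k = 10L, seed = 1L,
                           mode = c("paper", "strict"), ...) {
  mode <- match.arg(mode)
  n <- nrow(cohort)
  if (n < 2L * k) {
    # every training fold needs >= 2 rows and so does each validation fold
    if (n < k) stop("stratum of ", n, " is smaller than k = ", k)
  }
  fold <- make_folds(cohort$participant_id, k = k, seed = seed)
  if (min(table(fold)) < 2L) {
    stop("a fold has fewer than 2 participants; reduce k")
  }
  age <- cohort$age
  conf <- as.matrix(cohort[, confounds, drop = FALSE])

  if (mode == "paper") {
    res_model <- residualizer(features, conf)
    z <- apply_residualizer(res_model, features, conf)
  }

  predicted <- cpha <- rep(NA_real_, n)
  fold_fits <- vector("list", k)
  fold_bc <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    tr <- !te
    if (mode == "strict") {
      rm_f <- residualizer(features[tr, , drop = FALSE],
                           conf[tr, , drop = FALSE])
      ztr <- apply_residualizer(rm_f, features[tr, , drop = FALSE],
                                conf[tr, , drop = FALSE])
      zte <- apply_residualizer(rm_f, features[te, , drop = FALSE],
                                conf[te, , drop = FALSE])
    } else {
      ztr <- z[tr, , drop = FALSE]
      zte <- z[te, , drop = FALSE]
    }
    fit <- bayes_ridge(ztr, age[tr], ...)
    pred_tr <- predict(fit, ztr)
    bc <- fit_bias_correction(pred_tr - age[tr], age[tr])
    pred_te <- predict(fit, zte)
    predicted[te] <- pred_te
    cpha[te] <- apply_bias_correction(pred_te, age[te], bc)
    fold_fits[[f]] <- fit
    fold_bc[[f]] <- bc
    m <- heart_age_metrics(pred_te, cpha[te], age[te])
    per_fold[[f]] <- data.frame(fold = f, n = sum(te),
                                mae = m$corrected[["mae"]],
                                r2 = m$corrected[["r2"]],
                                alpha = bc$alpha, beta = bc$beta)
  }
  stopifnot(!anyNA(predicted))  # every participant predicted exactly once

  results <- data.frame(
    participant_id = cohort$participant_id,
    age = age,
    fold = as.integer(fold),
    predicted = predicted,
    cpha = cpha,
    delta = cpha - age,
    stringsAsFactors = FALSE
  )
  list(
    results = results,
    metrics = heart_age_metrics(predicted, cpha, age),
    per_fold = do.call(rbind, per_fold),
    fold_fits = fold_fits,
    fold_bias = fold_bc,
    residualizer = if (mode == "paper") res_model else NULL
  )
}

#' Estimate biological heart age with sex-stratified cross-validation
#'
#' The main fitting function. For each sex stratum: residualize body-size
#' confounds from the features and standardize them; split into `k` folds;
#' for each fold, fit the evidence-approximation Bayesian ridge on the
#' other `k - 1` folds with chronological age as the response, fit the
#' regression-dilution bias correction on the training folds' own deltas,
#' and apply model plus correction to the held-out fold. Every participant
#' thus receives exactly one out-of-fold corrected predicted heart age
#' (CPHA); the heart-age delta is `cpha - age` (positive = heart older
#' than its owner). Pooled out-of-fold metrics are reported per stratum;
#' per-fold values are retained in the object.
#'
#' A final model per stratum (ridge on all rows, bias correction on its
#' in-sample deltas) is also fitted so the object can [predict][
#' predict.heart_age] heart age for new participants.
#'
#' @param cohort Cohort table (see [validate_cohort()]).
#' @param features Numeric feature matrix, rows aligned with `cohort`.
#' @param confounds Confound column names regressed out of the features
#'   before modelling (default height and weight).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param mode `"paper"` residualizes and standardizes once on the full
#'   stratum before cross-validation (replicating the published analysis,
#'   which leaks fold information through the standardization moments);
#'   `"strict"` refits the residualizer inside each training fold.
#' @param ... Passed to [bayes_ridge()].
#' @return An object of class `heart_age` with `results` (one row per
#'   participant: id, sex, age, fold, predicted, cpha, delta), `metrics`
#'   (per-sex corrected and uncorrected metric sets), `strata` (per-sex
#'   fold fits, bias corrections, residualizer, final model), `k`, `mode`,
#'   `seed`, `confounds`.
#' @examples
#' sim <- simulate_cohort(cohort_config(
#'   n_women = 120, n_men = 120, manifest = default_manifest(10, 5, 5),
#'   seed = 1))
#' fit <- heart_age(sim$cohort, sim$features, k = 4, seed = 1)
#' summary(fit)
#' @export
heart_age <- function(cohort, features, confounds = c("height", "weight"),
                      k = 10L, seed = 1L, mode = c("paper", "strict"), ...) {
  mode <- match.arg(mode)
  validate_cohort(cohort)
  features <- validate_features(features, cohort)
  missing_conf <- setdiff(confounds, names(cohort))
  if (length(missing_conf)) {
    stop("cohort lacks confound column(s): ",
         paste(missing_conf, collapse = ", "))
  }
  strata <- split_by_sex(cohort)
  out <- list(results = NULL, metrics = list(), strata = list(),
              k = as.integer(k), mode = mode, seed = as.integer(seed),
              confounds = confounds)
  for (s in names(strata)) {
    st <- strata[[s]]
    if (nrow(st) == 0L) next
    idx <- match(st$participant_id, cohort$participant_id)
    cv <- run_cv_stratum(st, features[idx, , drop = FALSE],
                         confounds = confounds, k = k,
                         seed = seed + match(s, names(strata)),
                         mode = mode, ...)
    conf <- as.matrix(st[, confounds, drop = FALSE])
    final_res <- residualizer(features[idx, , drop = FALSE], conf)
    zfull <- apply_residualizer(final_res, features[idx, , drop = FALSE], conf)
    final_fit <- bayes_ridge(zfull, st$age, ...)
    final_bc <- fit_bias_correction(predict(final_fit, zfull) - st$age, st$age)
    cv$results <- cbind(cv$results[1L], sex = s, cv$results[-1L])
    out$results <- rbind(out$results, cv$results)
    out$metrics[[s]] <- cv$metrics
    out$strata[[s]] <- list(
      fold_fits = cv$fold_fits, fold_bias = cv$fold_bias,
      per_fold = cv$per_fold, residualizer = cv$residualizer,
      final_residualizer = final_res, final_fit = final_fit,
      final_bias = final_bc
    )
  }
  if (is.null(out$results)) stop("no non-empty sex stratum to fit")
  rownames(out$results) <- NULL
  class(out) <- "heart_age"
  out
}

#' @export
print.heart_age <- function(x, ...) {
  cat(sprintf("Heart age model: %d participants, k = %d folds, mode = %s\n",
              nrow(x$results), x$k, x$mode))
  for (s in names(x$metrics)) {
    m <- x$metrics[[s]]$corrected
    cat(sprintf("  %-6s n = %-6d MAE %.2f y  R^2 %.3f  r(cpha, age) %.3f  r(delta, age) %+.3f\n",
                s, x$metrics[[s]]$n, m[["mae"]], m[["r2"]],
                m[["r_pred_age"]], m[["r_delta_age"]]))
  }
  invisible(x)
}

#' @export
summary.heart_age <- function(object, ...) {
  rows <- lapply(names(object$metrics), function(s) {
    mc <- object$metrics[[s]]$corrected
    mu <- object$metrics[[s]]$uncorrected
    data.frame(
      sex = s, n = object$metrics[[s]]$n,
      mae = mc[["mae"]], r2 = mc[["r2"]],
      r_pred_age = mc[["r_pred_age"]], r_delta_age = mc[["r_delta_age"]],
      mae_uncorrected = mu[["mae"]], r2_uncorrected = mu[["r2"]],
      r_pred_age_uncorrected = mu[["r_pred_age"]],
      r_delta_age_uncorrected = mu[["r_delta_age"]],
      stringsAsFactors = FALSE
    )
  })
  out <- list(table = do.call(rbind, rows), k = object$k,
              mode = object$mode,
              delta_summary = summary(object$results$delta))
  class(out) <- "summary.heart_age"
  out
}

#' @export
print.summary.heart_age <- function(x, ...) {
  cat(sprintf("Sex-stratified heart age estimation (k = %d, mode = %s)\n",
              x$k, x$mode))
  cat("Pooled out-of-fold metrics (corrected predictions primary):\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("Heart age delta (years):\n")
  print(x$delta_summary)
  invisible(x)
}

#' Extract per-feature weights from a heart-age model
#'
#' @param object A `heart_age` fit.
#' @param which `"final"` (default) returns each stratum's full-data ridge
#'   weights; `"folds"` returns the mean across fold models.
#' @param ... Unused.
#' @return Matrix of weights, features x strata.
#' @export
coef.heart_age <- function(object, which = c("final", "folds"), ...) {
  which <- match.arg(which)
  cols <- lapply(object$strata, function(st) {
    if (which == "final") {
      coef(st$final_fit)
    } else {
      rowMeans(vapply(st$fold_fits, coef,
                      numeric(length(coef(st$final_fit)))))
    }
  })
  do.call(cbind, cols)
}

#' Heart-age deltas
#'
#' @param object A `heart_age` fit.
#' @param ... Unused.
#' @return Named numeric vector of out-of-fold heart-age deltas (years).
#' @export
residuals.heart_age <- function(object, ...) {
  stats::setNames(object$results$delta, object$results$participant_id)
}

#' Predict heart age for new participants
#'
#' Applies each stratum's final model (full-data residualizer, ridge, and
#' bias correction) to new data.
#'
#' @param object A `heart_age` fit.
#' @param cohort New cohort table (needs sex, age, and the confound
#'   columns used at fit).
#' @param features New feature matrix aligned with `cohort`.
#' @param ... Unused.
#' @return Data frame: `participant_id`, `sex`, `age`, `predicted`,
#'   `cpha`, `delta`.
#' @export
predict.heart_age <- function(object, cohort, features, ...) {
  validate_cohort(cohort)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(cohort))
  strata <- split_by_sex(cohort)
  out <- NULL
  for (s in names(strata)) {
    st <- strata[[s]]
    if (nrow(st) == 0L) next
    if (is.null(object$strata[[s]])) {
      stop("model has no fitted stratum for sex '", s, "'")
    }
    idx <- match(st$participant_id, cohort$participant_id)
    conf <- as.matrix(st[, object$confounds, drop = FALSE])
    mod <- object$strata[[s]]
    z <- apply_residualizer(mod$final_residualizer,
                            features[idx, , drop = FALSE], conf)
    pred <- predict(mod$final_fit, z)
    cpha <- apply_bias_correction(pred, st$age, mod$final_bias)
    out <- rbind(out, data.frame(
      participant_id = st$participant_id, sex = s, age = st$age,
      predicted = pred, cpha = cpha, delta = cpha - st$age,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Plot predicted versus actual age
#'
#' Scatter of corrected predicted heart age against chronological age per
#' sex, with the identity line.
#'
#' @param x A `heart_age` fit.
#' @param which `"cpha"` (default) or `"predicted"` (uncorrected).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.heart_age <- function(x, which = c("cpha", "predicted"), ...) {
  which <- match.arg(which)
  r <- x$results
  col <- ifelse(r$sex == "female", "#D55E00", "#0072B2")
  graphics::plot(r$age, r[[which]], col = col, pch = 16, cex = 0.4,
                 xlab = "Actual age (years)",
                 ylab = if (which == "cpha") {
                   "Corrected predicted heart age (years)"
                 } else {
                   "Predicted heart age (years)"
                 }, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("female", "male"), bty = "n",
                   col = c("#D55E00", "#0072B2"), pch = 16)
  invisible(x)
}
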