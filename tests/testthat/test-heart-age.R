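test_that("fold assignment is a balanced seeded partition", {
  f1 <- make_folds(paste0("p", 1:10), k = 10, seed = 1)
  expect_setequal(unname(f1), 1:10)  # singleton folds
  f2 <- make_folds(paste0("p", 1:25), k = 10, seed = 2)
  sizes <- sort(as.integer(table(f2)))
  expect_equal(sizes, c(rep(2L, 5), rep(3L, 5)))
  expect_identical(make_folds(paste0("p", 1:25), k = 10, seed = 2), f2)
  expect_error(make_folds(paste0("p", 1:5), k = 10), "at least k")
  expect_error(make_folds(paste0("p", 1:5), k = 1), "at least 2")
})

test_that("bias-correction line matches the least-squares oracle", {
  bc <- fit_bias_correction(c(2, 0, -2), c(50, 60, 70))
  expect_equal(bc$alpha, -0.2, tolerance = 1e-12)
  expect_equal(bc$beta, 12, tolerance = 1e-12)
  # perfect model: nothing to correct
  bc0 <- fit_bias_correction(c(0, 0, 0), c(50, 60, 70))
  expect_equal(bc0$alpha, 0)
  expect_equal(bc0$beta, 0)
  expect_error(fit_bias_correction(c(1, 2), c(60, 60)), "constant")
})

test_that("age-independent deltas give a slope within sampling noise", {
  set.seed(5)
  n <- 5000
  age <- runif(n, 45, 82)
  delta <- rnorm(n, 0, 3)
  bc <- fit_bias_correction(delta, age)
  se <- 3 / (sd(age) * sqrt(n))
  expect_lt(abs(bc$alpha), 3 * se)
})

test_that("bias correction applies the fitted line elementwise", {
  bc <- structure(list(alpha = -0.3, beta = 19), class = "bias_correction")
  expect_equal(apply_bias_correction(70, 60, bc), 69)
  id <- structure(list(alpha = 0, beta = 0), class = "bias_correction")
  expect_equal(apply_bias_correction(c(63, 71), c(60, 70), id), c(63, 71))
  # correcting the training data itself removes the age dependency exactly
  set.seed(8)
  age <- runif(200, 45, 82)
  pred <- 0.5 * age + 30 + rnorm(200, 0, 2)
  bc2 <- fit_bias_correction(pred - age, age)
  corrected_delta <- apply_bias_correction(pred, age, bc2) - age
  expect_lt(abs(cor(corrected_delta, age)), 1e-8)
})

test_that("metric set matches hand-computed values and flags degeneracy", {
  expect_warning(
    m <- heart_age_metrics(c(61, 59), c(61, 59), c(60, 60)),
    "constant"
  )
  expect_equal(unname(m$corrected[["mae"]]), 1)
  expect_true(is.na(m$corrected[["r_pred_age"]]))
  expect_warning(
    mp <- heart_age_metrics(c(50, 60, 65, 75), c(50, 60, 65, 75),
                            c(50, 60, 65, 75)),
    "constant"
  )
  expect_equal(unname(mp$corrected[["mae"]]), 0)
  expect_equal(unname(mp$corrected[["r2"]]), 1)
  expect_equal(unname(mp$corrected[["r_pred_age"]]), 1)
  expect_true(is.na(mp$corrected[["r_delta_age"]]))  # delta constant at 0
  m2 <- heart_age_metrics(c(52, 58, 66, 72), c(52, 58, 66, 72),
                          c(50, 60, 65, 75))
  expect_equal(unname(m2$corrected[["mae"]]), 2)  # mean of |2, -2, 1, -3|
})

test_that("fully age-determined features give near-perfect recovery", {
  # noiseless features proportional to age; the only residual error is
  # the (O(1/sqrt(n))) age variance removed with the body-size confounds
  sim <- quiet(simulate_cohort(cohort_config(
    n_women = 3000, n_men = 0, sigma_delta = 0,
    manifest = small_manifest(), latent_rank = 0,
    feature_age_loading_range = c(0.5, 1),
    confound_loading_range = c(0, 0),
    catalogue = small_catalogue(), planted_effects = NULL, seed = 21
  )))
  x <- outer(sim$cohort$age, sim$truth$feature_age_loadings)
  colnames(x) <- names(sim$truth$feature_age_loadings)
  fit <- quiet(heart_age(sim$cohort, x, k = 10, seed = 3))
  m <- fit$metrics$female$corrected
  expect_lt(m[["mae"]], 0.2)
  expect_gt(m[["r2"]], 0.99)
})

test_that("shuffled ages carry no signal", {
  sim <- quiet(simulate_cohort(cohort_config(
    n_women = 5000, n_men = 0, manifest = small_manifest(),
    catalogue = small_catalogue(), planted_effects = NULL, seed = 22
  )))
  coh <- sim$cohort
  set.seed(99)
  coh$age <- sample(coh$age)
  fit <- quiet(heart_age(coh, sim$features, k = 10, seed = 4))
  m <- fit$metrics$female
  expect_lt(abs(m$uncorrected[["r_pred_age"]]), 0.05)
  # uncorrected R^2 is at or below zero for a signal-free predictor; the
  # corrected R^2 is uninformative here (with no signal the fitted bias
  # line has slope ~ -1 and the correction reconstructs age trivially)
  expect_lt(m$uncorrected[["r2"]], 0.02)
})

test_that("every participant receives exactly one out-of-fold prediction", {
  sim <- small_sim(n_women = 80, n_men = 70, seed = 23)
  fit <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = 5))
  expect_setequal(fit$results$participant_id, sim$cohort$participant_id)
  expect_equal(anyDuplicated(fit$results$participant_id), 0L)
  expect_equal(fit$results$delta, fit$results$cpha - fit$results$age)
  expect_equal(sort(unique(fit$results$fold)), 1:5)
  # strata sum to total
  expect_equal(sum(fit$results$sex == "female"), 80)
  expect_equal(sum(fit$results$sex == "male"), 70)
})

test_that("paper and strict deconfounding modes differ but both work", {
  sim <- small_sim(n_women = 200, n_men = 0, seed = 24)
  fp <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = 6,
                        mode = "paper"))
  fs <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = 6,
                        mode = "strict"))
  expect_false(identical(fp$results$cpha, fs$results$cpha))
  expect_equal(fp$mode, "paper")
  expect_equal(fs$mode, "strict")
  expect_lt(abs(cor(fp$results$cpha, fs$results$cpha) - 1), 0.05)
})

test_that("estimated delta tracks the latent truth, improving with signal", {
  cors <- vapply(c(0.02, 0.06, 0.15), function(hi) {
    sim <- quiet(simulate_cohort(cohort_config(
      n_women = 800, n_men = 0, manifest = small_manifest(),
      feature_age_loading_range = c(-hi, hi),
      catalogue = small_catalogue(), planted_effects = NULL, seed = 25
    )))
    fit <- quiet(heart_age(sim$cohort, sim$features, k = 10, seed = 7))
    cor(fit$results$delta,
        sim$truth$delta_true[fit$results$participant_id])
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))  # monotone in feature signal-to-noise
})

test_that("training MAE bounds validation MAE on average", {
  diffs <- vapply(1:10, function(s) {
    sim <- quiet(simulate_cohort(cohort_config(
      n_women = 250, n_men = 0, manifest = small_manifest(),
      catalogue = small_catalogue(), planted_effects = NULL, seed = 30 + s
    )))
    fit <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = s))
    st <- fit$strata$female
    train_mae <- mean(vapply(st$fold_fits, function(f) {
      mean(abs(residuals(f)))
    }, numeric(1)))
    val_mae <- fit$metrics$female$uncorrected[["mae"]]
    val_mae - train_mae
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the fitted object supports prediction on new participants", {
  sim <- small_sim(n_women = 150, n_men = 150, seed = 26)
  fit <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = 8))
  new_sim <- small_sim(n_women = 30, n_men = 30, seed = 27)
  pred <- quiet(predict(fit, new_sim$cohort, new_sim$features))
  expect_equal(nrow(pred), 60)
  expect_true(all(is.finite(pred$cpha)))
  expect_equal(pred$delta, pred$cpha - pred$age)
  # coefficient matrix spans both strata
  w <- coef(fit)
  expect_equal(dim(w), c(ncol(sim$features), 2L))
})
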