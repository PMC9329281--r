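test_that("pearson correlation and p-value match closed-form cases", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  pr <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pr$r, 0.8, tolerance = 1e-12)
  # cross-check p against the t-distribution reference implementation
  ref <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pr$p, ref$p.value, tolerance = 1e-10)
  # perfect self-correlation sits at the numerical floor
  self <- pearson_with_p(c(1, 5, 2, 8), c(1, 5, 2, 8))
  expect_equal(self$r, 1)
  expect_lt(self$p, 1e-12)  # numerical floor, never exactly zero
  expect_gt(self$p, 0)
})

test_that("pearson flags degenerate inputs instead of erroring", {
  out <- pearson_with_p(c(1, 1, 1), c(1, 2, 3))
  expect_false(out$ok)
  expect_true(is.na(out$r))
  # pairwise complete-case filtering
  pr <- pearson_with_p(c(1, 2, 3, 4, NA), c(1, 3, 2, 4, 10))
  expect_equal(pr$n_used, 4)
  expect_equal(pr$r, 0.8, tolerance = 1e-12)
})

test_that("bonferroni correction multiplies within the family and caps", {
  expect_equal(bonferroni_p(0.001, 16), 0.016)
  expect_equal(bonferroni_p(0.2, 254), 1)
  # boundary: exactly 0.05 is not significant under strict <
  expect_equal(bonferroni_p(0.05 / 254, 254), 0.05)
  expect_false(bonferroni_p(0.05 / 254, 254) < 0.05)
  expect_error(bonferroni_p(0.01, 0), "at least 1")
  # monotone in p within a family; capping never flips significance
  p <- sort(runif(20))
  pc <- bonferroni_p(p, 7)
  expect_true(all(diff(pc) >= 0))
  expect_equal(pc < 0.05, (p * 7) < 0.05)
})

test_that("feature profiling ranks planted age-linked features on top", {
  set.seed(301)
  n <- 5000
  age <- runif(n, 45, 82)
  height <- rnorm(n, 170, 7)
  weight <- rnorm(n, 75, 13)
  heart <- age + rnorm(n, 0, 4)
  p_signal <- 20
  p_null <- 30
  x <- cbind(
    outer(heart, runif(p_signal, 0.05, 0.1)) +
      matrix(rnorm(n * p_signal), n, p_signal),
    matrix(rnorm(n * p_null), n, p_null)
  )
  colnames(x) <- c(sprintf("sig_%02d", 1:p_signal),
                   sprintf("null_%02d", 1:p_null))
  prof <- profile_feature_age(x, heart, cbind(height, weight, age))
  expect_equal(nrow(prof), 50)
  expect_true(all(prof$m == 50))
  top <- prof$variable[seq_len(p_signal)]
  expect_setequal(top, sprintf("sig_%02d", 1:p_signal))
  expect_equal(prof$rank, seq_len(nrow(prof)))
})

test_that("profiling an independent target stays within family error control", {
  set.seed(302)
  hits <- vapply(1:200, function(i) {
    n <- 120
    x <- matrix(rnorm(n * 10), n, 10)
    colnames(x) <- paste0("f", 1:10)
    target <- rnorm(n)
    conf <- cbind(height = rnorm(n, 170, 7), weight = rnorm(n, 75, 13),
                  age = runif(n, 45, 82))
    prof <- profile_feature_age(x, target, conf)
    any(prof$significant, na.rm = TRUE)
  }, logical(1))
  # FWER <= 0.05 with binomial slack at 200 replicates
  expect_lte(mean(hits), 0.05 + 2.6 * sqrt(0.05 * 0.95 / 200))
})

test_that("a single-feature family leaves the p-value uncorrected", {
  set.seed(303)
  n <- 200
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "only"))
  target <- rnorm(n)
  conf <- cbind(height = rnorm(n, 170, 7), weight = rnorm(n, 75, 13),
                age = runif(n, 45, 82))
  prof <- profile_feature_age(x, target, conf)
  expect_equal(prof$p_corrected, prof$p_raw)
})

test_that("manifest metadata is carried into the profile", {
  sim <- small_sim(n_women = 200, n_men = 0, seed = 31)
  fit <- quiet(heart_age(sim$cohort, sim$features, k = 5, seed = 9))
  prof <- profile_feature_age(
    sim$features, fit$results$cpha,
    sim$cohort[, c("height", "weight", "age")],
    manifest = sim$manifest
  )
  expect_true(all(c("category", "region") %in% names(prof)))
  expect_setequal(unique(prof$category),
                  c("shape", "first_order", "texture"))
})

test_that("phewas respects sex applicability and per-category families", {
  sim <- small_sim(n_women = 300, n_men = 300, seed = 32)
  fem <- sim$cohort$sex == "female"
  # ground-truth delta isolates the catalogue contract from model noise
  delta_f <- sim$truth$delta_true[sim$cohort$participant_id[fem]]
  ph <- phewas(delta_f, sim$exposures[fem, ], sim$catalogue,
               sim$cohort[fem, c("age", "height", "weight")],
               sex = "female")
  # male-specific variables absent; female-specific present
  expect_false(any(grepl("^M_", ph$variable)))
  expect_true(any(grepl("^F_", ph$variable)))
  # family size = category size for that sex
  expect_true(all(ph$m[ph$category == "A"] == 10))
  expect_true(all(ph$m[ph$category == "Female specific"] == 6))
  # deconfounding makes the exposure age-orthogonal, so the planted
  # delta-linked variable survives age adjustment and is detected
  expect_true(ph$significant[ph$variable == "A_01"])
  expect_equal(ph$rank[ph$variable == "A_01"], 1L)
})

test_that("planted exposures are recovered at the attenuated correlation", {
  sim <- quiet(simulate_cohort(cohort_config(
    n_women = 5000, n_men = 0, manifest = small_manifest(),
    catalogue = small_catalogue(),
    planted_effects = c(A_01 = 0.3), seed = 33
  )))
  fit <- quiet(heart_age(sim$cohort, sim$features, k = 10, seed = 11))
  res <- fit$results[match(sim$cohort$participant_id,
                           fit$results$participant_id), ]
  attenuation <- cor(res$delta, sim$truth$delta_true)
  ph <- phewas(res$delta, sim$exposures, sim$catalogue,
               sim$cohort[, c("age", "height", "weight")], sex = "female")
  row <- ph[ph$variable == "A_01", ]
  expect_true(row$significant)
  expect_lt(abs(row$r - 0.3 * attenuation), 0.05)
})

test_that("an all-null catalogue keeps per-category FWER at the nominal level", {
  set.seed(304)
  n <- 400
  cat40 <- small_catalogue(sizes = c(A = 10L, B = 10L, C = 10L, D = 10L),
                           n_female = 0L, n_male = 0L)
  fails <- matrix(NA, 200, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  for (i in 1:200) {
    delta <- rnorm(n, 0, 5)
    exposures <- matrix(rnorm(n * 40), n, 40,
                        dimnames = list(NULL, cat40$variable_id))
    conf <- cbind(age = runif(n, 45, 82), height = rnorm(n, 165, 6),
                  weight = rnorm(n, 70, 12))
    ph <- phewas(delta, exposures, cat40, conf, sex = "female")
    fails[i, ] <- vapply(c("A", "B", "C", "D"), function(g) {
      any(ph$significant[ph$category == g], na.rm = TRUE)
    }, logical(1))
  }
  fwer <- colMeans(fails)
  tol <- 2.6 * sqrt(0.05 * 0.95 / 200)
  expect_true(all(fwer <= 0.05 + tol))
})

test_that("variables below the minimum usable n are flagged not evaluable", {
  set.seed(305)
  n <- 300
  cat3 <- small_catalogue(sizes = c(A = 2L), n_female = 0L, n_male = 0L)
  exposures <- matrix(rnorm(n * 2), n, 2,
                      dimnames = list(NULL, cat3$variable_id))
  exposures[1:250, 2] <- NA  # only 50 usable values
  delta <- rnorm(n, 0, 5)
  conf <- cbind(age = runif(n, 45, 82), height = rnorm(n, 165, 6),
                weight = rnorm(n, 70, 12))
  ph <- phewas(delta, exposures, cat3, conf, sex = "female")
  expect_false(ph$evaluable[ph$variable == "A_02"])
  expect_true(is.na(ph$r[ph$variable == "A_02"]))
  # non-evaluable rows rank last
  expect_equal(ph$rank[ph$variable == "A_02"], 2L)
})
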