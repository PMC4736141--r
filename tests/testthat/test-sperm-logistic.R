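test_that("outcome independent of x gives the symmetric null fit", {
  fit <- fit_logistic(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$slope, 0, tolerance = 1e-8)
  expect_equal(predict_prob(fit, c(-2, 0, 7)), rep(0.5, 3),
               tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 4, tolerance = 1e-12)
})

test_that("perfect separation is flagged, not returned as garbage", {
  fit <- fit_logistic(1:4, c(0, 0, 1, 1))
  expect_false(fit$converged)
  expect_error(predict_prob(fit, 2), "converge")
  expect_error(invert_threshold(fit, 0.99), "converge")
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_logistic(1:4, c(1, 1, 1, 1)), "no outcome variation")
  expect_error(fit_logistic(1:2, c(0, 1)), "at least 3")
})

test_that("IRLS estimates match the brute-force likelihood oracle", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 50
    x <- runif(n, 0, 6)
    y <- rbinom(n, 1, plogis(-3 + 1.2 * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(x, y)
    if (!fit$converged) next
    oracle <- brute_force_logistic(x, y)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-4)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-4)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("pseudo-R2 measures stay on their scales", {
  set.seed(5)
  x <- runif(60, 0, 6)
  y <- rbinom(60, 1, plogis(-3 + 1.2 * x))
  fit <- fit_logistic(x, y)
  r2 <- fit$pseudo_r2
  expect_true(r2$mcfadden >= 0 && r2$mcfadden < 1)
  expect_true(r2$nagelkerke >= 0 && r2$nagelkerke <= 1)
  expect_true(r2$tjur >= 0 && r2$tjur <= 1)
  expect_true(fit$p_wald_slope > 0 && fit$p_wald_slope <= 1)
})

test_that("predict_prob and invert_threshold are exact inverses", {
  # closed-form landmarks of the unit logistic
  unit <- fit_logistic(c(-6, -3, -1, 1, 3, 6, -2, 2),
                       c(0, 0, 0, 1, 1, 1, 1, 0))
  expect_equal(predict_prob(unit, 0), plogis(unit$intercept))
  manual <- structure(list(predictor = "x", intercept = 0, slope = 1,
                           se_intercept = 1, se_slope = 1,
                           p_wald_slope = 0.5, loglik = -1, aic = 6,
                           pseudo_r2 = list(), n = 8, converged = TRUE),
                      class = "sperm_logistic_fit")
  expect_equal(predict_prob(manual, 0), 0.5, tolerance = 1e-12)
  expect_equal(predict_prob(manual, log(99)), 0.99, tolerance = 1e-12)
  expect_equal(invert_threshold(manual, 0.5), 0, tolerance = 1e-12)
  expect_equal(invert_threshold(manual, 0.99), log(99), tolerance = 1e-12)
  expect_equal(round(invert_threshold(manual, 0.99), 5), 4.59512)
  shifted <- manual
  shifted$intercept <- -3
  expect_equal(predict_prob(shifted, 3), 0.5, tolerance = 1e-12)
  # round trip at the three working probabilities, on a real fit
  for (p in c(0.01, 0.5, 0.99))
    expect_equal(predict_prob(unit, invert_threshold(unit, p)), p,
                 tolerance = 1e-9)
  zero <- manual
  zero$slope <- 0
  expect_error(invert_threshold(zero, 0.5), "slope")
})

test_that("threshold pairs are ordered, rounded half-up, and equivariant", {
  set.seed(11)
  x <- runif(120, 0.5, 6)
  y <- rbinom(120, 1, plogis(-11.28 + 4.18 * x))
  fit <- fit_logistic(x, y)
  tp <- threshold_pair(fit)
  expect_lt(tp$lower_cm, tp$upper_cm)
  expect_equal(predict_prob(fit, tp$upper_raw), 0.99, tolerance = 1e-9)
  expect_equal(predict_prob(fit, tp$lower_raw), 0.01, tolerance = 1e-9)
  expect_equal(tp$upper_cm, round_half_up(tp$upper_raw, 1))
  # affine rescaling of the predictor transforms thresholds accordingly
  fit_mm <- fit_logistic(x * 10, y)  # cm -> mm
  tp_mm <- threshold_pair(fit_mm, digits = 3)
  expect_equal(tp_mm$upper_raw, tp$upper_raw * 10, tolerance = 1e-4)
  expect_equal(tp_mm$lower_raw, tp$lower_raw * 10, tolerance = 1e-4)
})

test_that("rounding of thresholds is half away from zero", {
  expect_equal(round_half_up(3.75, 1), 3.8)
  expect_equal(round_half_up(1.65, 1), 1.7)
  expect_equal(round_half_up(16.5 / 100 * 100), 17)
})

test_that("parametric bootstrap returns coherent threshold intervals", {
  set.seed(13)
  x <- runif(150, 0.5, 6)
  y <- rbinom(150, 1, plogis(-11.28 + 4.18 * x))
  fit <- fit_logistic(x, y)
  bt <- bootstrap_thresholds(fit, x, n_boot = 300, seed = 2)
  expect_gt(bt$n_used, 250)
  expect_lt(bt$upper_cm[["ci_lower"]], bt$upper_cm[["ci_upper"]])
  expect_gt(bt$upper_cm[["median"]], bt$lower_cm[["median"]])
  bt2 <- bootstrap_thresholds(fit, x, n_boot = 300, seed = 2)
  expect_identical(bt, bt2)
})

test_that("predictor comparison prefers the informative predictor", {
  # outcome is a deterministic step in length, independent coin flip in age
  set.seed(17)
  n <- 40
  len <- runif(n, 1, 6)
  age <- runif(n, 12, 60)
  co <- data.frame(animal_id = sprintf("c%02d", 1:n), source = "castration",
                   age_months = age, bcs = NA_real_,
                   left_length_cm = len, right_length_cm = len,
                   mean_length_cm = len,
                   sperm_present = len > 3.5, stringsAsFactors = FALSE)
  # scramble any age signal
  co$age_months <- sample(co$age_months)
  cmp <- compare_predictors(co)
  expect_equal(cmp$preferred, "mean_length_cm")
  expect_false(cmp$fit_length$converged)  # separation-safe handling
  expect_lt(cmp$fit_length$aic, cmp$fit_age$aic)
  expect_null(cmp$thresholds)
})

test_that("comparing a predictor with itself gives zero AIC difference", {
  fx <- table_fixture("experiment2")
  same <- fx
  same$age_months <- same$mean_length_cm
  cmp <- compare_predictors(same)
  expect_equal(cmp$aic_difference, 0, tolerance = 1e-9)
})

test_that("experiment-2 fixture comparison is stable and length-led", {
  cmp <- compare_predictors(table_fixture("experiment2"))
  expect_equal(cmp$n, 28)
  expect_equal(cmp$preferred, "mean_length_cm")
  expect_true(cmp$fit_length$converged)
  expect_lt(cmp$fit_length$aic, cmp$fit_age$aic)
  # regression snapshot of the frozen fixture values (not published values)
  expect_equal(cmp$fit_length$aic, 24.35930, tolerance = 1e-5)
  expect_equal(cmp$fit_age$aic, 29.98955, tolerance = 1e-5)
  expect_equal(cmp$thresholds$upper_cm, 4.3, tolerance = 1e-9)
  expect_equal(cmp$thresholds$lower_cm, 1.5, tolerance = 1e-9)
})

test_that("threshold recovery from cohorts simulated at known truth", {
  # generating curve has its 0.99 crossing exactly at 3.8 cm; the transition
  # is one cm wide so the crossing is statistically identifiable at n = 200
  hits <- 0
  for (r in 1:20) {
    # excised-organ growth truth spans the threshold region; young-skewed
    # ages as in routine castration cohorts
    co <- simulate_cohort(cohort_config(
      n = 200, source_mix = c(in_vivo = 0, castration = 0.8, necropsy = 0.2),
      age_range_months = c(11, 113), age_distribution = "loguniform",
      true_growth = growth_params(4.43, 0.069, 15.47, sigma = 0.3),
      true_logistic = sperm_logistic_from_thresholds(2.8, 3.8),
      seed = 900 + r))
    cmp <- compare_predictors(co)
    if (is.null(cmp$thresholds)) next
    if (abs(cmp$thresholds$upper_raw - 3.8) <= 0.3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
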