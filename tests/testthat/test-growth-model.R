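table3_truth <- growth_params(4.96, 0.078, 5.89, sigma = 0.3)

test_that("growth curve hits its closed-form landmarks", {
  # at age = gamma the logistic sits exactly at half the asymptote
  expect_equal(growth_mean(table3_truth, 5.89), 4.96 / 2, tolerance = 1e-12)
  # independent one-line evaluation of the curve at the cohort median age
  oracle <- 4.96 / (1 + exp(-0.078 * (25.5 - 5.89)))
  expect_equal(growth_mean(table3_truth, 25.5), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 3), 4.077)
})

test_that("BCS multiplier of one reduces to the plain curve", {
  with_bcs <- growth_params(4.96, 0.078, 5.89, delta = 0.5)
  ages <- seq(13, 48, by = 5)
  expect_equal(growth_mean(with_bcs, ages, bcs = 2),
               growth_mean(table3_truth, ages), tolerance = 1e-12)
  expect_error(growth_mean(with_bcs, ages), "bcs")
  expect_error(growth_mean(table3_truth, ages, bcs = 2), "delta")
})

test_that("growth curve is monotone in age, BCS-ordered, and bounded by alpha", {
  ages <- seq(6, 120, by = 0.5)
  mu <- growth_mean(table3_truth, ages)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu > 0 & mu < 4.96))
  expect_equal(growth_mean(table3_truth, 1e6), 4.96, tolerance = 1e-9)
  # for ages above gamma, higher BCS never gives a shorter expected length
  wb <- growth_params(4.96, 0.078, 5.89, delta = 0.3)
  post <- ages[ages > 5.89]
  expect_true(all(growth_mean(wb, post, bcs = 4.5) >=
                    growth_mean(wb, post, bcs = 2.5)))
})

test_that("log-likelihood matches the normal density arithmetic", {
  one <- data.frame(animal_id = "a", source = "castration", age_months = 20,
                    bcs = NA_real_, left_length_cm = 3, right_length_cm = 3,
                    mean_length_cm = 3, sperm_present = NA)
  # L = mu, sigma = 1: standard normal log-density at zero
  p <- growth_params(3, 0.1, 0, sigma = 1)
  expect_equal(growth_loglik(p, one, "null"), -0.5 * log(2 * pi),
               tolerance = 1e-9)
  expect_equal(round(growth_loglik(p, one, "null"), 5), -0.91894)
  # one sigma away: -log(sqrt(2 pi)) - 1/2
  p4 <- growth_params(4, 0.1, 0, sigma = 1)
  expect_equal(growth_loglik(p4, one, "null"), -0.5 * log(2 * pi) - 0.5,
               tolerance = 1e-9)
  # additivity: duplicating the cohort doubles the value
  two <- rbind(one, one)
  expect_equal(growth_loglik(p, two, "null"),
               2 * growth_loglik(p, one, "null"), tolerance = 1e-12)
  # BCS variant refuses records without a BCS, naming them
  pb <- growth_params(4, 0.1, 0, delta = 0.3, sigma = 1)
  expect_error(growth_loglik(pb, one, "increment_bcs"), "rows: 1")
})

test_that("null-variant likelihood is maximised at the sample mean", {
  co <- simulate_cohort(recovery_config(seed = 21, n = 30))
  grid <- seq(2, 8, by = 0.01)
  ll <- vapply(grid, function(a)
    growth_loglik(growth_params(a, 0.1, 0, sigma = 0.4), co, "null"), 0)
  expect_equal(grid[which.max(ll)], mean(co$mean_length_cm),
               tolerance = 0.011)
})

test_that("sampler reproduces the conjugate normal-mean posterior", {
  co <- simulate_cohort(recovery_config(seed = 31, n = 40))
  # sigma fixed at 1, near-flat uniform prior: posterior for the constant
  # mean is N(sample mean, 1/n) in closed form
  post <- run_growth_mcmc(co, "null",
                          priors = growth_priors(
                            alpha = list(dist = "uniform", min = 0.01,
                                         max = 100)),
                          config = test_mcmc(seed = 9), fixed_sigma = 1)
  draws <- post$draws[, "alpha"]
  mcse <- batch_mcse(draws)
  expect_lt(abs(mean(draws) - mean(co$mean_length_cm)), 3 * mcse)
  # posterior sd should be close to 1/sqrt(n)
  expect_equal(sd(draws), 1 / sqrt(nrow(co)), tolerance = 0.1)
  expect_true(all(post$rhat < 1.05))
})

test_that("sampler output is reproducible and validly summarised", {
  co <- simulate_cohort(recovery_config(seed = 41, n = 40))
  cfg <- quick_mcmc(seed = 2)
  a <- run_growth_mcmc(co, "increment", config = cfg)
  b <- run_growth_mcmc(co, "increment", config = cfg)
  expect_identical(a$draws, b$draws)
  s <- a$summaries
  expect_true(all(s$ci_lower <= s$median & s$median <= s$ci_upper))
})

test_that("sampler rejects unidentifiable or ill-posed inputs", {
  flat <- data.frame(animal_id = letters[1:4], source = "castration",
                     age_months = c(15, 20, 30, 40), bcs = NA_real_,
                     left_length_cm = 3, right_length_cm = 3,
                     mean_length_cm = 3, sperm_present = NA)
  expect_error(run_growth_mcmc(flat, "null", config = quick_mcmc()),
               "unidentifiable")
  co <- simulate_cohort(recovery_config(seed = 51, n = 20))
  expect_error(run_growth_mcmc(co, "increment_bcs", config = quick_mcmc()),
               "fixed_beta")
  expect_error(run_growth_mcmc(co, "increment", fixed_beta = 0.1,
                               config = quick_mcmc()), "increment_bcs")
})

test_that("DIC matches hand arithmetic on a toy posterior", {
  toy <- data.frame(animal_id = c("a", "b"), source = "castration",
                    age_months = c(20, 30), bcs = NA_real_,
                    left_length_cm = c(3, 4), right_length_cm = c(3, 4),
                    mean_length_cm = c(3, 4), sperm_present = NA)
  # two hand-written null-variant draws (alpha, sigma)
  draws <- cbind(alpha = c(3.2, 3.8), sigma = c(0.5, 0.8))
  dev <- function(a, s) -2 * sum(dnorm(c(3, 4), a, s, log = TRUE))
  d1 <- dev(3.2, 0.5); d2 <- dev(3.8, 0.8)
  dbar <- (d1 + d2) / 2
  dhat <- dev(3.5, 0.65)
  res <- compute_dic(draws, toy, "null")
  expect_equal(res$p_d, dbar - dhat, tolerance = 1e-9)
  expect_equal(res$dic, dbar + (dbar - dhat), tolerance = 1e-9)
  expect_equal(res$dic, res$mean_deviance + res$p_d, tolerance = 1e-9)
  # degenerate single-draw posterior: p_D = 0 and DIC = D at that draw
  one <- cbind(alpha = 3.2, sigma = 0.5)
  res1 <- compute_dic(one, toy, "null")
  expect_equal(res1$p_d, 0, tolerance = 1e-9)
  expect_equal(res1$dic, d1, tolerance = 1e-9)
  expect_error(compute_dic(draws[0, , drop = FALSE], toy, "null"),
               "nonempty")
})

test_that("fit_growth orchestrates DIC deltas and the fixed-beta handoff", {
  co <- simulate_cohort(recovery_config(seed = 61, n = 50))
  cfg <- quick_mcmc(seed = 4)
  fn <- fit_growth(co, "null", config = cfg)
  expect_equal(fn$dic, fn$mean_deviance + fn$p_d, tolerance = 1e-9)
  # delta DIC of the null against itself is zero
  fn2 <- fit_growth(co, "null", config = cfg, null_result = fn)
  expect_equal(fn2$delta_dic, 0, tolerance = 1e-9)
  expect_error(fit_growth(co, "increment_bcs", config = cfg),
               "increment_result")
  fi <- fit_growth(co, "increment", config = cfg, null_result = fn)
  fb <- fit_growth(co, "increment_bcs", config = cfg, null_result = fn,
                   increment_result = fi)
  expect_equal(fb$fixed_beta, density_mode(fi$posterior$draws[, "beta"]),
               tolerance = 1e-12)
  expect_false("beta" %in% fb$summaries$parameter)
})

test_that("null-variant posterior concentrates at the sample mean", {
  three <- data.frame(animal_id = c("a", "b", "c"), source = "castration",
                      age_months = c(15, 25, 35), bcs = NA_real_,
                      left_length_cm = c(2, 3, 4),
                      right_length_cm = c(2, 3, 4),
                      mean_length_cm = c(2, 3, 4), sperm_present = NA)
  fit <- fit_growth(three, "null",
                    config = mcmc_config(n_chains = 2, n_iterations = 12000,
                                         n_burnin = 2000, seed = 6))
  med <- fit$summaries$median[fit$summaries$parameter == "alpha"]
  expect_lt(abs(med - 3), 0.2)
})

test_that("posterior medians sharpen with sample size", {
  err <- function(n, seed) {
    co <- simulate_cohort(recovery_config(seed = seed, n = n))
    f <- fit_growth(co, "increment", config = quick_mcmc(seed = seed))
    s <- f$summaries
    abs(s$median[s$parameter == "alpha"] - 4.96)
  }
  e72 <- median(vapply(1:3, function(s) err(72, 70 + s), 0))
  e500 <- median(vapply(1:3, function(s) err(500, 80 + s), 0))
  expect_lt(e500, e72 + 0.05)
})
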