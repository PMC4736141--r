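# Shared test helpers: small configs and an independent brute-force logistic
# likelihood oracle.

# Table-3 generating truth for recovery studies; no in-vivo offset so the
# fitted growth model is well specified for the simulated data.
recovery_config <- function(seed, n = 72, sigma = 0.3) {
  cohort_config(n = n,
                true_growth = growth_params(4.96, 0.078, 5.89, sigma = sigma),
                in_vivo_offset_cm = 0,
                seed = seed)
}

# Short MCMC runs for unit tests; replicate studies use test_mcmc() below.
quick_mcmc <- function(seed = 1, n_iterations = 4000, n_burnin = 1500) {
  mcmc_config(n_chains = 2, n_iterations = n_iterations,
              n_burnin = n_burnin, seed = seed)
}

test_mcmc <- function(seed = 1) {
  mcmc_config(n_chains = 3, n_iterations = 8000, n_burnin = 3000,
              seed = seed)
}

# Independent maximum-likelihood oracle for the logistic model: direct
# Nelder-Mead maximisation of the Bernoulli log-likelihood, no IRLS.
brute_force_logistic <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(intercept = fit$par[1], slope = fit$par[2], loglik = -fit$value)
}

# Monte-Carlo standard error of a chain mean by batch means.
batch_mcse <- function(x, n_batches = 30) {
  n <- length(x)
  bs <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(means) / sqrt(n_batches)
}
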