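## Bayesian growth model ------------------------------------------------------
##
## Three variants of a normal model for observed mean testicular length L_i:
##   null:          L_i ~ Normal(alpha, sigma)        (intercept only)
##   increment:     L_i ~ Normal(mu_i, sigma),  mu_i = alpha / (1 + exp(-beta (Age_i - gamma)))
##   increment_bcs: as increment but the exponent is multiplied by BCS_i * delta
##                  and beta is fixed at its posterior mode from the increment fit.
## Estimation is component-wise adaptive random-walk Metropolis; variants are
## compared by DIC (mean posterior deviance plus the Spiegelhalter p_D
## penalty with the posterior mean as plug-in).

GROWTH_VARIANTS <- c("null", "increment", "increment_bcs")

#' Logistic growth curve for mean testicular length
#'
#' Evaluates mu(age) = alpha / (1 + exp(-beta * (age - gamma))), the expected
#' mean testicular length at a given age. When `params$delta` is set the
#' exponent is multiplied by `bcs * delta`, so a higher body condition score
#' steepens the increment; `bcs` must then be supplied (and must not be
#' supplied otherwise).
#'
#' @param params a [growth_params()] object.
#' @param age age in months (vectorised).
#' @param bcs body condition score(s), required iff `params$delta` is set.
#' @return expected mean length(s) in cm, in (0, alpha).
#' @export
growth_mean <- function(params, age, bcs = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (is.null(params$delta) && !is.null(bcs))
    stop("bcs supplied but params$delta is not set", call. = FALSE)
  if (!is.null(params$delta) && is.null(bcs))
    stop("params$delta is set but bcs was not supplied", call. = FALSE)
  expo <- -params$beta * (age - params$gamma)
  if (!is.null(params$delta)) expo <- expo * bcs * params$delta
  params$alpha / (1 + exp(expo))
}

#' Gaussian log-likelihood of a cohort under a growth variant
#'
#' Sum over records of the normal log-density of observed mean length at the
#' variant's expected value: constant `alpha` for the null variant, the
#' logistic growth curve for `increment`, and the BCS-scaled curve for
#' `increment_bcs` (every record must then carry a BCS).
#'
#' @param params a [growth_params()] object (with `delta` for the BCS
#'   variant; `sigma` must be positive).
#' @param cohort a cohort data.frame.
#' @param variant one of `"null"`, `"increment"`, `"increment_bcs"`.
#' @return the scalar log-likelihood.
#' @export
growth_loglik <- function(params, cohort, variant = "increment") {
  variant <- match.arg(variant, GROWTH_VARIANTS)
  stopifnot(inherits(params, "growth_params"), params$sigma > 0)
  L <- cohort$mean_length_cm
  mu <- switch(variant,
    null = rep(params$alpha, length(L)),
    increment = growth_mean(params, cohort$age_months),
    increment_bcs = {
      bad <- which(is.na(cohort$bcs))
      if (length(bad))
        stop("increment_bcs requires a BCS for every record; missing in ",
             "rows: ", paste(bad, collapse = ", "), call. = FALSE)
      growth_mean(params, cohort$age_months, cohort$bcs)
    })
  sum(stats::dnorm(L, mu, params$sigma, log = TRUE))
}

#' Prior specification for the growth model
#'
#' Weakly informative defaults spanning the data scale: uniforms on alpha
#' (cm), beta (per month), gamma (months) and delta (per BCS unit), and a
#' half-Cauchy on the residual SD sigma. Each prior is a list with a `dist`
#' field (`"uniform"` or `"half_cauchy"`) and hyperparameters (`min`/`max` or
#' `scale`); any component can be overridden.
#'
#' @param alpha,beta,gamma,delta,sigma per-parameter prior lists.
#' @return a list of class `prior_spec`.
#' @export
growth_priors <- function(alpha = list(dist = "uniform", min = 0, max = 20),
                          beta = list(dist = "uniform", min = 0, max = 1),
                          gamma = list(dist = "uniform", min = -50, max = 120),
                          delta = list(dist = "uniform", min = 0, max = 5),
                          sigma = list(dist = "half_cauchy", scale = 1)) {
  pr <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
             sigma = sigma)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (!is.list(p) || is.null(p$dist) ||
        !p$dist %in% c("uniform", "half_cauchy"))
      stop("prior for ", nm, " must be uniform or half_cauchy", call. = FALSE)
    if (p$dist == "uniform" && (is.null(p$min) || is.null(p$max) ||
                                p$max <= p$min))
      stop("uniform prior for ", nm, " needs min < max", call. = FALSE)
    if (p$dist == "half_cauchy" && (is.null(p$scale) || p$scale <= 0))
      stop("half_cauchy prior for ", nm, " needs a positive scale",
           call. = FALSE)
  }
  structure(pr, class = "prior_spec")
}

prior_logdens <- function(prior, value) {
  switch(prior$dist,
    uniform = if (value < prior$min || value > prior$max) -Inf else
      -log(prior$max - prior$min),
    half_cauchy = if (value <= 0) -Inf else
      log(2) + stats::dcauchy(value, 0, prior$scale, log = TRUE))
}

#' MCMC sampler configuration
#'
#' @param n_chains number of chains (>= 2 so R-hat is defined).
#' @param n_iterations iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded from each chain; proposal
#'   adaptation happens only here and is frozen afterwards.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param proposal_scales optional named numeric vector of initial
#'   random-walk SDs (names among alpha, beta, gamma, delta, log_sigma).
#' @param seed integer; chain c uses seed + c - 1.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 20000, n_burnin = 5000,
                        thin = 1, proposal_scales = NULL, seed = 1L) {
  stopifnot(n_chains >= 2, n_iterations > 0, n_burnin > 0, thin >= 1)
  if (n_burnin >= n_iterations)
    stop("n_burnin must be smaller than n_iterations", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 proposal_scales = proposal_scales, seed = as.integer(seed)),
            class = "mcmc_config")
}

## Sampling parameterisation: positive parameters (alpha, beta, delta,
## sigma) are sampled on the log scale -- the posterior ridge trading alpha
## against beta is close to log-linear, so the adapted joint proposals can
## follow it -- while gamma stays on its natural (months) scale. Priors are
## stated on the natural scale; the log-scale Jacobian is added explicitly.
variant_free_params <- function(variant, fixed_sigma = NULL) {
  base <- switch(variant,
                 null = "log_alpha",
                 increment = c("log_alpha", "log_beta", "gamma"),
                 increment_bcs = c("log_alpha", "gamma", "log_delta"))
  if (is.null(fixed_sigma)) c(base, "log_sigma") else base
}

natural_param_name <- function(nm) sub("^log_", "", nm)

## Fast likelihood path used inside the sampler and DIC loop: no parameter
## object construction, vectors prepared once per fit.
fast_loglik <- function(alpha, beta, gamma, delta, sigma, L, age, bcs,
                        variant) {
  mu <- switch(variant,
    null = alpha,
    increment = alpha / (1 + exp(-beta * (age - gamma))),
    increment_bcs = alpha / (1 + exp(-beta * (age - gamma) * bcs * delta)))
  sum(stats::dnorm(L, mu, sigma, log = TRUE))
}

## Log posterior on the sampling scale (includes log-scale Jacobians).
growth_logpost <- function(theta, dat, variant, priors, fixed_beta,
                           fixed_sigma) {
  lp <- 0
  nat <- numeric(length(theta))
  names(nat) <- vapply(names(theta), natural_param_name, "")
  for (i in seq_along(theta)) {
    nm <- names(theta)[i]
    if (startsWith(nm, "log_")) {
      v <- exp(theta[[i]])
      if (!is.finite(v)) return(-Inf)
      lp <- lp + prior_logdens(priors[[natural_param_name(nm)]], v) +
        theta[[i]]
      nat[i] <- v
    } else {
      lp <- lp + prior_logdens(priors[[nm]], theta[[i]])
      nat[i] <- theta[[i]]
    }
    if (!is.finite(lp)) return(-Inf)
  }
  sigma <- if (is.null(fixed_sigma)) nat[["sigma"]] else fixed_sigma
  beta <- if (variant == "increment_bcs") fixed_beta else nat["beta"][[1L]]
  lp + fast_loglik(nat[["alpha"]], beta, nat["gamma"][[1L]],
                   nat["delta"][[1L]], sigma, dat$L, dat$age, dat$bcs,
                   variant)
}

default_scales <- c(log_alpha = 0.1, log_beta = 0.3, gamma = 3,
                    log_delta = 0.3, log_sigma = 0.2)

clip_to_support <- function(th, priors) {
  for (nm in names(th)) {
    pr <- priors[[natural_param_name(nm)]]
    if (is.null(pr) || pr$dist != "uniform") next
    if (startsWith(nm, "log_")) {
      eps <- 1e-6 * (pr$max - pr$min)
      th[nm] <- min(max(th[nm], log(max(pr$min, 0) + eps)),
                    log(pr$max - eps))
    } else {
      th[nm] <- min(max(th[nm], pr$min + 1e-6 * (pr$max - pr$min)),
                    pr$max - 1e-6 * (pr$max - pr$min))
    }
  }
  th
}

## Heuristic starting values on the sampling scale.
start_theta <- function(free, dat, priors) {
  L <- dat$L
  th <- c(log_alpha = log(max(mean(L) * 1.1, 0.5)),
          log_beta = log(0.08),
          gamma = 10,
          log_delta = log(0.3),
          log_sigma = log(max(stats::sd(L) / 2, 0.05)))
  clip_to_support(th[free], priors)
}

## Posterior mode found by Nelder-Mead from a few spread starts. Chains are
## initialised here (plus jitter): the BCS variant's posterior has a
## near-zero-mass trap mode (delta ~ 0, alpha ~ twice the asymptote) that
## random-walk chains cannot leave within any reasonable run length.
find_map <- function(dat, variant, priors, fixed_beta, fixed_sigma) {
  free <- variant_free_params(variant, fixed_sigma)
  obj <- function(v) {
    names(v) <- free
    lp <- growth_logpost(v, dat, variant, priors, fixed_beta, fixed_sigma)
    if (is.finite(lp)) -lp else 1e10
  }
  base <- start_theta(free, dat, priors)
  starts <- list(base)
  for (f in c(0.5, 2)) {
    s <- base
    if ("log_beta" %in% free) s["log_beta"] <- base["log_beta"] + log(f)
    if ("log_delta" %in% free) s["log_delta"] <- base["log_delta"] + log(f)
    if ("gamma" %in% free) s["gamma"] <- base["gamma"] * f
    starts[[length(starts) + 1L]] <- clip_to_support(s, priors)
  }
  best <- NULL
  method <- if (length(free) > 1L) "Nelder-Mead" else "BFGS"
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = method,
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(base)
  out <- best$par
  names(out) <- free
  clip_to_support(out, priors)
}

init_theta <- function(free, map, priors) {
  jitter <- stats::rnorm(length(free), 0, default_scales[free] * 2)
  clip_to_support(stats::setNames(map + jitter, free), priors)
}

run_single_chain <- function(dat, variant, priors, config, fixed_beta,
                             fixed_sigma, chain, map) {
  set.seed(config$seed + chain - 1L)
  free <- variant_free_params(variant, fixed_sigma)
  d <- length(free)
  theta <- init_theta(free, map, priors)
  scales <- default_scales[free]
  if (!is.null(config$proposal_scales)) {
    user <- config$proposal_scales
    scales[names(user)[names(user) %in% free]] <-
      user[names(user) %in% free]
  }
  lp <- growth_logpost(theta, dat, variant, priors, fixed_beta, fixed_sigma)
  if (!is.finite(lp)) { # fall back to the mode itself if the jitter left support
    theta <- stats::setNames(map, free)
    lp <- growth_logpost(theta, dat, variant, priors, fixed_beta,
                         fixed_sigma)
  }
  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thin
  draws <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, free))
  ## burn-in history feeds the joint-proposal covariance
  hist <- matrix(NA_real_, config$n_burnin, d)
  acc <- att <- stats::setNames(numeric(d), free)
  joint_R <- NULL          # Cholesky factor of the adapted covariance
  joint_scale <- 2.38 / sqrt(d)
  joint_acc <- joint_att <- 0
  kept <- 0L
  adapt_every <- 50L
  cov_every <- 200L
  for (it in seq_len(config$n_iterations)) {
    ## component-wise random-walk sweep
    for (nm in free) {
      prop <- theta
      prop[nm] <- prop[nm] + stats::rnorm(1, 0, scales[nm])
      lp_prop <- growth_logpost(prop, dat, variant, priors, fixed_beta,
                                fixed_sigma)
      att[nm] <- att[nm] + 1
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc[nm] <- acc[nm] + 1
      }
    }
    ## joint random-walk step along the adapted covariance (handles the
    ## strong alpha-beta-gamma posterior correlation the component sweep
    ## cannot traverse efficiently)
    if (!is.null(joint_R)) {
      ## 10% of joint steps are 5x larger, to traverse the long ridge of
      ## the growth posterior (alpha-beta-gamma trade-off) faster
      mult <- if (stats::runif(1) < 0.1) 5 else 1
      step <- drop(stats::rnorm(d) %*% joint_R) * joint_scale * mult
      prop <- theta + step
      lp_prop <- growth_logpost(prop, dat, variant, priors, fixed_beta,
                                fixed_sigma)
      joint_att <- joint_att + 1
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        joint_acc <- joint_acc + 1
      }
    }
    ## adaptation happens during burn-in only; everything is frozen
    ## afterwards so detailed balance holds on the retained draws
    if (it <= config$n_burnin) {
      hist[it, ] <- theta
      if (it %% adapt_every == 0L) {
        rate <- acc / pmax(att, 1)
        scales <- pmin(pmax(scales * exp(rate - 0.44), 1e-4), 50)
        acc[] <- 0
        att[] <- 0
        if (joint_att > 0) {
          joint_scale <- min(max(
            joint_scale * exp(joint_acc / joint_att - 0.23), 1e-4), 10)
          joint_acc <- joint_att <- 0
        }
      }
      if (it >= 400L && it %% cov_every == 0L) {
        win <- hist[max(1L, it %/% 2L):it, , drop = FALSE]
        S <- stats::cov(win) + diag(1e-8, d)
        R <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(R)) joint_R <- R
      }
    }
    if (it > config$n_burnin &&
        (it - config$n_burnin) %% config$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE], scales = scales)
}

## Convert sampling-scale draws to the natural scale (exp the log_ columns).
natural_draws <- function(draws) {
  out <- draws
  logcols <- grep("^log_", colnames(out))
  out[, logcols] <- exp(out[, logcols, drop = FALSE])
  colnames(out) <- vapply(colnames(out), natural_param_name, "")
  out
}

#' Run the Metropolis sampler for one growth variant
#'
#' Component-wise adaptive random-walk Metropolis over the variant's free
#' parameters (sigma sampled on the log scale; adaptation restricted to the
#' burn-in). Chains are seeded deterministically from `config$seed`, so the
#' same inputs always give identical draws. Convergence is summarised by the
#' split-chain R-hat; values above 1.1 set `converged = FALSE` and raise a
#' warning rather than failing.
#'
#' @param cohort cohort data.frame (nonempty, validated).
#' @param variant `"null"`, `"increment"` or `"increment_bcs"`.
#' @param priors a [growth_priors()] object.
#' @param config an [mcmc_config()] object.
#' @param fixed_beta increment-rate value used (not sampled) by the
#'   `increment_bcs` variant; required there, forbidden elsewhere.
#' @param fixed_sigma optional fixed residual SD (then sigma is not sampled).
#' @return an object of class `growth_posterior`: per-chain draw matrices on
#'   the natural scale, pooled draws, per-parameter summaries (median, 95%
#'   credible interval, KDE mode), R-hat, and sampler metadata.
#' @export
run_growth_mcmc <- function(cohort, variant, priors = growth_priors(),
                            config = mcmc_config(), fixed_beta = NULL,
                            fixed_sigma = NULL) {
  variant <- match.arg(variant, GROWTH_VARIANTS)
  validate_cohort(cohort)
  if (variant == "increment_bcs" && is.null(fixed_beta))
    stop("increment_bcs requires fixed_beta (the posterior mode of beta ",
         "from an increment fit)", call. = FALSE)
  if (variant != "increment_bcs" && !is.null(fixed_beta))
    stop("fixed_beta is only meaningful for the increment_bcs variant",
         call. = FALSE)
  if (variant == "increment_bcs" && anyNA(cohort$bcs))
    stop("increment_bcs requires a BCS for every record; missing in rows: ",
         paste(which(is.na(cohort$bcs)), collapse = ", "), call. = FALSE)
  if (is.null(fixed_sigma) &&
      stats::sd(cohort$mean_length_cm) == 0)
    stop("all mean lengths are identical: sigma is unidentifiable",
         call. = FALSE)
  dat <- list(L = cohort$mean_length_cm, age = cohort$age_months,
              bcs = cohort$bcs)
  map <- find_map(dat, variant, priors, fixed_beta, fixed_sigma)
  chains <- lapply(seq_len(config$n_chains), function(ch)
    run_single_chain(dat, variant, priors, config, fixed_beta,
                     fixed_sigma, ch, map))
  draws_by_chain <- lapply(chains, function(x) natural_draws(x$draws))
  pooled <- do.call(rbind, draws_by_chain)
  pars <- colnames(pooled)
  rhat <- vapply(pars, function(nm)
    split_rhat(lapply(draws_by_chain, function(d) d[, nm])), 0)
  converged <- all(is.finite(rhat) & rhat < 1.1)
  if (!converged)
    warning("R-hat above 1.1 for: ",
            paste(pars[!(is.finite(rhat) & rhat < 1.1)], collapse = ", "),
            "; chains may not have converged", call. = FALSE)
  summaries <- do.call(rbind, lapply(pars, function(nm) {
    x <- pooled[, nm]
    data.frame(parameter = nm, median = stats::median(x),
               ci_lower = unname(stats::quantile(x, 0.025)),
               ci_upper = unname(stats::quantile(x, 0.975)),
               mode = density_mode(x), stringsAsFactors = FALSE)
  }))
  structure(list(variant = variant, chains = draws_by_chain, draws = pooled,
                 summaries = summaries, rhat = rhat, converged = converged,
                 fixed_beta = fixed_beta, fixed_sigma = fixed_sigma,
                 priors = priors, config = config, n = nrow(cohort)),
            class = "growth_posterior")
}

#' Deviance information criterion from posterior draws
#'
#' Classic DIC: with deviance D(theta) = -2 log-likelihood, DIC =
#' mean(D) + p_D where the effective number of parameters p_D =
#' mean(D) - D(posterior mean of theta) (Spiegelhalter's penalty, posterior
#' mean on the natural scale as the plug-in point).
#'
#' @param draws matrix of posterior draws on the natural scale (columns among
#'   alpha, beta, gamma, delta, sigma).
#' @param cohort the fitted cohort.
#' @param variant the growth variant the draws came from.
#' @param fixed_beta,fixed_sigma fixed values used during sampling, if any.
#' @return list with `dic`, `p_d` and `mean_deviance`.
#' @export
compute_dic <- function(draws, cohort, variant, fixed_beta = NULL,
                        fixed_sigma = NULL) {
  variant <- match.arg(variant, GROWTH_VARIANTS)
  if (is.null(dim(draws)) || nrow(draws) == 0L)
    stop("draws must be a nonempty matrix", call. = FALSE)
  if (variant == "increment_bcs" && anyNA(cohort$bcs))
    stop("increment_bcs requires a BCS for every record", call. = FALSE)
  dat <- list(L = cohort$mean_length_cm, age = cohort$age_months,
              bcs = cohort$bcs)
  dev_at <- function(row) {
    sigma <- if (is.null(fixed_sigma)) row[["sigma"]] else fixed_sigma
    beta <- if (variant == "increment_bcs") fixed_beta else row["beta"][[1L]]
    -2 * fast_loglik(row[["alpha"]], beta, row["gamma"][[1L]],
                     row["delta"][[1L]], sigma, dat$L, dat$age, dat$bcs,
                     variant)
  }
  dev <- vapply(seq_len(nrow(draws)), function(i) dev_at(draws[i, ]), 0)
  mean_dev <- mean(dev)
  dev_at_mean <- dev_at(colMeans(draws))
  p_d <- mean_dev - dev_at_mean
  list(dic = mean_dev + p_d, p_d = p_d, mean_deviance = mean_dev)
}

#' Fit one growth variant and attach DIC
#'
#' Orchestrates [run_growth_mcmc()] and [compute_dic()]. For the
#' `increment_bcs` variant the increment-rate parameter is fixed at the KDE
#' mode of the beta draws from a supplied increment fit. When a null-model
#' fit is supplied, `delta_dic = dic(null) - dic(this variant)` is recorded,
#' so larger values favour this variant over the intercept-only baseline.
#'
#' @inheritParams run_growth_mcmc
#' @param null_result optional `growth_fit` of the null variant (for
#'   `delta_dic`).
#' @param increment_result `growth_fit` of the increment variant; required by
#'   `increment_bcs` unless `fixed_beta` is given directly.
#' @return an object of class `growth_fit`: the `growth_posterior` plus
#'   `dic`, `p_d`, `mean_deviance`, `delta_dic` and formatted summaries.
#' @export
fit_growth <- function(cohort, variant, priors = growth_priors(),
                       config = mcmc_config(), null_result = NULL,
                       increment_result = NULL, fixed_beta = NULL) {
  variant <- match.arg(variant, GROWTH_VARIANTS)
  if (variant == "increment_bcs" && is.null(fixed_beta)) {
    if (is.null(increment_result))
      stop("increment_bcs needs an increment_result (or fixed_beta) to fix ",
           "beta at its posterior mode", call. = FALSE)
    fixed_beta <- density_mode(increment_result$posterior$draws[, "beta"])
  }
  post <- run_growth_mcmc(cohort, variant, priors, config,
                          fixed_beta = if (variant == "increment_bcs")
                            fixed_beta else NULL)
  dic <- compute_dic(post$draws, cohort, variant,
                     fixed_beta = post$fixed_beta)
  delta_dic <- if (!is.null(null_result)) null_result$dic - dic$dic else
    NA_real_
  fmt <- sprintf("%.3g (%.3g-%.3g)", post$summaries$median,
                 post$summaries$ci_lower, post$summaries$ci_upper)
  names(fmt) <- post$summaries$parameter
  structure(list(variant = variant, posterior = post, dic = dic$dic,
                 p_d = dic$p_d, mean_deviance = dic$mean_deviance,
                 delta_dic = delta_dic, summaries = post$summaries,
                 formatted = fmt, rhat = post$rhat,
                 converged = post$converged, fixed_beta = post$fixed_beta,
                 n = post$n),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth model fit (", x$variant, " variant), n = ", x$n, "\n", sep = "")
  if (!is.null(x$fixed_beta))
    cat(sprintf("beta fixed at %.4g (posterior mode from increment fit)\n",
                x$fixed_beta))
  df <- x$summaries
  df$estimate <- x$formatted[df$parameter]
  print(df[, c("parameter", "estimate", "mode")], row.names = FALSE)
  cat(sprintf("DIC %.2f (p_D %.2f)", x$dic, x$p_d))
  if (!is.na(x$delta_dic))
    cat(sprintf(", Delta DIC vs null %.1f", x$delta_dic))
  cat("\nR-hat:", paste(sprintf("%s %.3f", names(x$rhat), x$rhat),
                        collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: chains may not have converged\n")
  invisible(x)
}
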