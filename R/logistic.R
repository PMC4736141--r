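## Sperm-presence logistic models ---------------------------------------------
##
## Binomial-logit GLMs of sperm presence (cauda epididymis) on a single
## predictor -- age in months or mean testicular length in cm -- with Wald
## tests, AIC, three pseudo-R2 measures, and inversion of the fitted curve
## into management thresholds.

#' Fit a single-predictor sperm-presence logistic model
#'
#' Maximum-likelihood binomial-logit fit (iteratively reweighted least
#' squares via [stats::glm()]) of a binary outcome on one predictor, with
#' Wald standard errors from the observed information, AIC, and McFadden,
#' Nagelkerke and Tjur pseudo-R2. Quasi-complete separation (non-convergence
#' or |slope| > 50) is flagged with `converged = FALSE` rather than returning
#' silently unstable estimates.
#'
#' @param x numeric predictor (age in months or mean length in cm).
#' @param y binary outcome (logical or 0/1), sperm present or not.
#' @param predictor label recorded in the result.
#' @return an object of class `sperm_logistic_fit` with elements
#'   `intercept`, `slope`, `se_intercept`, `se_slope`, `p_wald_slope`,
#'   `loglik`, `aic`, `pseudo_r2` (named list), `n`, `converged`.
#' @export
fit_logistic <- function(x, y, predictor = "x") {
  y <- as.integer(y)
  stopifnot(is.numeric(x), length(x) == length(y), all(y %in% 0:1))
  if (length(y) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("no outcome variation: y contains a single class", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  slope <- unname(co["x", "Estimate"])
  ## quasi-complete separation: IRLS "converges" onto a perfect fit with a
  ## diverging slope; flag via the slope size or a vanishing deviance
  converged <- fit$converged && abs(slope) <= 50 &&
    stats::deviance(fit) > 1e-6
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))))
  n <- length(y)
  p_hat <- unname(stats::fitted(fit))
  pseudo_r2 <- list(
    mcfadden = 1 - ll / ll0,
    nagelkerke = (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n)),
    tjur = mean(p_hat[y == 1]) - mean(p_hat[y == 0]))
  structure(list(
    predictor = predictor,
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope = slope,
    se_intercept = unname(co["(Intercept)", "Std. Error"]),
    se_slope = unname(co["x", "Std. Error"]),
    p_wald_slope = unname(co["x", "Pr(>|z|)"]),
    loglik = ll, aic = -2 * ll + 4, pseudo_r2 = pseudo_r2,
    n = n, converged = converged), class = "sperm_logistic_fit")
}

#' @export
print.sperm_logistic_fit <- function(x, ...) {
  cat("Sperm-presence logistic fit on ", x$predictor, " (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  intercept %.4g (SE %.3g), slope %.4g (SE %.3g)\n",
              x$intercept, x$se_intercept, x$slope, x$se_slope))
  cat(sprintf("  Wald p(slope) = %.3g, AIC = %.2f\n", x$p_wald_slope, x$aic))
  cat(sprintf("  pseudo-R2: McFadden %.2f, Nagelkerke %.2f, Tjur %.2f\n",
              x$pseudo_r2$mcfadden, x$pseudo_r2$nagelkerke, x$pseudo_r2$tjur))
  if (!x$converged) cat("  WARNING: separation suspected; not converged\n")
  invisible(x)
}

#' Fitted sperm-presence probability
#'
#' Inverse-logit of the fitted linear predictor at new values.
#'
#' @param fit a converged `sperm_logistic_fit`.
#' @param x predictor value(s).
#' @return probabilities in (0, 1), monotone in `x` when the slope is
#'   nonzero.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "sperm_logistic_fit"))
  if (!fit$converged)
    stop("fit did not converge (separation); predictions are undefined",
         call. = FALSE)
  inv_logit(fit$intercept + fit$slope * x)
}

#' Invert the fitted curve at a target probability
#'
#' Solves probability = p for the predictor: x = (logit(p) - intercept) /
#' slope, so that `predict_prob(fit, invert_threshold(fit, p))` returns `p`
#' exactly.
#'
#' @param fit a converged `sperm_logistic_fit` with nonzero slope.
#' @param p target probability in (0, 1).
#' @return the predictor value at which the fitted probability equals `p`.
#' @export
invert_threshold <- function(fit, p) {
  stopifnot(inherits(fit, "sperm_logistic_fit"))
  if (!fit$converged)
    stop("fit did not converge (separation); threshold is undefined",
         call. = FALSE)
  if (fit$slope == 0)
    stop("threshold undefined: slope is zero", call. = FALSE)
  stopifnot(all(p > 0), all(p < 1))
  (logit(p) - fit$intercept) / fit$slope
}

#' Management thresholds from a sperm-presence fit
#'
#' The testicular lengths at which the fitted probability of sperm presence
#' crosses `p_upper` (sperm production near-certain above this length) and
#' `p_lower` (near-impossible below it), reported rounded half-up to
#' `digits` decimals alongside the unrounded solutions.
#'
#' @param fit a converged `sperm_logistic_fit` on mean length.
#' @param p_upper,p_lower the two target probabilities.
#' @param digits decimals for the reported thresholds.
#' @return an object of class `threshold_pair` with `upper_cm`, `lower_cm`
#'   (rounded), `upper_raw`, `lower_raw`, and the targets used.
#' @export
threshold_pair <- function(fit, p_upper = 0.99, p_lower = 0.01, digits = 1) {
  stopifnot(p_upper > p_lower)
  upper_raw <- invert_threshold(fit, p_upper)
  lower_raw <- invert_threshold(fit, p_lower)
  structure(list(upper_cm = round_half_up(upper_raw, digits),
                 lower_cm = round_half_up(lower_raw, digits),
                 upper_raw = upper_raw, lower_raw = lower_raw,
                 p_upper = p_upper, p_lower = p_lower, rounding = digits),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(paste0("Sperm-presence thresholds: >= %.", x$rounding,
                     "f cm (p >= %.2f), <= %.", x$rounding,
                     "f cm (p <= %.2f)\n"),
              x$upper_cm, x$p_upper, x$lower_cm, x$p_lower))
  invisible(x)
}

#' Parametric-bootstrap thresholds
#'
#' Resamples binary outcomes from the fitted probabilities, refits the
#' logistic, and collects the threshold pair from every converged resample;
#' reports the bootstrap median thresholds with percentile 95% intervals.
#' This is the "median curve" reading of the thresholds, as opposed to the
#' plug-in MLE curve of [threshold_pair()].
#'
#' @param fit a converged `sperm_logistic_fit`.
#' @param x the predictor values the fit was made on.
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @param p_upper,p_lower threshold target probabilities.
#' @return list with per-threshold median and 95% percentile CI, and the
#'   number of converged resamples used.
#' @export
bootstrap_thresholds <- function(fit, x, n_boot = 2000, seed = 1L,
                                 p_upper = 0.99, p_lower = 0.01) {
  stopifnot(inherits(fit, "sperm_logistic_fit"), fit$converged)
  set.seed(seed)
  p_hat <- predict_prob(fit, x)
  ups <- los <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    yb <- stats::rbinom(length(x), 1L, p_hat)
    if (length(unique(yb)) < 2L) next
    fb <- fit_logistic(x, yb, predictor = fit$predictor)
    if (!fb$converged || fb$slope == 0) next
    ups[b] <- invert_threshold(fb, p_upper)
    los[b] <- invert_threshold(fb, p_lower)
  }
  ok <- !is.na(ups)
  summ <- function(v) c(median = stats::median(v[ok]),
                        ci_lower = unname(stats::quantile(v[ok], 0.025)),
                        ci_upper = unname(stats::quantile(v[ok], 0.975)))
  list(upper_cm = summ(ups), lower_cm = summ(los),
       n_used = sum(ok), n_boot = n_boot, seed = seed)
}

#' Compare age and length as predictors of sperm presence
#'
#' Fits the two single-predictor sperm-presence models (on age in months and
#' on mean testicular length in cm) to the ex-vivo records of a cohort,
#' reports both fits with their Wald p-values, pseudo-R2 and AIC, the AIC
#' difference, the preferred predictor (lower AIC), and -- when the length
#' model converged -- the management threshold pair from its fitted curve.
#'
#' @param cohort cohort data.frame; records with a non-missing
#'   `sperm_present` are used and must carry age and mean length.
#' @param p_upper,p_lower threshold targets passed to [threshold_pair()].
#' @return an object of class `sperm_comparison`.
#' @export
compare_predictors <- function(cohort, p_upper = 0.99, p_lower = 0.01) {
  validate_cohort(cohort)
  sub <- cohort[!is.na(cohort$sperm_present), , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 records with sperm outcomes", call. = FALSE)
  fit_age <- fit_logistic(sub$age_months, sub$sperm_present,
                          predictor = "age_months")
  fit_len <- fit_logistic(sub$mean_length_cm, sub$sperm_present,
                          predictor = "mean_length_cm")
  d_aic <- fit_age$aic - fit_len$aic
  preferred <- if (fit_len$aic <= fit_age$aic) "mean_length_cm" else
    "age_months"
  thresholds <- if (fit_len$converged && fit_len$slope != 0)
    threshold_pair(fit_len, p_upper, p_lower) else NULL
  structure(list(fit_age = fit_age, fit_length = fit_len,
                 aic_difference = d_aic, preferred = preferred,
                 thresholds = thresholds, n = nrow(sub)),
            class = "sperm_comparison")
}

#' @export
print.sperm_comparison <- function(x, ...) {
  cat("Sperm presence: age vs mean testicular length (n = ", x$n, ")\n",
      sep = "")
  for (f in list(x$fit_age, x$fit_length))
    cat(sprintf("  %-15s p = %.3g, Nagelkerke R2 = %.2f, AIC = %.2f%s\n",
                f$predictor, f$p_wald_slope, f$pseudo_r2$nagelkerke, f$aic,
                if (f$converged) "" else " [not converged]"))
  cat(sprintf("  preferred predictor: %s (AIC difference %.2f)\n",
              x$preferred, x$aic_difference))
  if (!is.null(x$thresholds)) print(x$thresholds)
  invisible(x)
}
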