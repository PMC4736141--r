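## Cohort container -----------------------------------------------------------
##
## A cohort is a plain data.frame with one row per animal (or excised organ
## pair) and the columns below. Sources: "in_vivo" (on-farm calliper
## measurement through the scrotal layers), "castration" and "necropsy"
## (excised organs, measured without scrotal layers and examined for sperm in
## the cauda epididymis).

COHORT_COLUMNS <- c("animal_id", "source", "age_months", "bcs",
                    "left_length_cm", "right_length_cm", "mean_length_cm",
                    "sperm_present")
COHORT_SOURCES <- c("in_vivo", "castration", "necropsy")

#' Validate a cohort data frame
#'
#' Checks the cohort contract: required columns, known sources, positive ages
#' and lengths, body condition scores (when present) on the 1-5 scale, the
#' mean length equal to the arithmetic mean of left and right lengths, and
#' sperm outcomes absent for live animals.
#'
#' @param cohort data.frame with the cohort columns.
#' @return the cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_source <- !cohort$source %in% COHORT_SOURCES
  if (any(bad_source))
    stop("unknown source value(s) in rows: ",
         paste(which(bad_source), collapse = ", "), call. = FALSE)
  if (any(!is.finite(cohort$age_months) | cohort$age_months <= 0))
    stop("age_months must be positive in all rows", call. = FALSE)
  len_ok <- is.finite(cohort$left_length_cm) & cohort$left_length_cm > 0 &
    is.finite(cohort$right_length_cm) & cohort$right_length_cm > 0
  if (any(!len_ok))
    stop("testicle lengths must be positive in rows: ",
         paste(which(!len_ok), collapse = ", "), call. = FALSE)
  bcs <- cohort$bcs[!is.na(cohort$bcs)]
  if (any(bcs < 1 | bcs > 5))
    stop("bcs values must lie in [1, 5]", call. = FALSE)
  expect_mean <- (cohort$left_length_cm + cohort$right_length_cm) / 2
  if (any(abs(cohort$mean_length_cm - expect_mean) > 1e-9))
    stop("mean_length_cm does not equal the mean of left and right lengths ",
         "in rows: ",
         paste(which(abs(cohort$mean_length_cm - expect_mean) > 1e-9),
               collapse = ", "), call. = FALSE)
  if (any(cohort$source == "in_vivo" & !is.na(cohort$sperm_present)))
    stop("sperm_present must be missing for in_vivo records", call. = FALSE)
  invisible(cohort)
}

#' Growth-curve parameter set
#'
#' Parameters of the logistic-in-age growth model for mean testicular length,
#' mu(age) = alpha / (1 + exp(-beta * (age - gamma))): `alpha` is the
#' asymptotic maximum mean length (cm), `beta` the increment rate (per month),
#' `gamma` the inflection age (months). The optional `delta` (per BCS unit)
#' multiplies the exponent by BCS * delta in the body-condition variant.
#' `sigma` is the residual standard deviation of observed mean length (cm).
#'
#' @param alpha,beta,gamma,sigma numeric scalars; alpha, beta, sigma > 0.
#' @param delta optional positive scalar, the BCS effect on the increment
#'   rate; `NULL` for the plain increment model.
#' @return a list of class `growth_params`.
#' @export
growth_params <- function(alpha, beta, gamma, delta = NULL, sigma = 0.3) {
  stopifnot(is.numeric(alpha), alpha > 0,
            is.numeric(beta), beta > 0,
            is.numeric(gamma), is.finite(gamma),
            is.numeric(sigma), sigma >= 0)
  if (!is.null(delta)) stopifnot(is.numeric(delta), delta > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, sigma = sigma),
            class = "growth_params")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the on-farm study arm: n = 72 live animals aged 13-48
#' months, body condition scores on the half-point 2.5-5 scale with median 4,
#' growth truth at the published increment-model estimates, and an in-vivo
#' length offset standing in for the scrotal layers included when measuring
#' live animals. The default sperm-presence logistic is parameterised so its
#' 0.99 and 0.01 probability crossings sit at 3.8 and 1.6 cm.
#'
#' @param n number of records.
#' @param source_mix named proportions over `in_vivo`, `castration`,
#'   `necropsy`; must sum to 1.
#' @param age_range_months length-2 increasing positive vector.
#' @param age_distribution `"uniform"` (default) or `"loguniform"`; the
#'   log-uniform option reproduces the young-skewed age profile typical of
#'   routine castrations (most animals presented young, a long right tail).
#' @param bcs_levels,bcs_probs discrete BCS distribution (half-point steps).
#' @param true_growth `growth_params` generating mean lengths.
#' @param true_logistic length-2 numeric `(intercept, slope)` on the logit
#'   scale for sperm presence versus mean length (ex-vivo records only).
#' @param in_vivo_offset_cm nonnegative length added to both testicle lengths
#'   of live-animal records before the mean is computed (scrotal layers).
#' @param lr_sd_cm standard deviation of the left-right asymmetry around the
#'   drawn mean length.
#' @param length_floor_cm positive floor applied to drawn mean lengths.
#' @param seed integer seed; simulation is a pure function of config + seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n = 72,
                          source_mix = c(in_vivo = 1, castration = 0,
                                         necropsy = 0),
                          age_range_months = c(13, 48),
                          age_distribution = c("uniform", "loguniform"),
                          bcs_levels = seq(2.5, 5, by = 0.5),
                          bcs_probs = c(0.10, 0.15, 0.20, 0.25, 0.20, 0.10),
                          true_growth = growth_params(4.96, 0.078, 5.89,
                                                      sigma = 0.3),
                          true_logistic = sperm_logistic_from_thresholds(),
                          in_vivo_offset_cm = 0.5,
                          lr_sd_cm = 0.1,
                          length_floor_cm = 0.1,
                          seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  if (is.null(names(source_mix)) ||
      !setequal(names(source_mix), COHORT_SOURCES))
    stop("source_mix must be named over in_vivo, castration, necropsy",
         call. = FALSE)
  if (abs(sum(source_mix) - 1) > 1e-9 || any(source_mix < 0))
    stop("source_mix proportions must be nonnegative and sum to 1",
         call. = FALSE)
  if (length(age_range_months) != 2L || any(age_range_months <= 0) ||
      diff(age_range_months) <= 0)
    stop("age_range_months must be a positive, increasing interval",
         call. = FALSE)
  if (length(bcs_levels) != length(bcs_probs) || any(bcs_probs < 0))
    stop("bcs_levels and bcs_probs must match", call. = FALSE)
  if (!inherits(true_growth, "growth_params"))
    stop("true_growth must be a growth_params object", call. = FALSE)
  if (true_growth$sigma < 0)
    stop("generating sigma must be nonnegative", call. = FALSE)
  stopifnot(length(true_logistic) == 2L, is.numeric(true_logistic),
            in_vivo_offset_cm >= 0, lr_sd_cm >= 0, length_floor_cm > 0)
  age_distribution <- match.arg(age_distribution)
  structure(list(n = as.integer(n), source_mix = source_mix[COHORT_SOURCES],
                 age_range_months = age_range_months,
                 age_distribution = age_distribution,
                 bcs_levels = bcs_levels,
                 bcs_probs = bcs_probs / sum(bcs_probs),
                 true_growth = true_growth, true_logistic = true_logistic,
                 in_vivo_offset_cm = in_vivo_offset_cm, lr_sd_cm = lr_sd_cm,
                 length_floor_cm = length_floor_cm, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sperm-presence logistic coefficients from target thresholds
#'
#' Solves for the `(intercept, slope)` of a logistic in mean testicular
#' length whose fitted probability crosses `p_upper` at `upper_cm` and
#' `p_lower` at `lower_cm`. With the defaults the generating curve reproduces
#' the published management thresholds (sperm near-certain at 3.8 cm,
#' near-impossible at 1.6 cm).
#'
#' @param lower_cm,upper_cm lengths (cm) at the lower and upper crossings.
#' @param p_lower,p_upper the target probabilities at those lengths.
#' @return numeric `(intercept, slope)` on the logit scale.
#' @export
sperm_logistic_from_thresholds <- function(lower_cm = 1.6, upper_cm = 3.8,
                                           p_lower = 0.01, p_upper = 0.99) {
  stopifnot(upper_cm > lower_cm, p_upper > p_lower,
            p_lower > 0, p_upper < 1)
  slope <- (logit(p_upper) - logit(p_lower)) / (upper_cm - lower_cm)
  intercept <- logit(p_upper) - slope * upper_cm
  c(intercept = intercept, slope = slope)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort under the generating model the analysis assumes: ages
#' uniform over the configured range, mean testicular length normal about the
#' logistic growth curve (floored at a small positive value), a symmetric
#' left-right split preserving the mean exactly, the in-vivo scrotal-layer
#' offset added to both lengths of live-animal records before the mean is
#' recomputed, and -- for castration/necropsy records -- a Bernoulli sperm
#' outcome with probability inverse-logit(intercept + slope * mean length).
#'
#' @param config a [cohort_config()] object (its `seed` fixes all draws).
#' @return a validated cohort data.frame with `config$n` rows.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object", call. = FALSE)
  g <- config$true_growth
  set.seed(config$seed)
  n <- config$n
  source <- sample(COHORT_SOURCES, n, replace = TRUE,
                   prob = config$source_mix)
  age <- if (config$age_distribution == "loguniform")
    exp(stats::runif(n, log(config$age_range_months[1]),
                     log(config$age_range_months[2])))
  else
    stats::runif(n, config$age_range_months[1], config$age_range_months[2])
  bcs <- sample(config$bcs_levels, n, replace = TRUE, prob = config$bcs_probs)
  mu <- if (is.null(g$delta)) growth_mean(g, age) else growth_mean(g, age, bcs)
  mean_len <- if (g$sigma > 0) stats::rnorm(n, mu, g$sigma) else mu
  mean_len <- pmax(mean_len, config$length_floor_cm)
  asym <- if (config$lr_sd_cm > 0) stats::rnorm(n, 0, config$lr_sd_cm) else
    numeric(n)
  ## clamp the split so both sides stay positive while preserving the mean
  asym <- pmin(pmax(asym, -(mean_len - config$length_floor_cm / 2)),
               mean_len - config$length_floor_cm / 2)
  left <- mean_len + asym
  right <- mean_len - asym
  iv <- source == "in_vivo"
  left[iv] <- left[iv] + config$in_vivo_offset_cm
  right[iv] <- right[iv] + config$in_vivo_offset_cm
  mean_len <- (left + right) / 2
  sperm <- rep(NA, n)
  ex <- !iv
  if (any(ex)) {
    p <- inv_logit(config$true_logistic[1] + config$true_logistic[2] *
                     mean_len[ex])
    sperm[ex] <- stats::rbinom(sum(ex), 1L, p) == 1L
  }
  cohort <- data.frame(
    animal_id = sprintf("SIM_%03d", seq_len(n)),
    source = source,
    age_months = age,
    bcs = bcs,
    left_length_cm = left,
    right_length_cm = right,
    mean_length_cm = mean_len,
    sperm_present = as.logical(sperm),
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
  cohort
}

## Deterministic fixtures -----------------------------------------------------
##
## Representative within-bin values, chosen once: length bins <3 / 3-3.9 / >4
## are represented by 2.5, 3.45 and 4.5 cm; age bins 12-23 / 24-35 / 36-48
## (or open-ended >36) by 18, 30 and 42 (or 60) months. Experiment-1 records
## carry the cohort's median BCS of 4.

fixture_experiment1 <- function() {
  ## counts[length bin, age bin]; rows <3, 3-3.9, >4; cols 12-23, 24-35, 36-48
  counts <- matrix(c(8, 0, 0,
                     14, 8, 0,
                     8, 24, 10), nrow = 3, byrow = TRUE)
  lengths <- c(2.5, 3.45, 4.5)
  ages <- c(18, 30, 42)
  rows <- list()
  for (i in 1:3) for (j in 1:3) {
    k <- counts[i, j]
    if (k == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      source = "in_vivo", age_months = ages[j], bcs = 4,
      left_length_cm = lengths[i], right_length_cm = lengths[i],
      mean_length_cm = lengths[i], sperm_present = NA,
      stringsAsFactors = FALSE)[rep(1L, k), ]
  }
  out <- do.call(rbind, rows)
  out <- cbind(animal_id = sprintf("E1_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

fixture_experiment2 <- function() {
  ## one row per table cell: length rep, age rep, source, positives, total
  cells <- data.frame(
    length = c(2.5, 2.5, 2.5, 2.5, 3.45, 3.45, 4.5, 4.5),
    age    = c(18, 18, 30, 60, 18, 30, 60, 60),
    source = c("castration", "necropsy", "castration", "castration",
               "castration", "castration", "castration", "necropsy"),
    pos    = c(1, 0, 1, 1, 3, 3, 4, 3),
    total  = c(6, 3, 4, 1, 4, 3, 4, 3),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    data.frame(
      source = ce$source, age_months = ce$age, bcs = NA_real_,
      left_length_cm = ce$length, right_length_cm = ce$length,
      mean_length_cm = ce$length,
      sperm_present = rep(c(TRUE, FALSE), c(ce$pos, ce$total - ce$pos)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(animal_id = sprintf("E2_%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Deterministic cohorts reproducing the published summary tables
#'
#' Seed-free fixtures whose binned counts reproduce the printed
#' length-by-age tables cell for cell: `"experiment1"` gives the 72
#' live-animal records (column totals 30/32/10), `"experiment2"` the 22
#' castration plus 6 necropsy organ pairs with their per-bin sperm outcomes.
#' Within-bin lengths and ages are fixed representative values (see source).
#'
#' @param which `"experiment1"` or `"experiment2"`.
#' @return a validated cohort data.frame.
#' @export
table_fixture <- function(which = c("experiment1", "experiment2")) {
  which <- match.arg(which)
  out <- switch(which,
                experiment1 = fixture_experiment1(),
                experiment2 = fixture_experiment2())
  validate_cohort(out)
  out
}
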