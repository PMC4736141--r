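#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.5 -> 1, 16.5 -> 17),
#' matching the presentation used in the cohort summary tables, rather than
#' R's default round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic seed derivation (fixed affine map modulo the integer
#' maximum) so each stage of a multi-stage analysis gets its own
#' reproducible seed and can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param stage integer stage offset.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.numeric(master) * 97 + stage) %% .Machine$integer.max)
}

#' Posterior mode by kernel density
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth,
#' 512-point grid) and its argmax. Used to fix the increment-rate parameter
#' at its posterior mode when fitting the body-condition growth variant.
#'
#' @param draws numeric vector of posterior draws.
#' @return the abscissa of the KDE maximum.
#' @export
density_mode <- function(draws) {
  stopifnot(is.numeric(draws), length(draws) >= 2L)
  d <- stats::density(draws, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale-reduction factor computed after splitting each chain in
#' half, so within-chain trends also inflate the statistic.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths).
#' @return the R-hat estimate (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  halves <- unlist(lapply(chains, function(ch) {
    n <- length(ch)
    h <- n %/% 2L
    list(ch[seq_len(h)], ch[(n - h + 1L):n])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)
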