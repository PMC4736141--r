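## Cohort I/O and the end-to-end analysis -------------------------------------

#' Read a cohort CSV
#'
#' Reads the cohort interchange format (header `animal_id,source,age_months,
#' bcs,left_length_cm,right_length_cm,mean_length_cm,sperm_present`; empty
#' fields are missing; `sperm_present` coded 0/1) with per-row validation.
#' A stored mean length is checked against the recomputed mean of the two
#' sides; a missing mean is filled in.
#'
#' @param path path to the CSV file.
#' @return a validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("cohort CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  cohort <- data.frame(
    animal_id = raw$animal_id,
    source = raw$source,
    age_months = num(raw$age_months),
    bcs = num(raw$bcs),
    left_length_cm = num(raw$left_length_cm),
    right_length_cm = num(raw$right_length_cm),
    mean_length_cm = num(raw$mean_length_cm),
    sperm_present = ifelse(raw$sperm_present == "", NA,
                           raw$sperm_present == "1"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    if (!r$source %in% COHORT_SOURCES)
      stop("row ", i, ": unknown source '", r$source, "'", call. = FALSE)
    if (is.na(r$age_months) || r$age_months <= 0)
      stop("row ", i, ": age_months must be a positive number",
           call. = FALSE)
    if (is.na(r$left_length_cm) || r$left_length_cm <= 0 ||
        is.na(r$right_length_cm) || r$right_length_cm <= 0)
      stop("row ", i, ": testicle lengths must be positive numbers",
           call. = FALSE)
    m <- (r$left_length_cm + r$right_length_cm) / 2
    if (!is.na(r$mean_length_cm) && abs(r$mean_length_cm - m) > 1e-6)
      stop("row ", i, ": stored mean_length_cm ", r$mean_length_cm,
           " disagrees with the mean of the two sides (", m, ")",
           call. = FALSE)
    cohort$mean_length_cm[i] <- m
  }
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]: missing values become empty fields and
#' `sperm_present` is coded 0/1.
#'
#' @param cohort validated cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  out$sperm_present <- ifelse(is.na(out$sperm_present), "",
                              as.integer(out$sperm_present))
  out$bcs <- ifelse(is.na(out$bcs), "", out$bcs)
  utils::write.csv(out[, COHORT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

cohort_metadata <- function(cohort) {
  by_source <- table(cohort$source)
  list(n = nrow(cohort),
       n_per_source = as.list(by_source),
       age_range_months = range(cohort$age_months),
       age_median_months = stats::median(cohort$age_months),
       bcs_range = if (all(is.na(cohort$bcs))) NULL else
         range(cohort$bcs, na.rm = TRUE),
       bcs_median = if (all(is.na(cohort$bcs))) NULL else
         stats::median(cohort$bcs, na.rm = TRUE),
       length_range_cm = range(cohort$mean_length_cm))
}

#' Run the full analysis on a cohort
#'
#' One-command reproduction of the whole analysis: descriptive
#' cross-tabulation, the three Bayesian growth fits (null, increment, and --
#' when every record has a BCS -- increment + BCS with the increment-rate
#' parameter fixed at its posterior mode) with DIC deltas against the null
#' model, and, when ex-vivo sperm outcomes are available, the logistic
#' age-versus-length comparison and the management threshold pair. Stages
#' lacking their inputs are skipped with an explicit notice in the report,
#' never silently. Deterministic given `seed`: per-stage seeds are derived
#' from the master seed by fixed offsets.
#'
#' @param cohort cohort data.frame, or a path to a cohort CSV.
#' @param mcmc an [mcmc_config()]; its seed is overridden per stage from
#'   `seed`.
#' @param seed master seed.
#' @param scheme a [bin_scheme()]; default chooses `"experiment2"` when any
#'   sperm outcome is present, else `"experiment1"`.
#' @return an object of class `analysis_report` (fully JSON-serialisable via
#'   [report_json()]).
#' @export
run_full_analysis <- function(cohort, mcmc = mcmc_config(), seed = 1L,
                              scheme = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  validate_cohort(cohort)
  has_sperm <- any(!is.na(cohort$sperm_present))
  if (is.null(scheme))
    scheme <- bin_scheme(if (has_sperm) "experiment2" else "experiment1")
  notices <- character()

  xtab <- cross_tabulate(cohort, scheme)

  growth <- list()
  cfg <- function(stage) {
    m <- mcmc
    m$seed <- derive_seed(seed, stage)
    m
  }
  fit_null <- fit_growth(cohort, "null", config = cfg(1L))
  fit_null$delta_dic <- 0
  fit_inc <- fit_growth(cohort, "increment", config = cfg(2L),
                        null_result = fit_null)
  growth$null <- fit_null
  growth$increment <- fit_inc
  if (!anyNA(cohort$bcs)) {
    growth$increment_bcs <- fit_growth(cohort, "increment_bcs",
                                       config = cfg(3L),
                                       null_result = fit_null,
                                       increment_result = fit_inc)
  } else {
    notices <- c(notices,
                 "increment_bcs skipped: BCS missing for some records")
  }

  logistic <- NULL
  n_outcomes <- sum(!is.na(cohort$sperm_present))
  if (n_outcomes >= 3L &&
      length(unique(stats::na.omit(cohort$sperm_present))) == 2L) {
    logistic <- compare_predictors(cohort)
  } else {
    notices <- c(notices, paste0(
      "logistic stage skipped: ", n_outcomes,
      " record(s) with sperm outcomes (need >= 3 spanning both classes)"))
  }

  structure(list(metadata = cohort_metadata(cohort),
                 tabulation = xtab, growth = growth, logistic = logistic,
                 notices = notices, seed = seed,
                 mcmc = mcmc[c("n_chains", "n_iterations", "n_burnin",
                               "thin")],
                 package_version = as.character(utils::packageVersion(
                   "alpacatestis"))),
            class = "analysis_report")
}

growth_fit_json <- function(f) {
  if (is.null(f)) return(NULL)
  list(variant = f$variant,
       summaries = f$summaries,
       dic = f$dic, p_d = f$p_d, mean_deviance = f$mean_deviance,
       delta_dic = f$delta_dic, rhat = as.list(f$rhat),
       converged = f$converged,
       fixed_beta = f$fixed_beta, n = f$n)
}

logistic_fit_json <- function(f) {
  f[c("predictor", "intercept", "slope", "se_intercept", "se_slope",
      "p_wald_slope", "loglik", "aic", "pseudo_r2", "n", "converged")]
}

#' Serialise an analysis report to JSON
#'
#' Writes (or returns) a lossless JSON document of the report's numeric
#' content: cohort metadata, binned counts, growth-fit summaries with DIC,
#' the logistic comparison and thresholds, notices and seeds. The same
#' report always serialises to byte-identical JSON.
#'
#' @param report an `analysis_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  x <- report
  doc <- list(
    metadata = x$metadata,
    tabulation = list(counts = x$tabulation$counts,
                      row_totals = as.list(x$tabulation$row_totals),
                      col_totals = as.list(x$tabulation$col_totals),
                      n = x$tabulation$n,
                      scheme = x$tabulation$scheme$which),
    growth = lapply(x$growth, growth_fit_json),
    logistic = if (is.null(x$logistic)) NULL else list(
      fit_age = logistic_fit_json(x$logistic$fit_age),
      fit_length = logistic_fit_json(x$logistic$fit_length),
      aic_difference = x$logistic$aic_difference,
      preferred = x$logistic$preferred,
      thresholds = if (is.null(x$logistic$thresholds)) NULL else
        unclass(x$logistic$thresholds)),
    notices = x$notices, seed = x$seed, mcmc = x$mcmc,
    package_version = x$package_version)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.analysis_report <- function(x, ...) {
  md <- x$metadata
  cat("Analysis report: n =", md$n, "(",
      paste(names(md$n_per_source), unlist(md$n_per_source),
            collapse = ", "), ")\n")
  cat(sprintf("ages %.1f-%.1f months (median %.1f)\n",
              md$age_range_months[1], md$age_range_months[2],
              md$age_median_months))
  for (f in x$growth) print(f)
  if (!is.null(x$logistic)) print(x$logistic)
  for (nt in x$notices) cat("NOTE:", nt, "\n")
  invisible(x)
}
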