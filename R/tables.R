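## Length-by-age contingency tables -------------------------------------------
##
## Bins follow the published summary tables: mean length <3 / 3-3.9 / >4 cm
## and age 12-23 / 24-35 / 36-48 months (live-animal arm) or an open-ended
## >36 (excised-organ arm). Intervals are half-open [lo, hi), so a length of
## exactly 4.0 falls in ">4" and 3.95 in "3-3.9"; the tables carry no bin
## below 12 months, so younger ages are rejected.

#' Binning scheme for the summary tables
#'
#' @param which `"experiment1"` (live animals, closed 36-48 top age bin
#'   label) or `"experiment2"` (excised organs, open-ended ">36").
#' @return list with length/age edges and labels, class `bin_scheme`.
#' @export
bin_scheme <- function(which = c("experiment1", "experiment2")) {
  which <- match.arg(which)
  structure(list(
    which = which,
    length_edges = c(3, 4),
    length_labels = c("<3", "3-3.9", ">4"),
    age_edges = c(24, 36),
    age_labels = if (which == "experiment1")
      c("12-23", "24-35", "36-48") else c("12-23", "24-35", ">36"),
    age_min = 12), class = "bin_scheme")
}

#' Assign length and age bins
#'
#' Half-open convention `[lo, hi)`: lengths `[0,3)`, `[3,4)`, `[4,Inf)`; ages
#' `[12,24)`, `[24,36)`, `[36,Inf)`. Ages below 12 months fall outside the
#' table grid and raise an error.
#'
#' @param length_cm,age_months positive numeric vectors.
#' @param scheme a [bin_scheme()].
#' @return data.frame with factor columns `length_bin` and `age_bin` whose
#'   levels are the scheme labels.
#' @export
assign_bins <- function(length_cm, age_months, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(!is.finite(length_cm) | length_cm <= 0) ||
      any(!is.finite(age_months) | age_months <= 0))
    stop("lengths and ages must be positive", call. = FALSE)
  if (any(age_months < scheme$age_min))
    stop("age below ", scheme$age_min,
         " months is outside the table grid", call. = FALSE)
  lb <- cut(length_cm, breaks = c(0, scheme$length_edges, Inf),
            labels = scheme$length_labels, right = FALSE)
  ab <- cut(age_months, breaks = c(scheme$age_min, scheme$age_edges, Inf),
            labels = scheme$age_labels, right = FALSE)
  data.frame(length_bin = lb, age_bin = ab)
}

#' Cross-tabulate a cohort by length and age bins
#'
#' Counts per (length bin, age bin) cell with row, column and grand totals.
#' When the cohort carries sperm outcomes, per-source matrices of positives
#' and totals are attached so presence percentages can be reported per cell.
#'
#' @param cohort cohort data.frame.
#' @param scheme a [bin_scheme()].
#' @return object of class `cohort_xtab`: `counts` (length x age matrix),
#'   `row_totals`, `col_totals`, `n`, and optionally `sperm`, a per-source
#'   list of `positives`/`totals` matrices.
#' @export
cross_tabulate <- function(cohort, scheme = bin_scheme()) {
  validate_cohort(cohort)
  bins <- assign_bins(cohort$mean_length_cm, cohort$age_months, scheme)
  counts <- table(bins$length_bin, bins$age_bin)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  out <- list(counts = counts,
              row_totals = rowSums(counts),
              col_totals = colSums(counts),
              n = sum(counts), scheme = scheme)
  has_sperm <- !is.na(cohort$sperm_present)
  if (any(has_sperm)) {
    out$sperm <- lapply(split(seq_len(nrow(cohort))[has_sperm],
                              cohort$source[has_sperm]), function(idx) {
      b <- bins[idx, , drop = FALSE]
      tot <- table(b$length_bin, b$age_bin)
      pos <- table(b$length_bin[cohort$sperm_present[idx]],
                   b$age_bin[cohort$sperm_present[idx]])
      list(positives = matrix(as.integer(pos), nrow = nrow(pos),
                              dimnames = dimnames(pos)),
           totals = matrix(as.integer(tot), nrow = nrow(tot),
                           dimnames = dimnames(tot)))
    })
  }
  structure(out, class = "cohort_xtab")
}

#' Sperm-presence percentage for a table cell
#'
#' `100 * positives / total`, rounded half-up to an integer percent (so 1 of
#' 6 gives 17).
#'
#' @param positives,total nonnegative counts with `positives <= total`,
#'   `total > 0` (vectorised).
#' @return integer percentages.
#' @export
presence_percent <- function(positives, total) {
  stopifnot(length(positives) == length(total))
  if (any(total <= 0))
    stop("total must be positive", call. = FALSE)
  if (any(positives < 0 | positives > total))
    stop("positives must lie in [0, total]", call. = FALSE)
  as.integer(round_half_up(100 * positives / total))
}

#' Render a contingency table as text cells
#'
#' Count tables render as integers; sperm tables render each cell as
#' "positives/total (percent)". Empty cells render as an en dash, matching
#' the published tables.
#'
#' @param xtab a `cohort_xtab`.
#' @param source for sperm tables, which source's cells to render; `NULL`
#'   renders plain counts.
#' @return character matrix with the scheme's bin labels as dimnames.
#' @export
format_contingency <- function(xtab, source = NULL) {
  stopifnot(inherits(xtab, "cohort_xtab"))
  dash <- "–"
  if (is.null(source)) {
    out <- ifelse(xtab$counts == 0, dash, as.character(xtab$counts))
    dimnames(out) <- dimnames(xtab$counts)
    return(out)
  }
  if (is.null(xtab$sperm) || is.null(xtab$sperm[[source]]))
    stop("no sperm outcomes tabulated for source ", source, call. = FALSE)
  s <- xtab$sperm[[source]]
  out <- matrix(dash, nrow(s$totals), ncol(s$totals),
                dimnames = dimnames(s$totals))
  nz <- which(s$totals > 0)
  out[nz] <- sprintf("%d/%d (%d)", s$positives[nz], s$totals[nz],
                     presence_percent(s$positives[nz], s$totals[nz]))
  out
}

#' @export
print.cohort_xtab <- function(x, ...) {
  cat("Cohort cross-tabulation (", x$scheme$which, "), n = ", x$n, "\n",
      sep = "")
  disp <- cbind(x$counts, Total = x$row_totals)
  disp <- rbind(disp, Total = c(x$col_totals, x$n))
  print(disp)
  if (!is.null(x$sperm)) {
    for (src in names(x$sperm)) {
      cat("\nSperm presence, source =", src, "\n")
      print(format_contingency(x, src), quote = FALSE)
    }
  }
  invisible(x)
}
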