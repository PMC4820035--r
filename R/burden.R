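# Per-study CNV burden: counts, per-subject rates and case/control rate
# ratios, overall and by CNV type, plus a conditional binomial rate test.

#' Per-study CNV burden summary
#'
#' For each study (and optionally each CNV-type stratum): the number of
#' CNVs in cases and controls, per-subject rates
#' (`n_case_cnvs / n_cases`, `n_control_cnvs / n_controls`) and the
#' case/control rate ratio. Values are returned unrounded; presentation
#' rounding (rates to 3 dp, ratios to 2 dp) belongs to the caller or to
#' [format_burden_table()].
#'
#' @param cnvs a `cnv_table`.
#' @param cohorts a `cohort_table` supplying denominators; every study
#'   present in `cnvs` must appear.
#' @param stratum one of `"ALL"`, `"DEL"`, `"DUP"`, or several.
#' @param test attach the [burden_test()] p-value per row.
#' @return data.frame: `study_id, stratum, n_case_cnvs, n_control_cnvs,
#'   case_rate, control_rate, ratio, p_value`; `ratio` is `NA` (flagged
#'   via `ratio_defined`) when the control rate is zero.
#' @export
burden_summary <- function(cnvs, cohorts, stratum = c("ALL", "DEL", "DUP"),
                           test = TRUE) {
  stratum <- match.arg(stratum, several.ok = TRUE)
  unknown <- setdiff(unique(cnvs$study_id), cohorts$study_id)
  if (length(unknown))
    stop("study in CNV table but not in cohorts: ", paste(unknown, collapse = ", "))
  rows <- list()
  for (st in stratum) {
    sub <- if (st == "ALL") cnvs else cnvs[cnvs$cnv_type == st, , drop = FALSE]
    for (k in seq_len(nrow(cohorts))) {
      s <- cohorts$study_id[k]
      nc <- sum(sub$study_id == s & sub$is_case == 1L)
      nu <- sum(sub$study_id == s & sub$is_case == 0L)
      case_rate <- nc / cohorts$n_cases[k]
      control_rate <- nu / cohorts$n_controls[k]
      ratio <- if (control_rate > 0) case_rate / control_rate else NA_real_
      p <- if (test) burden_test_counts(nc, nu, cohorts$n_cases[k], cohorts$n_controls[k])
           else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = s, stratum = st, n_case_cnvs = nc, n_control_cnvs = nu,
        case_rate = case_rate, control_rate = control_rate,
        ratio = ratio, ratio_defined = control_rate > 0, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

burden_test_counts <- function(n_case_cnvs, n_control_cnvs, n_cases, n_controls) {
  N <- n_case_cnvs + n_control_cnvs
  if (N == 0) return(NA_real_)
  p0 <- n_cases / (n_cases + n_controls)
  lower <- stats::pbinom(n_case_cnvs, N, p0)
  upper <- stats::pbinom(n_case_cnvs - 1, N, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Conditional binomial burden rate test
#'
#' Conditions on the total number of CNVs `N` observed in a study: under
#' equal per-subject rates, the case CNV count is
#' `Binomial(N, n_cases / (n_cases + n_controls))`. Two-sided by doubling
#' the smaller tail, capped at 1. Note the original studies' burden
#' p-values were computed by their own (unspecified, likely permutation)
#' procedures; this test is this package's declared replacement and is
#' not expected to reproduce published burden p-values.
#'
#' @param summary_row one row of [burden_summary()] output, or a list with
#'   `n_case_cnvs, n_control_cnvs`.
#' @param cohorts a `cohort_table` (for denominators).
#' @return two-sided p-value, `NA` when the study has zero CNVs.
#' @export
burden_test <- function(summary_row, cohorts) {
  k <- match(summary_row$study_id, cohorts$study_id)
  if (is.na(k)) stop("study '", summary_row$study_id, "' not in cohorts")
  burden_test_counts(summary_row$n_case_cnvs, summary_row$n_control_cnvs,
                     cohorts$n_cases[k], cohorts$n_controls[k])
}

#' Presentation-rounded burden table
#'
#' Rounds rates to 3 decimal places and ratios to 2 (half-up, as printed
#' burden tables do), leaving the computed columns untouched upstream.
#'
#' @param burden output of [burden_summary()].
#' @return data.frame with `case_rate`, `control_rate`, `ratio` rounded.
#' @export
format_burden_table <- function(burden) {
  out <- burden
  out$case_rate <- round_half_up(out$case_rate, 3)
  out$control_rate <- round_half_up(out$control_rate, 3)
  out$ratio <- round_half_up(out$ratio, 2)
  out
}

# round() in R rounds half to even; printed tables round half up.
round_half_up <- function(x, digits) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
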