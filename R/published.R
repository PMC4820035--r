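# Published summary inputs: the per-study CNV counts (>500 kb window)
# and cohort sizes reported by the pooled five-study ADHD case-control
# CNV analysis. Individual-level CNV calls were never deposited, so
# these printed counts are the reproducible input for burden arithmetic.

#' Cohort sizes of the five pooled ADHD case-control studies
#'
#' Post-QC subject counts for the Canadian, Cardiff (UK), Children's
#' Hospital of Philadelphia (CHOP), IMAGE 2 and PUWMa studies.
#'
#' @return a `cohort_table` with five rows.
#' @export
adhd_cohorts <- function() {
  cohort_table(
    study_id = c("CANADA", "CARDIFF", "CHOP", "IMAGE2", "PUWMA"),
    n_cases = c(247L, 603L, 1013L, 732L, 692L),
    n_controls = c(2357L, 1047L, 4105L, 2010L, 1101L))
}

#' Published per-study CNV counts (>500 kb) by case status and type
#'
#' The reported numbers of rare CNVs longer than 500 kb in cases and
#' controls of each study, overall and split into deletions and
#' duplications. Together with [adhd_cohorts()] these reproduce the
#' published per-subject rates and case/control rate ratios.
#'
#' @return data.frame: `study_id, stratum, n_case_cnvs, n_control_cnvs`.
#' @export
adhd_cnv_counts <- function() {
  data.frame(
    study_id = rep(c("CANADA", "CARDIFF", "CHOP", "IMAGE2", "PUWMA"), each = 3),
    stratum = rep(c("ALL", "DEL", "DUP"), 5),
    n_case_cnvs = c(22L, 4L, 18L,
                    65L, 13L, 52L,
                    220L, 28L, 192L,
                    89L, 22L, 67L,
                    59L, 25L, 34L),
    n_control_cnvs = c(217L, 52L, 165L,
                       78L, 13L, 65L,
                       382L, 80L, 302L,
                       191L, 47L, 144L,
                       86L, 28L, 58L),
    stringsAsFactors = FALSE)
}

#' Published rate ratios recomputed from counts
#'
#' Runs the printed counts through the package's burden arithmetic:
#' rates are case (control) CNV counts over cohort sizes and the ratio
#' is their quotient, rounded half-up to 2 decimals as printed tables do.
#'
#' @return data.frame `study_id, stratum, case_rate, control_rate, ratio`
#'   (rates unrounded, ratio at 2 dp).
#' @export
adhd_burden_ratios <- function() {
  counts <- adhd_cnv_counts()
  cohorts <- adhd_cohorts()
  k <- match(counts$study_id, cohorts$study_id)
  case_rate <- counts$n_case_cnvs / cohorts$n_cases[k]
  control_rate <- counts$n_control_cnvs / cohorts$n_controls[k]
  data.frame(study_id = counts$study_id, stratum = counts$stratum,
             case_rate = case_rate, control_rate = control_rate,
             ratio = round_half_up(case_rate / control_rate, 2),
             stringsAsFactors = FALSE)
}
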