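#' Classify radiological response under RECIST 1.1 (single lesion)
#'
#' Percent change is `100 * (post - baseline) / baseline`. A disappeared
#' lesion (post = 0) is a complete response; a decrease of at least 30% a
#' partial response; an increase of at least 20% progressive disease;
#' anything in between stable disease. Exact-threshold ties go to PR/PD:
#' the "at least" wording of those classes wins over the overlapping
#' "maximum" wording of stable disease. The RECIST 1.1 absolute 5-mm growth
#' minimum is deliberately not applied; only the percentage rule is used.
#'
#' @param baseline_mm Baseline longest diameter(s), mm, strictly positive.
#' @param post_mm Post-treatment diameter(s), mm, non-negative.
#' @return Data frame with columns `class` (factor with levels
#'   complete_response, partial_response, stable_disease,
#'   progressive_disease) and `percent_change`.
#' @export
classify_recist <- function(baseline_mm, post_mm) {
  if (any(!is.finite(baseline_mm)) || any(baseline_mm <= 0))
    stop_rimquant("baseline diameter must be positive", class = "rimquant_validation")
  if (any(!is.finite(post_mm)) || any(post_mm < 0))
    stop_rimquant("post-treatment diameter must be non-negative",
                  class = "rimquant_validation")
  pc <- 100 * (post_mm - baseline_mm) / baseline_mm
  cls <- ifelse(post_mm == 0, "complete_response",
         ifelse(pc <= -30, "partial_response",
         ifelse(pc >= 20, "progressive_disease", "stable_disease")))
  data.frame(class = factor(cls, levels = c("complete_response",
                                            "partial_response",
                                            "stable_disease",
                                            "progressive_disease")),
             percent_change = pc)
}

#' Grade hepatic steatosis from the affected-hepatocyte fraction
#'
#' Brunt grading: none below 5%, mild 5 to under 34%, moderate 34 to under
#' 67%, severe above. The printed bins (5-33 / 34-66) leave 33-34 and 66-67
#' unassigned; the scheme is contiguous, so each gap is folded into the
#' lower grade.
#'
#' @param fraction_percent Fraction(s) of affected hepatocytes, 0-100.
#' @return Ordered factor none < mild < moderate < severe.
#' @export
grade_steatosis <- function(fraction_percent) {
  if (any(!is.finite(fraction_percent)) || any(fraction_percent < 0) ||
      any(fraction_percent > 100))
    stop_rimquant("steatosis fraction must lie in [0, 100]",
                  class = "rimquant_validation")
  cut(fraction_percent, breaks = c(-Inf, 5, 34, 67, Inf), right = FALSE,
      labels = c("none", "mild", "moderate", "severe"), ordered_result = TRUE)
}

#' Was the patient pretreated with chemotherapy?
#'
#' Pretreatment means the last chemotherapy cycle started within three
#' months before surgery, operationalized as 90 days. A missing chemo date
#' means not pretreated.
#'
#' @param chemo_last_cycle_start `Date` (or `NA`) when the last cycle began.
#' @param surgery_date `Date` of surgery.
#' @param window_days Pretreatment window (default 90).
#' @return Logical vector.
#' @export
is_pretreated <- function(chemo_last_cycle_start, surgery_date, window_days = 90) {
  chemo_last_cycle_start <- as.Date(chemo_last_cycle_start)
  surgery_date <- as.Date(surgery_date)
  if (anyNA(surgery_date))
    stop_rimquant("surgery_date is required", class = "rimquant_validation")
  gap <- as.numeric(surgery_date - chemo_last_cycle_start)
  if (any(!is.na(gap) & gap < 0))
    stop_rimquant("chemotherapy date after surgery", class = "rimquant_validation")
  !is.na(gap) & gap <= window_days
}
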