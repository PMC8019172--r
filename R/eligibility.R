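#' Comorbidity index at an index year
#'
#' The comorbidity index (CI) of a subject is the number of distinct
#' chronic diagnosis codes registered up to and including the index
#' year. It is used as a matching variable to balance the disease load
#' of cases and controls, so that a severely ill case is not matched to
#' a healthy control.
#'
#' @param diagnoses Data frame of the subject's diagnosis history with
#'   columns `code` and `year` (one row per registration; repeat
#'   registrations of the same code are counted once).
#' @param index_year Integer year; registrations after it are ignored.
#' @param chronic_codes Optional character vector of codes that count as
#'   chronic; `NULL` counts every distinct code present.
#' @return A non-negative integer count.
#' @examples
#' dg <- data.frame(code = c("K74", "T90", "K74"),
#'                  year = c(2004, 2008, 2009))
#' comorbidity_index(dg, 2010)  # 2 distinct codes
#' @export
comorbidity_index <- function(diagnoses, index_year, chronic_codes = NULL) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0) return(0L)
  keep <- diagnoses$year <= index_year
  if (!is.null(chronic_codes)) keep <- keep & diagnoses$code %in% chronic_codes
  length(unique(diagnoses$code[keep]))
}

#' Comorbidity-index eligibility of a case-control pair
#'
#' Under `"exact"` balancing the control must carry the same number of
#' chronic diseases as the case; under `"varying"` an absolute
#' difference up to `threshold` is allowed (threshold 1 means a case
#' with 3 diseases accepts controls with 2, 3 or 4); `"none"` disables
#' the constraint.
#'
#' @param case_ci,control_ci Non-negative integer comorbidity indices.
#' @param mode `"none"`, `"exact"` or `"varying"`.
#' @param threshold Non-negative integer, used when `mode = "varying"`.
#' @return Logical (vectorised over the ci arguments).
#' @export
ci_eligible <- function(case_ci, control_ci,
                        mode = c("none", "exact", "varying"),
                        threshold = 1L) {
  mode <- match.arg(mode)
  if (threshold < 0) stop("'threshold' must be non-negative")
  switch(mode,
         none = rep(TRUE, length(case_ci)),
         exact = case_ci == control_ci,
         varying = abs(case_ci - control_ci) <= threshold)
}

#' Follow-up eligibility of a case-control pair
#'
#' Registry follow-up is matched on the entry year. `"exact"` requires
#' case and control to have entered the registry the same year;
#' `"trimmed"` allows the control to have entered earlier (the control
#' then has at least as many years of follow-up as the case); `"off"`
#' disables the constraint.
#'
#' @param case_entry,control_entry Integer registry entry years.
#' @param mode `"exact"`, `"trimmed"` or `"off"`.
#' @return Logical (vectorised over the entry years).
#' @examples
#' follow_up_eligible(2004, 2003, "exact")    # FALSE
#' follow_up_eligible(2004, 2003, "trimmed")  # TRUE
#' @export
follow_up_eligible <- function(case_entry, control_entry,
                               mode = c("exact", "trimmed", "off")) {
  mode <- match.arg(mode)
  switch(mode,
         exact = case_entry == control_entry,
         trimmed = control_entry <= case_entry,
         off = rep(TRUE, length(case_entry)))
}
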