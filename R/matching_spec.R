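#' Matching configuration
#'
#' Bundles the full configuration of one matching run: which variables
#' are matched exactly, the calipers and weights of the varying
#' variables, how registry follow-up and the comorbidity index are
#' handled, the number of controls per case and whether controls are
#' sampled with replacement.
#'
#' @param exact_vars Character vector of exactly matched variables.
#'   Supported names are `"sex"`, `"practice_id"` and `"jcg"` (the
#'   yearly contact group: a control qualifies for a case's subset when
#'   it consulted the GP in the case's index year).
#' @param age_caliper Maximum allowed absolute age difference in whole
#'   years (non-negative).
#' @param follow_up One of `"exact"` (case and control entered the
#'   registry the same year), `"trimmed"` (the control entered in or
#'   before the case's entry year) or `"off"`.
#' @param ci One of `"none"`, `"exact"` or `"varying"`: how the
#'   comorbidity index (count of distinct chronic diagnoses registered
#'   up to the index year) is balanced between case and control.
#' @param ci_threshold Maximum allowed absolute comorbidity-index
#'   difference when `ci = "varying"`.
#' @param n_controls Number of controls sought per case (one matching
#'   round per control).
#' @param replacement Logical; may one control serve several cases?
#'   Within a single case's set a control is never repeated.
#' @param weights Named positive weights of the varying difference
#'   variables, used to compute the pair distance
#'   \eqn{D_{ij} = \sum_k |x_{ik}^{1} - x_{ik}^{0}| W_k}.
#' @param ordering_priority Order in which difference variables are
#'   compared when ranking a case's candidate controls. Any of
#'   `"follow_up_diff"`, `"age_diff"`, `"ci_diff"`, `"distance"`. The
#'   default puts the follow-up difference before the age difference;
#'   after these the control frequency breaks ties, then the control id.
#' @param chronic_codes Optional character vector restricting which
#'   diagnosis codes count as chronic when computing the comorbidity
#'   index; `NULL` counts every distinct code in the diagnosis history.
#' @param exposure_codes Optional character vector restricting which
#'   prescription codes count as the exposure; `NULL` counts any.
#'
#' @return An object of class `matching_spec`.
#' @examples
#' matching_spec(age_caliper = 2, follow_up = "trimmed", ci = "varying")
#' @export
matching_spec <- function(exact_vars = c("sex", "practice_id", "jcg"),
                          age_caliper = 2,
                          follow_up = c("trimmed", "exact", "off"),
                          ci = c("none", "exact", "varying"),
                          ci_threshold = 1L,
                          n_controls = 4L,
                          replacement = FALSE,
                          weights = c(follow_up_diff = 1, age_diff = 1,
                                      ci_diff = 1),
                          ordering_priority = c("follow_up_diff",
                                                "age_diff"),
                          chronic_codes = NULL,
                          exposure_codes = NULL) {
  follow_up <- match.arg(follow_up)
  ci <- match.arg(ci)
  known_exact <- c("sex", "practice_id", "jcg")
  if (!all(exact_vars %in% known_exact))
    stop("unknown exact variable(s): ",
         paste(setdiff(exact_vars, known_exact), collapse = ", "))
  if (!is.numeric(age_caliper) || length(age_caliper) != 1 ||
      is.na(age_caliper) || age_caliper < 0)
    stop("'age_caliper' must be a single non-negative number")
  if (!is.numeric(ci_threshold) || length(ci_threshold) != 1 ||
      is.na(ci_threshold) || ci_threshold < 0)
    stop("'ci_threshold' must be a single non-negative integer")
  if (!is.numeric(n_controls) || length(n_controls) != 1 ||
      is.na(n_controls) || n_controls < 1)
    stop("'n_controls' must be a positive integer")
  if (!is.logical(replacement) || length(replacement) != 1 ||
      is.na(replacement))
    stop("'replacement' must be TRUE or FALSE")
  if (any(weights <= 0) || is.null(names(weights)))
    stop("'weights' must be named and strictly positive")
  allowed_order <- c("follow_up_diff", "age_diff", "ci_diff", "distance")
  if (!all(ordering_priority %in% allowed_order))
    stop("unknown ordering variable(s): ",
         paste(setdiff(ordering_priority, allowed_order), collapse = ", "))
  structure(
    list(exact_vars = exact_vars,
         age_caliper = as.numeric(age_caliper),
         follow_up = follow_up,
         ci = ci,
         ci_threshold = as.integer(ci_threshold),
         n_controls = as.integer(n_controls),
         replacement = replacement,
         weights = weights,
         ordering_priority = ordering_priority,
         chronic_codes = chronic_codes,
         exposure_codes = exposure_codes),
    class = "matching_spec")
}

#' @export
print.matching_spec <- function(x, ...) {
  cat("Case-control matching specification\n")
  cat("  exact variables :", paste(x$exact_vars, collapse = ", "), "\n")
  cat("  age caliper     :", x$age_caliper, "years\n")
  cat("  follow-up       :", x$follow_up, "\n")
  cat("  comorbidity idx :", x$ci,
      if (x$ci == "varying") sprintf("(threshold %d)", x$ci_threshold)
      else "", "\n")
  cat("  controls/case   :", x$n_controls,
      if (x$replacement) "(with replacement)" else "(without replacement)",
      "\n")
  invisible(x)
}

# Difference variables that enter the distance under this spec.
# Exact modes force a zero difference, so only truly varying terms count.
active_distance_vars <- function(spec) {
  vars <- "age_diff"
  if (spec$follow_up == "trimmed") vars <- c(vars, "follow_up_diff")
  if (spec$ci == "varying") vars <- c(vars, "ci_diff")
  vars
}
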