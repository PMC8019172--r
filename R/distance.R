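#' Weighted absolute-difference distance between a case and a control
#'
#' The matching distance between case \eqn{i} and potential control
#' \eqn{j} is the weighted sum of absolute differences over the varying
#' matching variables,
#' \deqn{D_{ij} = \sum_{k=1}^{p} |x_{ik}^{1} - x_{ik}^{0}| \, W_k,}
#' where \eqn{x^{1}} and \eqn{x^{0}} are the case's and control's values
#' and \eqn{W_k > 0} the per-variable weights. Exactly matched variables
#' never differ within a subset and so contribute nothing.
#'
#' @param case_values,control_values Numeric vectors of equal length
#'   `p`, the varying matching variables of the case and the control.
#' @param weights Positive numeric vector of length `p` (default all 1).
#' @return A single non-negative number.
#' @examples
#' pair_distance(c(50, 2004), c(48, 2004))          # 2
#' pair_distance(c(50, 2004), c(48, 2003), c(1, 3)) # 5
#' @seealso [total_distance()]
#' @export
pair_distance <- function(case_values, control_values,
                          weights = rep(1, length(case_values))) {
  if (length(case_values) != length(control_values))
    stop("'case_values' and 'control_values' must have the same length")
  if (length(weights) != length(case_values))
    stop("'weights' must have the same length as the value vectors")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be finite and strictly positive")
  sum(abs(case_values - control_values) * weights)
}

#' Total distance of a matched cohort
#'
#' The total distance \eqn{T = \sum_i D_{ij}} over all matched
#' (case, control, round) slots summarises how close the whole matched
#' sample is; the matcher aims to minimise it.
#'
#' @param cohort A [cc_match()] result, or a data frame of matched pairs
#'   with a `distance` column.
#' @return A single non-negative number; 0 for an empty cohort.
#' @export
total_distance <- function(cohort) {
  pairs <- if (inherits(cohort, "cc_cohort")) cohort$matched else cohort
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  sum(pairs$distance)
}
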