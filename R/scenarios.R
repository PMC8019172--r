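#' Build the analysis data set from a matched cohort
#'
#' Joins the matched sets back to the registry: one row per set member
#' (the case plus its matched controls), with the case indicator and
#' the exposure status derived from the prescription history — a
#' subject counts as exposed when it has at least one qualifying
#' prescription in or before the set's index year (the case's
#' diagnosis year, which its controls inherit).
#'
#' @param cohort A [cc_match()] result.
#' @param registry The registry the cohort was matched from.
#' @param exposure_codes Optional character vector of prescription
#'   codes that define the exposure; `NULL` counts any prescription.
#' @return Data frame with columns `set_id` (the case id), `subject_id`,
#'   `is_case`, `exposed`, `index_year`.
#' @export
matched_sets_data <- function(cohort, registry, exposure_codes = NULL) {
  m <- cohort$matched
  subjects <- registry$subjects
  case_ids <- unique(m$case_id)
  iy <- setNames(subjects$index_year[match(case_ids, subjects$subject_id)],
                 case_ids)
  out <- rbind(
    data.frame(set_id = case_ids, subject_id = case_ids,
               is_case = TRUE, stringsAsFactors = FALSE),
    data.frame(set_id = m$case_id, subject_id = m$control_id,
               is_case = FALSE, stringsAsFactors = FALSE))
  out$index_year <- as.integer(iy[out$set_id])
  ex <- registry$exposures
  if (!is.null(exposure_codes)) ex <- ex[ex$code %in% exposure_codes, ,
                                         drop = FALSE]
  first_rx <- if (nrow(ex) == 0)
    integer(0) else tapply(ex$year, ex$subject_id, min)
  fy <- first_rx[out$subject_id]
  out$exposed <- !is.na(fy) & fy <= out$index_year
  out <- out[order(out$set_id, !out$is_case, out$subject_id), ]
  rownames(out) <- NULL
  out
}

#' Factorial grid of matching scenarios
#'
#' Builds the full Cartesian product of matching-configuration levels
#' used for the odds-ratio sensitivity analysis. The default grid — six
#' age calipers, exact and trimmed follow-up, three comorbidity-index
#' modes and both replacement arms — yields the canonical 72 scenarios
#' (36 per replacement arm).
#'
#' @param age_calipers Numeric vector of age calipers (years).
#' @param follow_up Character vector of follow-up modes.
#' @param ci Character vector of comorbidity-index modes.
#' @param replacement Logical vector of replacement arms.
#' @param n_controls Controls per case (single value, default 4).
#' @return Data frame with one row per scenario, columns `scenario_id`,
#'   `age_caliper`, `follow_up`, `ci`, `replacement`, `n_controls`;
#'   deterministic order, no duplicates.
#' @examples
#' nrow(build_scenario_grid())  # 72
#' @export
build_scenario_grid <- function(age_calipers = 0:5,
                                follow_up = c("exact", "trimmed"),
                                ci = c("none", "exact", "varying"),
                                replacement = c(FALSE, TRUE),
                                n_controls = 4L) {
  if (length(age_calipers) == 0 || length(follow_up) == 0 ||
      length(ci) == 0 || length(replacement) == 0)
    stop("every scenario factor needs at least one level")
  g <- expand.grid(age_caliper = age_calipers, follow_up = follow_up,
                   ci = ci, replacement = replacement,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(g)) stop("duplicate scenario levels supplied")
  g$n_controls <- as.integer(n_controls)
  g <- g[order(g$replacement, g$follow_up, g$ci, g$age_caliper), ]
  g$scenario_id <- seq_len(nrow(g))
  rownames(g) <- NULL
  g[, c("scenario_id", "age_caliper", "follow_up", "ci", "replacement",
        "n_controls")]
}

#' Run the matching and odds-ratio analysis over a scenario grid
#'
#' For every scenario the base specification is specialised, the
#' registry matched, and the exposure odds ratio estimated by
#' conditional logistic regression on the matched sets. A failure in
#' one scenario (e.g. no informative sets) is recorded in its row and
#' does not abort the batch.
#'
#' @param registry A registry object.
#' @param grid A [build_scenario_grid()] data frame.
#' @param base_spec A [matching_spec()] supplying everything the grid
#'   does not vary (exact variables, weights, thresholds, code lists).
#' @return Data frame with one row per scenario: the scenario columns
#'   plus `n_cases_matched`, `n_unique_controls`, `n_slots`,
#'   `controls_1` ... `controls_n` (how many cases obtained each number
#'   of controls), `total_distance`, `or`, `ci_low`, `ci_high`,
#'   `n_informative_sets` and `error` (NA when the scenario succeeded).
#' @export
run_scenarios <- function(registry, grid = build_scenario_grid(),
                          base_spec = matching_spec()) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid[i, ]
    out <- sc
    out$n_cases_matched <- NA_integer_
    out$n_unique_controls <- NA_integer_
    out$n_slots <- NA_integer_
    for (k in seq_len(sc$n_controls))
      out[[paste0("controls_", k)]] <- NA_integer_
    out$total_distance <- NA_real_
    out$or <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
    out$n_informative_sets <- NA_integer_
    out$error <- NA_character_
    tryCatch({
      spec <- base_spec
      spec$age_caliper <- sc$age_caliper
      spec$follow_up <- sc$follow_up
      spec$ci <- sc$ci
      spec$replacement <- sc$replacement
      spec$n_controls <- sc$n_controls
      cohort <- cc_match(registry, spec)
      out$n_cases_matched <- cohort$n_cases_matched
      out$n_unique_controls <- cohort$n_unique_controls
      out$n_slots <- nrow(cohort$matched)
      hist <- controls_per_case(cohort)
      for (k in seq_len(sc$n_controls))
        out[[paste0("controls_", k)]] <- hist[[k]]
      out$total_distance <- cohort$total_distance
      sets <- matched_sets_data(cohort, registry,
                                base_spec$exposure_codes)
      fit <- suppressWarnings(
        clr_fit(is_case ~ exposed, sets, set = "set_id"))
      if (fit$converged) {
        orr <- odds_ratios(fit)
        out$or <- orr$or[1]
        out$ci_low <- orr$ci_low[1]
        out$ci_high <- orr$ci_high[1]
      } else {
        out$error <- "clr did not converge"
      }
      out$n_informative_sets <- fit$n_informative_sets
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
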