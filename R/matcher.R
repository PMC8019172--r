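#' Select the best remaining control for every case
#'
#' Given candidates ordered by [order_candidates()], the first row per
#' case is that case's closest available control under the configured
#' priority.
#'
#' @param ordered_candidates An ordered candidate data frame.
#' @return One row per case id present in the input.
#' @export
select_top_per_case <- function(ordered_candidates) {
  ordered_candidates[!duplicated(ordered_candidates$case_id), ,
                     drop = FALSE]
}

#' Split a selection into unique and duplicated controls
#'
#' A control selected by two or more cases in the same iteration is
#' "duplicated" and must be arbitrated when matching without
#' replacement; controls selected by exactly one case are "unique" and
#' can be assigned immediately.
#'
#' @param selected One selected row per case ([select_top_per_case()]).
#' @return A list with data frames `unique` and `duplicated`; the two
#'   parts partition the input.
#' @export
split_duplicates <- function(selected) {
  if (nrow(selected) == 0)
    return(list(unique = selected, duplicated = selected))
  n_by_control <- table(selected$control_id)
  dup <- selected$control_id %in% names(n_by_control)[n_by_control >= 2]
  list(unique = selected[!dup, , drop = FALSE],
       duplicated = selected[dup, , drop = FALSE])
}

#' Arbitrate contested controls by the least-pool-first rule
#'
#' Each contested control is assigned to the competing case with the
#' smallest remaining pool (`total_controls_per_case`); on ties the
#' smaller case id wins. Losing cases return to the pool and are
#' retried in the next inner iteration. This rule is what makes the
#' sequential selection optimal in practice: a case with few options is
#' never robbed of them by a case that has plenty.
#'
#' @param duplicated Rows of contested controls ([split_duplicates()]).
#' @return One winning row per contested control id.
#' @export
resolve_duplicates <- function(duplicated) {
  if (nrow(duplicated) == 0) return(duplicated)
  o <- order(duplicated$control_id, duplicated$total_controls_per_case,
             duplicated$case_id)
  duplicated <- duplicated[o, , drop = FALSE]
  duplicated[!duplicated(duplicated$control_id), , drop = FALSE]
}

#' Assign controls to cases over matching rounds
#'
#' The core assignment engine. One round is run per requested control:
#' within a round, pool statistics are recomputed, candidates
#' re-ordered, one control selected per still-unserved case, contested
#' controls arbitrated by [resolve_duplicates()], and (without
#' replacement) assigned controls removed from the pool; the inner
#' iteration repeats until every case with a non-empty pool has
#' received a control this round. The engine is fully deterministic:
#' identical inputs give identical assignments.
#'
#' @param candidates Candidate rows ([expand_candidates()] output,
#'   several subsets may be stacked); pool statistics are (re)computed
#'   internally.
#' @param spec A [matching_spec()]; `n_controls`, `replacement` and
#'   `ordering_priority` are used.
#' @param case_ids Optional character vector of all case ids that
#'   sought controls (defaults to those present in `candidates`); used
#'   to report cases left without a single control.
#' @return A list with `matched` (data frame: candidate columns plus
#'   `round`) and `unmatched_case_ids`.
#' @export
assign_controls <- function(candidates, spec,
                            case_ids = unique(candidates$case_id)) {
  cand <- candidates
  matched <- list()
  for (r in seq_len(spec$n_controls)) {
    pending <- intersect(case_ids, unique(cand$case_id))
    while (length(pending) > 0) {
      sub <- cand[cand$case_id %in% pending, , drop = FALSE]
      if (nrow(sub) == 0) break
      sub <- annotate_pool_stats(sub)
      sub <- order_candidates(sub, spec$ordering_priority)
      sel <- select_top_per_case(sub)
      if (spec$replacement) {
        winners <- sel
      } else {
        parts <- split_duplicates(sel)
        winners <- rbind(parts$unique, resolve_duplicates(parts$duplicated))
      }
      if (nrow(winners) == 0) break
      winners$round <- r
      matched[[length(matched) + 1L]] <- winners
      pending <- setdiff(pending, winners$case_id)
      if (spec$replacement) {
        # a control may serve other cases, but never the same case twice
        drop <- paste(cand$case_id, cand$control_id) %in%
          paste(winners$case_id, winners$control_id)
        cand <- cand[!drop, , drop = FALSE]
      } else {
        cand <- cand[!(cand$control_id %in% winners$control_id), ,
                     drop = FALSE]
      }
    }
  }
  matched <- if (length(matched) > 0) do.call(rbind, matched) else
    cbind(candidates[0, , drop = FALSE], round = integer(0))
  rownames(matched) <- NULL
  o <- order(matched$case_id, matched$round)
  matched <- matched[o, , drop = FALSE]
  list(matched = matched,
       unmatched_case_ids = sort(setdiff(case_ids, matched$case_id)))
}

#' Match cases to controls in a registry
#'
#' Runs the full pipeline on a registry object: exact-variable
#' subsetting, candidate expansion under the calipers, pool statistics,
#' ordering, and the round-based optimal assignment, returning a
#' matched cohort.
#'
#' Control covariates are evaluated at the index year the control
#' inherits from the case: age is the index year minus the birth year,
#' and the comorbidity index counts distinct chronic codes registered
#' up to the index year. When `"jcg"` is an exact variable a control is
#' eligible for a case only if it consulted the GP in the case's index
#' year.
#'
#' @param registry A registry object ([generate_registry()],
#'   [read_registry()] or [toy_fixture()]): a list with data frames
#'   `subjects`, `contacts`, `diagnoses`, `exposures`.
#' @param spec A [matching_spec()].
#' @return An object of class `cc_cohort`: a list with `matched`
#'   (one row per matched case-control slot: `case_id`, `control_id`,
#'   `round`, `subset_key`, differences and `distance`),
#'   `unmatched_case_ids`, `n_cases`, `n_unique_controls`,
#'   `total_distance` and the `spec` used.
#' @examples
#' reg <- toy_fixture()
#' cc_match(reg, matching_spec(n_controls = 1))
#' @export
cc_match <- function(registry, spec = matching_spec()) {
  subjects <- registry$subjects
  cases <- subjects[subjects$is_case, , drop = FALSE]
  controls <- subjects[!subjects$is_case, , drop = FALSE]
  if (nrow(cases) == 0) {
    warning("no cases in the registry; returning an empty cohort")
    return(new_cc_cohort(
      cbind(empty_candidates(), round = integer(0)),
      character(0), 0L, spec))
  }
  if (any(is.na(cases$index_year)))
    stop("every case must have an index year before matching")

  case_frame <- data.frame(
    subject_id = cases$subject_id,
    sex = cases$sex,
    practice_id = cases$practice_id,
    entry_year = cases$entry_year,
    jcg = cases$index_year,
    age = cases$index_year - cases$birth_year,
    stringsAsFactors = FALSE)
  case_frame$ci <- ci_pairs(registry$diagnoses, case_frame$subject_id,
                            cases$index_year, spec$chronic_codes)

  index_years <- sort(unique(cases$index_year))
  if ("jcg" %in% spec$exact_vars) {
    ct <- registry$contacts
    ct <- ct[ct$subject_id %in% controls$subject_id &
               ct$year %in% index_years, , drop = FALSE]
    ctrl_rep <- unique(ct[, c("subject_id", "year")])
  } else {
    ctrl_rep <- expand.grid(subject_id = controls$subject_id,
                            year = index_years,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  }
  m <- match(ctrl_rep$subject_id, controls$subject_id)
  control_frame <- data.frame(
    subject_id = ctrl_rep$subject_id,
    sex = controls$sex[m],
    practice_id = controls$practice_id[m],
    entry_year = controls$entry_year[m],
    jcg = ctrl_rep$year,
    age = ctrl_rep$year - controls$birth_year[m],
    stringsAsFactors = FALSE)
  control_frame$ci <- ci_pairs(registry$diagnoses,
                               control_frame$subject_id,
                               control_frame$jcg, spec$chronic_codes)

  split_vars <- union(spec$exact_vars, "jcg")
  subsets <- split_exact_subsets(case_frame, control_frame, split_vars)
  cand_list <- lapply(subsets, expand_candidates, spec = spec)
  candidates <- do.call(rbind, c(list(empty_candidates()), cand_list))
  candidates <- annotate_pool_stats(candidates)

  res <- assign_controls(candidates, spec,
                         case_ids = case_frame$subject_id)
  new_cc_cohort(res$matched, res$unmatched_case_ids, nrow(cases), spec)
}

empty_candidates <- function() {
  data.frame(subset_key = character(0), case_id = character(0),
             control_id = character(0), age_diff = numeric(0),
             follow_up_diff = numeric(0), ci_diff = numeric(0),
             distance = numeric(0), stringsAsFactors = FALSE)
}

new_cc_cohort <- function(matched, unmatched_case_ids, n_cases, spec) {
  structure(
    list(matched = matched,
         unmatched_case_ids = unmatched_case_ids,
         n_cases = n_cases,
         n_cases_matched = length(unique(matched$case_id)),
         n_unique_controls = length(unique(matched$control_id)),
         total_distance = total_distance(matched),
         spec = spec),
    class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("Matched case-control cohort (1:%d, %s replacement)\n",
              x$spec$n_controls,
              if (x$spec$replacement) "with" else "without"))
  cat(sprintf("  cases matched   : %d of %d\n", x$n_cases_matched,
              x$n_cases))
  cat(sprintf("  controls used   : %d unique (%d slots)\n",
              x$n_unique_controls, nrow(x$matched)))
  cat(sprintf("  total distance T: %g\n", x$total_distance))
  if (length(x$unmatched_case_ids) > 0)
    cat(sprintf("  unmatched cases : %d\n", length(x$unmatched_case_ids)))
  invisible(x)
}

#' @export
summary.cc_cohort <- function(object, ...) {
  hist <- controls_per_case(object)
  structure(list(cohort = object, controls_per_case = hist),
            class = "summary.cc_cohort")
}

#' @export
print.summary.cc_cohort <- function(x, ...) {
  print(x$cohort)
  cat("  controls per matched case:\n")
  print(x$controls_per_case)
  invisible(x)
}

#' @export
as.data.frame.cc_cohort <- function(x, ...) x$matched

#' Histogram of controls per matched case
#'
#' @param cohort A `cc_cohort`.
#' @return Named integer vector: how many cases obtained 1, 2, ...,
#'   `n_controls` controls. Counts sum to the number of matched cases.
#' @export
controls_per_case <- function(cohort) {
  n <- cohort$spec$n_controls
  got <- table(factor(table(cohort$matched$case_id), levels = seq_len(n)))
  setNames(as.integer(got), paste0("controls_", seq_len(n)))
}

# Comorbidity index for vectors of (subject, year) pairs.
ci_pairs <- function(diagnoses, ids, years, chronic_codes = NULL) {
  out <- integer(length(ids))
  if (is.null(diagnoses) || nrow(diagnoses) == 0 || length(ids) == 0)
    return(out)
  dg <- diagnoses[diagnoses$subject_id %in% unique(ids), , drop = FALSE]
  if (!is.null(chronic_codes))
    dg <- dg[dg$code %in% chronic_codes, , drop = FALSE]
  if (nrow(dg) == 0) return(out)
  for (y in unique(years)) {
    sel <- years == y
    d2 <- unique(dg[dg$year <= y, c("subject_id", "code")])
    cnt <- table(d2$subject_id)
    hit <- as.integer(cnt[ids[sel]])
    hit[is.na(hit)] <- 0L
    out[sel] <- hit
  }
  out
}
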