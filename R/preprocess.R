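#' Split cases and controls into exact-matching subsets
#'
#' The first pre-processing step: cases and controls are grouped by the
#' factorial combination of the exact matching variables, and all later
#' work happens independently within each subset. Only combinations
#' containing at least one case are kept; controls whose key matches no
#' case key are discarded. A control row may match several subsets only
#' if it appears as several rows (e.g. one row per contact year when the
#' yearly contact group is an exact variable); each row lands in the
#' single subset its key selects.
#'
#' @param cases,controls Data frames with one row per (replicated)
#'   subject carrying at least the `exact_vars` columns and a
#'   `subject_id` column.
#' @param exact_vars Character vector of column names to match exactly.
#' @return A list of subsets, each a list with elements `key` (named
#'   character vector), `subset_key` (the key collapsed to one string),
#'   `cases` and `controls` (data frames; `controls` may have zero
#'   rows, in which case the subset is flagged with attribute
#'   `empty_pool`).
#' @export
split_exact_subsets <- function(cases, controls, exact_vars) {
  for (v in exact_vars) {
    if (!v %in% names(cases) || !v %in% names(controls))
      stop("exact variable '", v, "' missing from input")
    bad <- is.na(cases[[v]])
    if (any(bad))
      stop("missing value of exact variable '", v, "' for case(s): ",
           paste(cases$subject_id[bad], collapse = ", "))
  }
  key_of <- function(df) {
    if (length(exact_vars) == 0) return(rep("", nrow(df)))
    do.call(paste, c(lapply(exact_vars, function(v) as.character(df[[v]])),
                     sep = "|"))
  }
  case_keys <- key_of(cases)
  control_keys <- key_of(controls)
  out <- lapply(sort(unique(case_keys)), function(k) {
    cs <- cases[case_keys == k, , drop = FALSE]
    ct <- controls[control_keys == k, , drop = FALSE]
    key <- setNames(as.character(cs[1, exact_vars]), exact_vars)
    sub <- list(key = key, subset_key = k, cases = cs, controls = ct)
    if (nrow(ct) == 0) attr(sub, "empty_pool") <- TRUE
    sub
  })
  out
}

#' Expand a subset into case-control candidate rows
#'
#' The second pre-processing step replicates every eligible control into
#' every case's pool ("artificial observations"), one candidate row per
#' case-control pair that satisfies all varying constraints: the age
#' caliper, the follow-up rule and the comorbidity-index rule. Each row
#' carries the per-variable differences and the weighted distance
#' \eqn{D_{ij}}.
#'
#' @param subset One element of [split_exact_subsets()]: `cases` and
#'   `controls` data frames with columns `subject_id`, `age`,
#'   `entry_year` and (unless `spec$ci == "none"`) `ci`, all evaluated
#'   at the relevant index year.
#' @param spec A [matching_spec()].
#' @return A data frame of candidate rows (possibly zero rows) with
#'   columns `subset_key`, `case_id`, `control_id`, `age_diff`,
#'   `follow_up_diff`, `ci_diff`, `distance`.
#' @export
expand_candidates <- function(subset, spec) {
  cs <- subset$cases
  ct <- subset$controls
  empty <- data.frame(subset_key = character(0), case_id = character(0),
                      control_id = character(0), age_diff = numeric(0),
                      follow_up_diff = numeric(0), ci_diff = numeric(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cs) == 0 || nrow(ct) == 0) return(empty)
  idx <- expand.grid(i = seq_len(nrow(cs)), j = seq_len(nrow(ct)),
                     KEEP.OUT.ATTRS = FALSE)
  age_diff <- abs(cs$age[idx$i] - ct$age[idx$j])
  fu_diff <- cs$entry_year[idx$i] - ct$entry_year[idx$j]
  if (spec$follow_up == "off") fu_diff <- abs(fu_diff)
  have_ci <- "ci" %in% names(cs) && "ci" %in% names(ct)
  ci_diff <- if (have_ci) abs(cs$ci[idx$i] - ct$ci[idx$j]) else
    rep(NA_real_, nrow(idx))
  keep <- age_diff <= spec$age_caliper &
    follow_up_eligible(cs$entry_year[idx$i], ct$entry_year[idx$j],
                       spec$follow_up)
  if (spec$ci != "none") {
    if (!have_ci) stop("spec requires comorbidity-index balancing but the ",
                       "subset carries no 'ci' column")
    keep <- keep & ci_eligible(cs$ci[idx$i], ct$ci[idx$j], spec$ci,
                               spec$ci_threshold)
  }
  if (!any(keep)) return(empty)
  out <- data.frame(
    subset_key = rep(subset$subset_key, sum(keep)),
    case_id = cs$subject_id[idx$i[keep]],
    control_id = ct$subject_id[idx$j[keep]],
    age_diff = as.numeric(age_diff[keep]),
    follow_up_diff = as.numeric(fu_diff[keep]),
    ci_diff = as.numeric(ci_diff[keep]),
    stringsAsFactors = FALSE)
  w <- spec$weights
  dist <- out$age_diff * w[["age_diff"]]
  if (spec$follow_up == "trimmed")
    dist <- dist + out$follow_up_diff * w[["follow_up_diff"]]
  if (spec$ci == "varying")
    dist <- dist + out$ci_diff * w[["ci_diff"]]
  out$distance <- dist
  out
}

#' Annotate candidate rows with pool statistics
#'
#' The third pre-processing step adds the two auxiliary variables that
#' drive the optimal assignment: `total_controls_per_case`, the size of
#' each case's remaining pool (the case with the smallest pool wins a
#' contested control), and `frequency_of_controls`, how many cases each
#' control is still available to (low-frequency controls are matched
#' first, leaving widely shared controls for later cases).
#'
#' @param candidates A candidate data frame from [expand_candidates()]
#'   (rows from several subsets may be concatenated).
#' @return The same rows with the two counter columns added/refreshed.
#' @export
annotate_pool_stats <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$total_controls_per_case <- integer(0)
    candidates$frequency_of_controls <- integer(0)
    return(candidates)
  }
  candidates$total_controls_per_case <-
    as.integer(ave(seq_len(nrow(candidates)), candidates$case_id,
                   FUN = length))
  candidates$frequency_of_controls <-
    as.integer(ave(seq_len(nrow(candidates)), candidates$control_id,
                   FUN = length))
  candidates
}

#' Order candidate rows for optimal selection
#'
#' The fourth pre-processing step sorts the candidates so that taking
#' the first row per case yields its closest available control. Rows
#' are ordered by case, then by the configured difference variables
#' (by default the follow-up difference before the age difference,
#' because follow-up carries more weight), then by the control
#' frequency (rarely available controls first) and finally by control
#' id as a deterministic tie-break.
#'
#' @param candidates Annotated candidates from [annotate_pool_stats()].
#' @param priority Character vector of difference columns, in
#'   decreasing importance; any of `"follow_up_diff"`, `"age_diff"`,
#'   `"ci_diff"`, `"distance"`.
#' @return The same rows, permuted; the operation is idempotent.
#' @export
order_candidates <- function(candidates,
                             priority = c("follow_up_diff", "age_diff")) {
  missing_cols <- setdiff(priority, names(candidates))
  if (length(missing_cols) > 0)
    stop("unknown ordering variable(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(candidates) == 0) return(candidates)
  keys <- c(list(candidates$case_id),
            lapply(priority, function(v) candidates[[v]]),
            list(candidates$frequency_of_controls, candidates$control_id))
  candidates[do.call(order, keys), , drop = FALSE]
}

# Comorbidity index of many subjects at (possibly) different index
# years, in one pass. Returns a named integer vector along subject_ids.
ci_at_index <- function(diagnoses, subject_ids, index_years,
                        chronic_codes = NULL) {
  out <- setNames(integer(length(subject_ids)), subject_ids)
  if (is.null(diagnoses) || nrow(diagnoses) == 0) return(out)
  dg <- diagnoses
  if (!is.null(chronic_codes)) dg <- dg[dg$code %in% chronic_codes, ,
                                        drop = FALSE]
  dg <- dg[dg$subject_id %in% subject_ids, , drop = FALSE]
  if (nrow(dg) == 0) return(out)
  iy <- setNames(index_years, subject_ids)
  dg <- dg[dg$year <= iy[dg$subject_id], , drop = FALSE]
  if (nrow(dg) == 0) return(out)
  dg <- unique(dg[, c("subject_id", "code")])
  tab <- table(dg$subject_id)
  out[names(tab)] <- as.integer(tab)
  out
}
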