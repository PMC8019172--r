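make_frames <- function(seed = 1, n_cases = 6, n_ctl = 20, n_keys = 4) {
  set.seed(seed)
  keys <- sprintf("F|P%02d", seq_len(n_keys))
  cases <- data.frame(
    subject_id = sprintf("c%02d", seq_len(n_cases)),
    sex = "F",
    practice_id = sprintf("P%02d", sample(seq_len(n_keys), n_cases,
                                          replace = TRUE)),
    age = sample(40:80, n_cases, replace = TRUE),
    entry_year = sample(2000:2008, n_cases, replace = TRUE),
    ci = sample(0:3, n_cases, replace = TRUE),
    stringsAsFactors = FALSE)
  controls <- data.frame(
    subject_id = sprintf("k%02d", seq_len(n_ctl)),
    sex = "F",
    practice_id = sprintf("P%02d", sample(seq_len(n_keys + 2), n_ctl,
                                          replace = TRUE)),
    age = sample(40:80, n_ctl, replace = TRUE),
    entry_year = sample(2000:2008, n_ctl, replace = TRUE),
    ci = sample(0:3, n_ctl, replace = TRUE),
    stringsAsFactors = FALSE)
  list(cases = cases, controls = controls)
}

test_that("exact subsetting keeps one subset per case key and discards orphan controls", {
  cases <- data.frame(subject_id = c("c1", "c2", "c3"),
                      sex = c("F", "F", "M"),
                      practice_id = c("P1", "P2", "P1"),
                      stringsAsFactors = FALSE)
  controls <- data.frame(subject_id = sprintf("k%d", 1:10),
                         sex = rep(c("F", "M"), 5),
                         practice_id = rep(c("P1", "P2", "P3", "P4", "P1"),
                                           each = 2),
                         stringsAsFactors = FALSE)
  subs <- split_exact_subsets(cases, controls, c("sex", "practice_id"))
  expect_length(subs, 3)  # three distinct case keys
  for (s in subs) {
    expect_gte(nrow(s$cases), 1)
    if (nrow(s$controls) > 0) {
      expect_true(all(s$controls$sex == s$key[["sex"]]))
      expect_true(all(s$controls$practice_id == s$key[["practice_id"]]))
    }
  }
})

test_that("subsets with an empty control pool are retained and flagged", {
  cases <- data.frame(subject_id = "c1", sex = "F", practice_id = "P9",
                      stringsAsFactors = FALSE)
  controls <- data.frame(subject_id = "k1", sex = "M", practice_id = "P9",
                         stringsAsFactors = FALSE)
  subs <- split_exact_subsets(cases, controls, c("sex", "practice_id"))
  expect_length(subs, 1)
  expect_identical(nrow(subs[[1]]$controls), 0L)
  expect_true(isTRUE(attr(subs[[1]], "empty_pool")))
})

test_that("subset members are exactly the key-filtered input (no loss, no invention)", {
  f <- make_frames(seed = 42)
  subs <- split_exact_subsets(f$cases, f$controls, c("sex", "practice_id"))
  got_cases <- sort(unlist(lapply(subs, function(s) s$cases$subject_id)))
  expect_identical(got_cases, sort(f$cases$subject_id))
  case_keys <- unique(paste(f$cases$sex, f$cases$practice_id))
  keep <- paste(f$controls$sex, f$controls$practice_id) %in% case_keys
  got_ctl <- sort(unlist(lapply(subs, function(s) s$controls$subject_id)))
  expect_identical(got_ctl, sort(f$controls$subject_id[keep]))
})

test_that("missing exact-variable values are reported with the subject id", {
  cases <- data.frame(subject_id = c("c1", "c2"), sex = c("F", NA),
                      stringsAsFactors = FALSE)
  controls <- data.frame(subject_id = "k1", sex = "F",
                         stringsAsFactors = FALSE)
  expect_error(split_exact_subsets(cases, controls, "sex"), "c2")
})

test_that("candidate expansion enumerates eligible pairs exactly", {
  sub <- list(subset_key = "s",
              cases = data.frame(subject_id = c("c1", "c2", "c3"),
                                 age = c(50, 60, 70),
                                 entry_year = c(2005, 2004, 2006),
                                 ci = c(1, 0, 2),
                                 stringsAsFactors = FALSE),
              controls = data.frame(subject_id = sprintf("k%d", 1:5),
                                    age = c(49, 52, 61, 70, 73),
                                    entry_year = c(2005, 2003, 2004,
                                                   2006, 2007),
                                    ci = c(1, 2, 0, 3, 2),
                                    stringsAsFactors = FALSE))
  spec <- matching_spec(age_caliper = 2, follow_up = "trimmed",
                        ci = "varying", ci_threshold = 1)
  got <- expand_candidates(sub, spec)
  # brute-force enumeration with independent eligibility logic
  expected <- 0
  for (i in 1:3) for (j in 1:5) {
    ok <- abs(sub$cases$age[i] - sub$controls$age[j]) <= 2 &&
      sub$controls$entry_year[j] <= sub$cases$entry_year[i] &&
      abs(sub$cases$ci[i] - sub$controls$ci[j]) <= 1
    expected <- expected + ok
  }
  expect_identical(nrow(got), as.integer(expected))
  expect_true(all(got$age_diff <= 2))
  expect_true(all(got$follow_up_diff >= 0))
  expect_true(all(got$ci_diff <= 1))
  # distance is the weighted sum of the active varying differences
  expect_equal(got$distance,
               got$age_diff + got$follow_up_diff + got$ci_diff)
})

test_that("expansion with constraints off yields the full cross product", {
  f <- make_frames(seed = 5, n_keys = 1)
  sub <- list(subset_key = "s", cases = f$cases, controls = f$controls)
  spec <- matching_spec(age_caliper = Inf, follow_up = "off", ci = "none")
  got <- expand_candidates(sub, spec)
  expect_identical(nrow(got), nrow(f$cases) * nrow(f$controls))
  expect_identical(nrow(expand_candidates(
    list(subset_key = "s", cases = f$cases[0, ], controls = f$controls),
    spec)), 0L)
  expect_identical(nrow(expand_candidates(
    list(subset_key = "s", cases = f$cases, controls = f$controls[0, ]),
    spec)), 0L)
})

test_that("widening any caliper grows the candidate set monotonically", {
  f <- make_frames(seed = 9, n_keys = 1)
  sub <- list(subset_key = "s", cases = f$cases, controls = f$controls)
  key <- function(df) paste(df$case_id, df$control_id)
  prev <- character(0)
  for (cal in c(0, 1, 2, 5, 40)) {
    cur <- key(expand_candidates(
      sub, matching_spec(age_caliper = cal, follow_up = "trimmed",
                         ci = "none")))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  prev_ci <- character(0)
  for (thr in 0:3) {
    cur <- key(expand_candidates(
      sub, matching_spec(age_caliper = 5, follow_up = "trimmed",
                         ci = "varying", ci_threshold = thr)))
    expect_true(all(prev_ci %in% cur))
    prev_ci <- cur
  }
})

test_that("pool statistics equal independent group-by recounts", {
  f <- make_frames(seed = 13)
  subs <- split_exact_subsets(f$cases, f$controls, c("sex", "practice_id"))
  spec <- matching_spec(age_caliper = 10, follow_up = "off", ci = "none")
  cand <- do.call(rbind, lapply(subs, expand_candidates, spec = spec))
  ann <- annotate_pool_stats(cand)
  for (cid in unique(ann$case_id))
    expect_identical(unique(ann$total_controls_per_case[ann$case_id == cid]),
                     sum(ann$case_id == cid))
  for (kid in unique(ann$control_id))
    expect_identical(unique(ann$frequency_of_controls[ann$control_id == kid]),
                     sum(ann$control_id == kid))
  solo <- names(which(table(ann$control_id) == 1))
  if (length(solo) > 0)
    expect_true(all(ann$frequency_of_controls[ann$control_id %in% solo] == 1))
})

test_that("candidate ordering puts follow-up before age, then frequency, then id", {
  cand <- data.frame(
    subset_key = "s",
    case_id = c("c1", "c1", "c1", "c1"),
    control_id = c("k4", "k3", "k2", "k1"),
    age_diff = c(0, 5, 1, 1),
    follow_up_diff = c(1, 0, 0, 0),
    ci_diff = 0,
    distance = c(1, 5, 1, 1),
    stringsAsFactors = FALSE)
  ann <- annotate_pool_stats(cand)
  got <- order_candidates(ann)
  # zero follow-up difference first; among those smaller age; id tie-break
  expect_identical(got$control_id, c("k1", "k2", "k3", "k4"))
  # swapped priority: age difference dominates, so k4 (age 0, follow-up
  # 1) now sorts first; the age-1 pair breaks on control id
  got2 <- order_candidates(ann, priority = c("age_diff", "follow_up_diff"))
  expect_identical(got2$control_id, c("k4", "k1", "k2", "k3"))
  expect_error(order_candidates(ann, priority = "no_such"), "unknown")
})

test_that("ordering is a permutation, idempotent, and matches a comparator oracle", {
  f <- make_frames(seed = 21)
  subs <- split_exact_subsets(f$cases, f$controls, c("sex", "practice_id"))
  spec <- matching_spec(age_caliper = 20, follow_up = "trimmed", ci = "none")
  cand <- annotate_pool_stats(
    do.call(rbind, lapply(subs, expand_candidates, spec = spec)))
  got <- order_candidates(cand)
  expect_identical(sort(paste(got$case_id, got$control_id)),
                   sort(paste(cand$case_id, cand$control_id)))
  expect_identical(order_candidates(got), got)
  # independent comparator: base-R order on the same keys
  ref <- cand[order(cand$case_id, cand$follow_up_diff, cand$age_diff,
                    cand$frequency_of_controls, cand$control_id), ]
  expect_identical(got$control_id, ref$control_id)
  expect_identical(got$case_id, ref$case_id)
})
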