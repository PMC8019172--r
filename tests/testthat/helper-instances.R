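# Builders for small abstract matching instances and CLR data, plus
# naive reference implementations used as independent oracles.

# A candidate table over abstract ids: every feasible pair carries an
# age_diff drawn from 0:6 and distance == age_diff (unit weight), so
# the lexicographic ordering priority "age_diff" coincides with the
# distance and matcher totals are comparable with min-cost oracles.
random_instance <- function(seed, disjoint = FALSE,
                            max_cases = 8, max_controls = 12) {
  set.seed(seed)
  n_cases <- sample(2:max_cases, 1)
  n_ctl <- sample(n_cases:max_controls, 1)
  case_ids <- sprintf("c%02d", seq_len(n_cases))
  ctl_ids <- sprintf("k%02d", seq_len(n_ctl))
  if (disjoint) {
    owner <- sort(rep_len(seq_len(n_cases), n_ctl))
    rows <- data.frame(case_id = case_ids[owner], control_id = ctl_ids,
                       stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(case_id = case_ids, control_id = ctl_ids,
                     stringsAsFactors = FALSE)
    rows <- g[runif(nrow(g)) < 0.5, , drop = FALSE]
  }
  if (nrow(rows) == 0) rows <- data.frame(case_id = case_ids[1],
                                          control_id = ctl_ids[1],
                                          stringsAsFactors = FALSE)
  rows$subset_key <- "s"
  rows$age_diff <- sample(0:6, nrow(rows), replace = TRUE)
  rows$follow_up_diff <- 0
  rows$ci_diff <- 0
  rows$distance <- rows$age_diff
  rownames(rows) <- NULL
  rows[, c("subset_key", "case_id", "control_id", "age_diff",
           "follow_up_diff", "ci_diff", "distance")]
}

instance_spec <- function(n_controls = 1L, replacement = FALSE) {
  matching_spec(n_controls = n_controls, replacement = replacement,
                ordering_priority = "age_diff")
}

# Matched-set data for conditional logistic regression: n_sets sets of
# 1 case + m controls with a binary exposure.
random_clr_data <- function(seed, n_sets = 15, p_exposed = 0.5) {
  set.seed(seed)
  rows <- lapply(seq_len(n_sets), function(s) {
    m <- sample(1:4, 1)
    data.frame(set_id = s,
               is_case = c(TRUE, rep(FALSE, m)),
               exposed = runif(m + 1) < p_exposed)
  })
  do.call(rbind, rows)
}

# Naive conditional log-likelihood: explicit loops, no shared code with
# the package implementation.
naive_cloglik <- function(beta, d) {
  ll <- 0
  for (s in unique(d$set_id)) {
    rows <- d[d$set_id == s, ]
    num <- exp(beta * rows$exposed[rows$is_case])
    den <- sum(exp(beta * rows$exposed))
    ll <- ll + log(num / den)
  }
  ll
}

# One-dimensional likelihood maximisation oracle.
grid_search_beta <- function(d, lower = -8, upper = 8) {
  stats::optimize(function(b) naive_cloglik(b, d),
                  interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# A miniature registry built directly from covariate tables, with
# everything in one exact subset unless stated otherwise.
mini_registry <- function(case_age, ctrl_age,
                          case_entry = rep(2005L, length(case_age)),
                          ctrl_entry = rep(2005L, length(ctrl_age)),
                          index_year = 2010L) {
  n1 <- length(case_age); n0 <- length(ctrl_age)
  id <- c(sprintf("c%02d", seq_len(n1)), sprintf("k%02d", seq_len(n0)))
  subjects <- data.frame(
    subject_id = id,
    is_case = rep(c(TRUE, FALSE), c(n1, n0)),
    sex = "F", practice_id = "P01",
    birth_year = index_year - as.integer(c(case_age, ctrl_age)),
    entry_year = as.integer(c(case_entry, ctrl_entry)),
    index_year = c(rep(index_year, n1), rep(NA_integer_, n0)),
    exposed = FALSE, stringsAsFactors = FALSE)
  contacts <- data.frame(subject_id = id, year = index_year,
                         stringsAsFactors = FALSE)
  empty <- data.frame(subject_id = character(0), code = character(0),
                      year = integer(0), stringsAsFactors = FALSE)
  casematch:::new_cc_registry(subjects, contacts, empty, empty)
}
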