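#' Generate a synthetic primary-care registry with known ground truth
#'
#' Emulates the structure of a practice-based morbidity registry:
#' patients belong to practices, enter the registry in some year,
#' consult their GP in a random subset of subsequent years, accumulate
#' distinct chronic diagnosis codes over time, and may become incident
#' cases during the 2010-2015 ascertainment window. Exposure (an
#' antibiotic prescription on or before the index year) is assigned
#' from the logistic model
#' \deqn{\mathrm{logit}\, P(\mathrm{exposed}) = \alpha +
#'   \log(\mathrm{OR}) \cdot \mathrm{case} + \gamma \cdot \mathrm{CI},}
#' so the conditional odds ratio of exposure given case status within a
#' comorbidity-index stratum is exactly `true_or`. Case status itself
#' depends on the comorbidity index through `ci_case_effect`, which
#' makes the CI a genuine confounder when both effects are non-zero:
#' ignoring it biases the crude exposure OR away from `true_or`, and
#' balancing it during matching removes that bias.
#'
#' Chronic codes onset only during 2000-2009, the decade before the
#' ascertainment window opens (conditions present before registry entry
#' are back-registered with their onset year), so a subject's
#' comorbidity index does not depend on its entry year and is the
#' same whichever index year in 2010-2015 it is evaluated at; exposed
#' subjects carry a prescription in their entry year, so the
#' event-derived exposure agrees with the model assignment for every
#' admissible index year. Both choices keep the generating odds ratio
#' exactly interpretable in the matched analysis.
#'
#' @param n_patients Number of subjects.
#' @param n_practices Number of practices.
#' @param year_range Length-2 integer vector, the registry observation
#'   window (default 2000-2015; the case window is 2010 to its end).
#' @param contact_rate Per-year probability of at least one GP contact.
#' @param chronic_incidence_rate Per-year probability of a new chronic
#'   diagnosis code onset (over 2000-2009).
#' @param case_rate Target marginal probability of being a case among
#'   eligible subjects.
#' @param exposure_baseline_prob Baseline exposure probability of an
#'   unexposed-profile subject (control with CI at the cohort mean).
#' @param true_or True conditional odds ratio of exposure for cases
#'   versus controls, given the comorbidity index.
#' @param ci_exposure_effect Log-odds of exposure per comorbidity-index
#'   unit (\eqn{\gamma}).
#' @param ci_case_effect Log-odds of being a case per comorbidity-index
#'   unit.
#' @param seed Integer seed; the same seed reproduces the registry
#'   bit for bit.
#' @return An object of class `cc_registry`: a list of data frames
#'   `subjects` (`subject_id`, `is_case`, `sex`, `practice_id`,
#'   `birth_year`, `entry_year`, `index_year`, `exposed`), `contacts`
#'   (`subject_id`, `year`), `diagnoses` (`subject_id`, `code`,
#'   `year`) and `exposures` (`subject_id`, `code`, `year`).
#' @examples
#' reg <- generate_registry(n_patients = 200, seed = 1)
#' reg
#' @export
generate_registry <- function(n_patients = 2000,
                              n_practices = 5,
                              year_range = c(2000, 2015),
                              contact_rate = 0.7,
                              chronic_incidence_rate = 0.15,
                              case_rate = 0.05,
                              exposure_baseline_prob = 0.2,
                              true_or = 1.5,
                              ci_exposure_effect = 0.5,
                              ci_case_effect = 0.4,
                              seed = 1L) {
  probs <- c(contact_rate, chronic_incidence_rate, case_rate,
             exposure_baseline_prob)
  if (any(probs < 0 | probs > 1))
    stop("rates and probabilities must lie in [0, 1]")
  if (!is.numeric(true_or) || true_or <= 0)
    stop("'true_or' must be a positive number")
  y0 <- year_range[1]; y1 <- year_range[2]
  if (y1 < 2010) stop("'year_range' must reach at least 2010")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  id <- sprintf("S%06d", seq_len(n_patients))
  sex <- sample(c("F", "M"), n_patients, replace = TRUE)
  practice <- sprintf("P%02d", sample.int(n_practices, n_patients,
                                          replace = TRUE))
  birth_year <- sample(1930:1990, n_patients, replace = TRUE)
  entry_year <- sample(y0:min(2012, y1 - 1), n_patients, replace = TRUE)

  # yearly GP contacts from entry to the end of the window
  n_years <- y1 - entry_year + 1L
  ctc_id <- rep(id, n_years)
  ctc_year <- unlist(lapply(seq_len(n_patients),
                            function(i) entry_year[i]:y1), use.names = FALSE)
  has_contact <- runif(length(ctc_id)) < contact_rate
  contacts <- data.frame(subject_id = ctc_id[has_contact],
                         year = ctc_year[has_contact],
                         stringsAsFactors = FALSE)

  # chronic diagnoses onset over the fixed 2000-2009 window, independent
  # of the entry year: conditions present before registration are
  # back-registered with their onset year, as GP registries do
  dg_last <- 2009L
  diag_rows <- vector("list", n_patients)
  code_pool <- sprintf("CHR%02d", 1:40)
  for (i in seq_len(n_patients)) {
    yrs <- y0:dg_last
    hit <- yrs[runif(length(yrs)) < chronic_incidence_rate]
    if (length(hit) > 0)
      diag_rows[[i]] <- data.frame(
        subject_id = id[i],
        code = sample(code_pool, length(hit)),
        year = hit, stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, c(list(data.frame(
    subject_id = character(0), code = character(0), year = integer(0),
    stringsAsFactors = FALSE)), diag_rows))

  # candidate index year (diagnosis year if the subject becomes a case)
  lo <- pmax(entry_year + 1L, 2010L)
  cand_index <- lo + floor(runif(n_patients) * (y1 - lo + 1))
  eligible <- lo <= y1   # at least one year of follow-up by the window
  ci <- ci_pairs(diagnoses, id, cand_index)

  # case status: logit P(case) = a + ci_case_effect * CI, centred so the
  # marginal rate stays near case_rate
  a_case <- qlogis(case_rate) - ci_case_effect * mean(ci[eligible])
  p_case <- plogis(a_case + ci_case_effect * ci)
  is_case <- eligible & (runif(n_patients) < p_case)
  index_year <- as.integer(ifelse(is_case, cand_index, NA_integer_))

  # exposure: conditional OR given CI is exactly true_or
  a_exp <- qlogis(exposure_baseline_prob) -
    ci_exposure_effect * mean(ci[eligible])
  p_exp <- plogis(a_exp + log(true_or) * is_case + ci_exposure_effect * ci)
  exposed <- runif(n_patients) < p_exp

  # exposed subjects get a prescription at entry (<= any admissible
  # index year), plus possibly repeats later
  exp_rows <- which(exposed)
  n_rep <- 1L + rbinom(length(exp_rows), 2, 0.3)
  exposures <- data.frame(
    subject_id = rep(id[exp_rows], n_rep),
    code = "J01",
    year = unlist(lapply(seq_along(exp_rows), function(k) {
      i <- exp_rows[k]
      c(entry_year[i],
        if (n_rep[k] > 1)
          sample(entry_year[i]:y1, n_rep[k] - 1L, replace = TRUE))
    }), use.names = FALSE),
    stringsAsFactors = FALSE)

  # cases always have a GP contact in their index year
  case_ct <- data.frame(subject_id = id[is_case],
                        year = index_year[is_case],
                        stringsAsFactors = FALSE)
  contacts <- unique(rbind(contacts, case_ct))
  contacts <- contacts[order(contacts$subject_id, contacts$year), ]
  rownames(contacts) <- NULL

  subjects <- data.frame(
    subject_id = id, is_case = is_case, sex = sex,
    practice_id = practice, birth_year = birth_year,
    entry_year = entry_year, index_year = as.integer(index_year),
    exposed = exposed, stringsAsFactors = FALSE)

  new_cc_registry(subjects, contacts, diagnoses, exposures)
}

new_cc_registry <- function(subjects, contacts, diagnoses, exposures) {
  structure(list(subjects = subjects, contacts = contacts,
                 diagnoses = diagnoses, exposures = exposures),
            class = "cc_registry")
}

#' @export
print.cc_registry <- function(x, ...) {
  cat(sprintf(
    "Registry: %d subjects (%d cases), %d contacts, %d diagnoses, %d prescriptions\n",
    nrow(x$subjects), sum(x$subjects$is_case), nrow(x$contacts),
    nrow(x$diagnoses), nrow(x$exposures)))
  invisible(x)
}

#' A small worked example: 4 cases and 9 controls
#'
#' A deterministic miniature registry for demonstrating and testing the
#' assignment algorithm. All 13 subjects share sex and practice and all
#' controls consulted the GP in 2010, the index year of all four cases,
#' so everyone sits in a single exact subset and matching is driven by
#' the age difference alone. The fixture is built so that both
#' algorithm branches are exercised under an age caliper of 2: two
#' cases contest the same nearest control, and one case has a single
#' eligible control (which the algorithm guarantees it receives).
#'
#' @return A `cc_registry` with 4 cases and 9 controls.
#' @examples
#' cc_match(toy_fixture(), matching_spec(n_controls = 1))
#' @export
toy_fixture <- function() {
  # ages at the 2010 index: cases 50, 50, 60, 80
  case_age <- c(c1 = 50, c2 = 50, c3 = 60, c4 = 80)
  ctrl_age <- c(k1 = 50, k2 = 51, k3 = 49, k4 = 60, k5 = 62,
                k6 = 81, k7 = 48, k8 = 52, k9 = 58)
  id <- c(names(case_age), names(ctrl_age))
  n <- length(id)
  subjects <- data.frame(
    subject_id = id,
    is_case = c(rep(TRUE, 4), rep(FALSE, 9)),
    sex = "F",
    practice_id = "P01",
    birth_year = 2010L - as.integer(c(case_age, ctrl_age)),
    entry_year = 2005L,
    index_year = c(rep(2010L, 4), rep(NA_integer_, 9)),
    exposed = rep(c(TRUE, FALSE), length.out = n),
    stringsAsFactors = FALSE)
  contacts <- data.frame(subject_id = rep(id, each = 2),
                         year = rep(c(2005L, 2010L), n),
                         stringsAsFactors = FALSE)
  diagnoses <- data.frame(subject_id = character(0), code = character(0),
                          year = integer(0), stringsAsFactors = FALSE)
  exposures <- data.frame(
    subject_id = id[subjects$exposed], code = "J01", year = 2006L,
    stringsAsFactors = FALSE)
  new_cc_registry(subjects, contacts, diagnoses, exposures)
}

# Save/restore the global RNG state so generators are side-effect free.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
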