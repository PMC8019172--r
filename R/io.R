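#' Read a registry from delimited text files
#'
#' Loads the four standard tables (subjects, contacts, diagnoses,
#' prescriptions) from CSV files with header rows. Column names can be
#' remapped through `column_map`, a named list (or a path to a JSON
#' file holding one) of the form
#' `list(subjects = c(subject_id = "patient"), ...)` mapping the
#' canonical name to the name used in the file. Rows with an
#' unparseable year are rejected with a message; duplicated subject
#' ids are a hard error.
#'
#' @param subjects_file Path to the subjects CSV (required columns
#'   after mapping: `subject_id`, `is_case`, `sex`, `practice_id`,
#'   `birth_year`, `entry_year`, `index_year`).
#' @param contacts_file,diagnoses_file,exposures_file Paths to the
#'   long-format event CSVs (`subject_id`, `year` and, for diagnoses
#'   and prescriptions, `code`); may be `NULL` for empty tables.
#' @param column_map Optional column remapping (named list or JSON
#'   file path).
#' @return A `cc_registry` object.
#' @seealso [write_registry()]
#' @export
read_registry <- function(subjects_file, contacts_file = NULL,
                          diagnoses_file = NULL, exposures_file = NULL,
                          column_map = NULL) {
  if (is.character(column_map))
    column_map <- jsonlite::read_json(column_map, simplifyVector = TRUE)
  remap <- function(df, table) {
    mp <- column_map[[table]]
    if (!is.null(mp))
      for (canon in names(mp)) {
        if (!mp[[canon]] %in% names(df))
          stop("mapped column '", mp[[canon]], "' not found in ", table)
        names(df)[names(df) == mp[[canon]]] <- canon
      }
    df
  }
  year_clean <- function(df, cols, table, required = TRUE) {
    for (cl in cols) {
      yr <- suppressWarnings(as.integer(df[[cl]]))
      bad <- is.na(yr) & !is.na(df[[cl]]) & df[[cl]] != ""
      if (required) bad <- bad | is.na(df[[cl]]) | df[[cl]] == ""
      if (any(bad)) {
        message(sum(bad), " row(s) of ", table,
                " rejected: unparseable '", cl, "'")
        df <- df[!bad, , drop = FALSE]
        yr <- yr[!bad]
      }
      df[[cl]] <- yr
    }
    df
  }
  sub <- remap(read.csv(subjects_file, stringsAsFactors = FALSE),
               "subjects")
  need <- c("subject_id", "is_case", "sex", "practice_id", "birth_year",
            "entry_year", "index_year")
  miss <- setdiff(need, names(sub))
  if (length(miss) > 0)
    stop("subjects file lacks column(s): ", paste(miss, collapse = ", "))
  sub <- year_clean(sub, c("birth_year", "entry_year"), "subjects")
  sub <- year_clean(sub, "index_year", "subjects", required = FALSE)
  if (anyDuplicated(sub$subject_id))
    stop("duplicated subject_id in subjects file: ",
         paste(unique(sub$subject_id[duplicated(sub$subject_id)]),
               collapse = ", "))
  sub$is_case <- as.logical(sub$is_case)
  long_tab <- function(path, table, with_code) {
    cols <- if (with_code)
      data.frame(subject_id = character(0), code = character(0),
                 year = integer(0), stringsAsFactors = FALSE)
    else data.frame(subject_id = character(0), year = integer(0),
                    stringsAsFactors = FALSE)
    if (is.null(path)) return(cols)
    df <- remap(read.csv(path, stringsAsFactors = FALSE), table)
    df <- year_clean(df, "year", table)
    df[, names(cols), drop = FALSE]
  }
  new_cc_registry(sub,
                  long_tab(contacts_file, "contacts", FALSE),
                  long_tab(diagnoses_file, "diagnoses", TRUE),
                  long_tab(exposures_file, "exposures", TRUE))
}

#' Write a registry to delimited text files
#'
#' Writes the four registry tables as plain CSV (`subjects.csv`,
#' `contacts.csv`, `diagnoses.csv`, `exposures.csv`) into `dir`.
#' Reading them back with [read_registry()] reproduces the registry.
#'
#' @param registry A `cc_registry`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("subjects", "contacts", "diagnoses", "exposures"))
    write.csv(registry[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' Write a matched cohort to CSV plus a JSON summary
#'
#' The long-format CSV holds one row per matched (case, control, round)
#' slot; the sidecar JSON (`<path>.summary.json`) carries provenance
#' (package version, seed if supplied, configuration hash) and the
#' cohort-level counts, so the CSV itself stays pipeable.
#'
#' @param cohort A `cc_cohort`.
#' @param path Output CSV path.
#' @param seed Optional integer recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_matches <- function(cohort, path, seed = NULL) {
  write.csv(cohort$matched, path, row.names = FALSE)
  spec_json <- jsonlite::toJSON(unclass(cohort$spec), auto_unbox = TRUE,
                                null = "null")
  summary <- list(
    provenance = list(
      package = "casematch",
      version = as.character(utils::packageVersion("casematch")),
      seed = seed,
      config_hash = sprintf("%08x", config_hash(spec_json))),
    n_cases = cohort$n_cases,
    n_cases_matched = cohort$n_cases_matched,
    n_unique_controls = cohort$n_unique_controls,
    n_slots = nrow(cohort$matched),
    total_distance = cohort$total_distance,
    controls_per_case = as.list(controls_per_case(cohort)),
    unmatched_case_ids = cohort$unmatched_case_ids)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# small deterministic string hash (polynomial mod a Mersenne prime)
config_hash <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 31 + b) %% 2147483647
  h
}
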