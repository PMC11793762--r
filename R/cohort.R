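#' Construct a longitudinal cohort
#'
#' Bundles a covariate schema, a long-format measurement table (one row per
#' patient-day) and a per-patient event table into a validated
#' `longitudinal_cohort` object. Days are integers anchored at each
#' patient's own day 0 (first assessment); calendar dates never enter the
#' analysis frame.
#'
#' @param measurements Tibble with columns `patient_id`, `day`, plus one
#'   column per schema covariate (numeric; `NA` marks a missing
#'   measurement).
#' @param patients Tibble with columns `patient_id`, `outcome_day`,
#'   `delivery_day`, `end_of_followup_day` (`NA` = event never observed;
#'   `end_of_followup_day` is required).
#' @param schema A [cohort_schema()]; defaults to [default_schema()].
#' @param validate Stop on the first invariant violation? If `FALSE` the
#'   object is returned unchecked (use [validate_cohort()] to inspect).
#' @return A `longitudinal_cohort`: list with elements `schema`,
#'   `measurements`, `patients`.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()]
#' @export
longitudinal_cohort <- function(measurements, patients,
                                schema = default_schema(),
                                validate = TRUE) {
  measurements <- tibble::as_tibble(measurements)
  patients <- tibble::as_tibble(patients)

  need <- c("patient_id", "day")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) abort(paste("measurements lack column(s):",
                                paste(miss, collapse = ", ")))
  needp <- c("patient_id", "outcome_day", "delivery_day", "end_of_followup_day")
  miss <- setdiff(needp, names(patients))
  if (length(miss)) abort(paste("patients lack column(s):",
                                paste(miss, collapse = ", ")))

  extra <- setdiff(names(measurements), c(need, schema_covariates(schema)))
  if (length(extra)) {
    abort(paste0("covariate column(s) not in schema: ",
                 paste(extra, collapse = ", ")))
  }
  # columns in schema order; absent covariates are an error only when used
  keep <- intersect(schema_covariates(schema), names(measurements))
  measurements <- measurements[, c(need, keep)]
  measurements$patient_id <- as.character(measurements$patient_id)
  measurements$day <- as.integer(measurements$day)
  patients$patient_id <- as.character(patients$patient_id)
  for (col in setdiff(needp, "patient_id")) {
    patients[[col]] <- as.integer(patients[[col]])
  }
  measurements <- dplyr::arrange(measurements, .data$patient_id, .data$day)
  patients <- dplyr::arrange(patients, .data$patient_id)

  out <- structure(
    list(schema = schema, measurements = measurements, patients = patients),
    class = "longitudinal_cohort"
  )
  if (validate) {
    v <- validate_cohort(out)
    if (nrow(v)) {
      abort(paste0("invalid cohort: ", v$rule[1], " (patient ", v$patient_id[1],
                   if (!is.na(v$day[1])) paste0(", day ", v$day[1]), ")"))
    }
  }
  out
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("<longitudinal_cohort>\n")
  cat("  patients:     ", nrow(x$patients), "\n")
  cat("  measurements: ", nrow(x$measurements), " patient-days\n", sep = "")
  cat("  covariates:   ", paste(schema_covariates(x$schema), collapse = ", "),
      "\n", sep = "")
  cat("  outcomes:     ", sum(!is.na(x$patients$outcome_day)), "\n")
  invisible(x)
}

#' Validate a longitudinal cohort
#'
#' Checks every structural invariant of the cohort data model and returns
#' the violations as data rather than raising: unique `(patient_id, day)`
#' pairs, day bounds, measurements never recorded after the composite
#' outcome day (follow-up measurements are not used once the outcome has
#' occurred), event days inside `[0, end_of_followup_day]`, and referential
#' integrity between the two tables.
#'
#' @param cohort A `longitudinal_cohort` (checked or not).
#' @return A tibble with columns `patient_id`, `day` (NA when the rule is
#'   patient-level) and `rule`; zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  m <- cohort$measurements
  p <- cohort$patients
  out <- list()
  viol <- function(pid, day, rule) {
    tibble::tibble(patient_id = as.character(pid),
                   day = as.integer(day), rule = rule)
  }

  dup <- m |>
    dplyr::count(.data$patient_id, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    out <- c(out, list(viol(dup$patient_id, dup$day,
                            "duplicate (patient_id, day) measurement row")))
  }
  neg <- dplyr::filter(m, .data$day < 0)
  if (nrow(neg)) {
    out <- c(out, list(viol(neg$patient_id, neg$day, "day must be >= 0")))
  }
  dupp <- p |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dupp)) {
    out <- c(out, list(viol(dupp$patient_id, NA, "duplicate patient_id")))
  }
  orphan <- dplyr::anti_join(m, p, by = "patient_id")
  if (nrow(orphan)) {
    out <- c(out, list(viol(unique(orphan$patient_id), NA,
                            "measurement for patient absent from patients table")))
  }
  bad_eof <- dplyr::filter(p, is.na(.data$end_of_followup_day) |
                                .data$end_of_followup_day < 0)
  if (nrow(bad_eof)) {
    out <- c(out, list(viol(bad_eof$patient_id, NA,
                            "end_of_followup_day required and >= 0")))
  }

  j <- dplyr::inner_join(m, p, by = "patient_id")
  post_out <- dplyr::filter(j, !is.na(.data$outcome_day) &
                                 .data$day > .data$outcome_day)
  if (nrow(post_out)) {
    out <- c(out, list(viol(post_out$patient_id, post_out$day,
                            "measurement after outcome_day")))
  }
  post_eof <- dplyr::filter(j, !is.na(.data$end_of_followup_day) &
                                 .data$day > .data$end_of_followup_day)
  if (nrow(post_eof)) {
    out <- c(out, list(viol(post_eof$patient_id, post_eof$day,
                            "measurement after end_of_followup_day")))
  }
  for (col in c("outcome_day", "delivery_day")) {
    bad <- dplyr::filter(p, !is.na(.data[[col]]) &
                              (.data[[col]] < 0 |
                               .data[[col]] > .data$end_of_followup_day))
    if (nrow(bad)) {
      out <- c(out, list(viol(bad$patient_id, bad[[col]],
                              paste(col, "outside [0, end_of_followup_day]"))))
    }
  }

  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(patient_id = character(), day = integer(), rule = character())
}

#' Read a longitudinal cohort from two CSV files
#'
#' Reads the long-format measurement table (`patient_id,day,<covariate...>`)
#' and the per-patient event table
#' (`patient_id,outcome_day,delivery_day,end_of_followup_day`) and returns a
#' validated cohort. Empty cells (and literal `NA`/`NaN`) become the missing
#' marker `NA`, never zero. Unknown covariate columns are rejected against
#' the schema.
#'
#' @param measurements_path,patients_path Paths to the two CSVs.
#' @inheritParams longitudinal_cohort
#' @return A `longitudinal_cohort`.
#' @export
read_cohort <- function(measurements_path, patients_path,
                        schema = default_schema()) {
  for (pth in c(measurements_path, patients_path)) {
    if (!file.exists(pth)) abort(paste("file not found:", pth))
  }
  m <- readr::read_csv(measurements_path, show_col_types = FALSE,
                       na = c("", "NA", "NaN"),
                       col_types = readr::cols(patient_id = readr::col_character(),
                                               .default = readr::col_double()))
  p <- readr::read_csv(patients_path, show_col_types = FALSE,
                       na = c("", "NA", "NaN"),
                       col_types = readr::cols(patient_id = readr::col_character(),
                                               .default = readr::col_double()))
  longitudinal_cohort(m, p, schema = schema)
}

#' Write a longitudinal cohort to two CSV files
#'
#' Inverse of [read_cohort()]: writes `measurements.csv` and `patients.csv`
#' under `out_dir` such that reading them back reproduces the in-memory
#' cohort exactly. Missing values are written as empty cells (never the
#' string "NA"), fixing the CSV dialect so round-trips are deterministic.
#'
#' @param cohort A valid `longitudinal_cohort`.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(out_dir, "measurements.csv")
  pp <- file.path(out_dir, "patients.csv")
  readr::write_csv(cohort$measurements, mp, na = "")
  readr::write_csv(cohort$patients, pp, na = "")
  invisible(c(measurements = mp, patients = pp))
}
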