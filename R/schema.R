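#' Declare a covariate schema for a longitudinal cohort
#'
#' A schema names every covariate a cohort may carry, its measurement unit,
#' its type (continuous or binary), and its missingness class. The
#' missingness class decides how downstream gap-filling treats the variable:
#' `"mar"` variables are handled by chained-equations multiple imputation
#' ([multiple_impute()]), `"mnar"` variables (labs a clinician may skip when
#' the last value looked normal, such as platelet counts) by
#' last-observation-carried-forward ([locf_fill()]), and `"none"` variables
#' are expected to be always observed.
#'
#' @param covariate Character vector of covariate names.
#' @param unit Character vector of units (same length, recycled if length 1).
#' @param type `"continuous"` or `"binary"` per covariate.
#' @param missing_class `"mar"`, `"mnar"` or `"none"` per covariate.
#' @return A tibble with class `cohort_schema`.
#' @examples
#' cohort_schema(
#'   covariate = c("platelets", "ast"),
#'   unit = c("1e9/L", "U/L"),
#'   type = "continuous",
#'   missing_class = c("mnar", "mar")
#' )
#' @export
cohort_schema <- function(covariate, unit, type = "continuous",
                          missing_class = "mar") {
  out <- tibble::tibble(
    covariate = as.character(covariate),
    unit = rep_len(as.character(unit), length(covariate)),
    type = rep_len(as.character(type), length(covariate)),
    missing_class = rep_len(as.character(missing_class), length(covariate))
  )
  if (anyDuplicated(out$covariate)) {
    abort("schema covariate names must be unique")
  }
  bad <- setdiff(out$type, c("continuous", "binary"))
  if (length(bad)) abort(paste0("unknown covariate type: ", bad[1]))
  bad <- setdiff(out$missing_class, c("mar", "mnar", "none"))
  if (length(bad)) abort(paste0("unknown missing_class: ", bad[1]))
  class(out) <- c("cohort_schema", class(out))
  out
}

#' Default preeclampsia monitoring schema
#'
#' The symptom and laboratory variables routinely collected at and after
#' admission for preeclampsia, with their conventional units: gestational age
#' (weeks), highest systolic blood pressure (mmHg), oxygen saturation (%),
#' platelet count (x10^9/L), mean platelet volume (fL), serum creatinine
#' (umol/L), aspartate transaminase (U/L) and the chest-pain/dyspnoea symptom
#' flag (0/1). Platelet-type labs default to the MNAR class (clinicians may
#' skip re-measurement when the last value was normal); gestational age and
#' systolic blood pressure are treated as always observed so that the MAR
#' missingness mechanism conditions only on observed data.
#'
#' @return A `cohort_schema` tibble with 8 rows.
#' @export
default_schema <- function() {
  cohort_schema(
    covariate = c(
      "gestational_age", "sbp_max", "spo2", "platelets",
      "mpv", "creatinine", "ast", "chest_pain"
    ),
    unit = c(
      "weeks", "mmHg", "%", "1e9/L",
      "fL", "umol/L", "U/L", "0/1"
    ),
    type = c(
      "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous", "continuous", "binary"
    ),
    missing_class = c(
      "none", "none", "mar", "mnar",
      "mnar", "mar", "mar", "mar"
    )
  )
}

schema_covariates <- function(schema) schema$covariate

schema_class <- function(schema, class) {
  schema$covariate[schema$missing_class == class]
}
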