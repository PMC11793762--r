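#' Build the risk set for one evaluation day
#'
#' A patient is evaluable (a risk-set member) on day `d` iff their composite
#' outcome has not occurred before `d` (a patient whose outcome occurs ON
#' day `d` remains in that day's set, so the day-`d` prediction is credited
#' with flagging them), follow-up has not ended before `d`, and at least one
#' measurement exists at a day `<= d`. Effective covariates are the latest
#' available values — per-covariate carry-forward of the most recent
#' non-missing observation at day `<= d`. The 48-h outcome label is 1 iff
#' the outcome day falls in `{d, d + 1}` (the two-calendar-day
#' discretization of "within 48 h").
#'
#' @param cohort A `longitudinal_cohort`.
#' @param day Evaluation day (>= 0).
#' @return A tibble of class `daily_risk_set`: `patient_id`, `day`, `label`,
#'   plus one column per covariate (effective carried-forward value; `NA`
#'   when never observed up to `day`).
#' @export
build_daily_risk_set <- function(cohort, day) {
  stopifnot(length(day) == 1, day >= 0)
  day <- as.integer(day)
  p <- cohort$patients
  member_ids <- p$patient_id[
    (is.na(p$outcome_day) | p$outcome_day >= day) &
      p$end_of_followup_day >= day
  ]
  covs <- intersect(schema_covariates(cohort$schema),
                    names(cohort$measurements))
  eff <- cohort$measurements |>
    dplyr::filter(.data$patient_id %in% member_ids, .data$day <= !!day) |>
    dplyr::arrange(.data$patient_id, .data$day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(covs), latest_value),
      .groups = "drop"
    )
  out <- eff |>
    dplyr::inner_join(p[, c("patient_id", "outcome_day")], by = "patient_id") |>
    dplyr::mutate(
      day = !!day,
      label = as.integer(!is.na(.data$outcome_day) &
                           .data$outcome_day %in% c(!!day, !!day + 1L))
    ) |>
    dplyr::select("patient_id", "day", "label", dplyr::all_of(covs))
  class(out) <- c("daily_risk_set", class(out))
  out
}

latest_value <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs)) x[max(obs)] else NA_real_
}

#' Run consecutive (serial) prediction over the evaluation horizon
#'
#' The core evaluation loop: for each day 0 .. `horizon - 1`, build the
#' daily risk set with carried-forward latest measurements, score every
#' member with the risk model, assign risk groups, and attach 48-h outcome
#' labels. Members for whom a required covariate is still unresolvable
#' after carry-forward (and imputation, if any) are dropped from that day's
#' set with a logged count — never silently scored. Given an
#' [multiple_impute()] result, the loop runs once per completed dataset;
#' rows carry the dataset index `.imp` and downstream metrics are pooled
#' per dataset ([pool_estimates()]).
#'
#' @param cohort A `longitudinal_cohort` or `imputation_set` (a
#'   `synthetic_cohort` is accepted and unwrapped).
#' @param model A [logistic_model_spec()] or any function
#'   `f(covariate_tibble) -> probabilities` (pluggable black-box
#'   predictor).
#' @param scheme A [stratification_scheme()].
#' @param horizon Number of evaluation days (days `0 .. horizon - 1`).
#' @return A `serial_prediction`: list with `predictions` (tibble `.imp`,
#'   `day`, `patient_id`, `probability`, `group`, `label`), `dropped`
#'   (tibble `.imp`, `day`, `n_dropped`), `scheme`, `horizon`, `m`.
#' @export
run_consecutive_prediction <- function(cohort, model,
                                       scheme = stratification_scheme(),
                                       horizon = 14) {
  if (horizon < 1) abort("horizon must be >= 1")
  horizon <- as.integer(horizon)
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  cohorts <- if (inherits(cohort, "imputation_set")) cohort$datasets
             else list(cohort)

  res <- purrr::imap(cohorts, function(ch, k) {
    per_day <- purrr::map(seq_len(horizon) - 1L, function(d) {
      rs <- build_daily_risk_set(ch, d)
      score_risk_set(rs, model, scheme, imp = k, day = d)
    })
    list(
      predictions = dplyr::bind_rows(purrr::map(per_day, "predictions")),
      dropped = dplyr::bind_rows(purrr::map(per_day, "dropped"))
    )
  })
  structure(list(
    predictions = dplyr::bind_rows(purrr::map(res, "predictions")),
    dropped = dplyr::bind_rows(purrr::map(res, "dropped")),
    scheme = scheme, horizon = horizon, m = length(cohorts)
  ), class = "serial_prediction")
}

score_risk_set <- function(rs, model, scheme, imp = 1L, day = 0L) {
  req <- if (inherits(model, "logistic_model_spec")) model_requirements(model)
         else setdiff(names(rs), c("patient_id", "day", "label"))
  req <- intersect(req, names(rs))
  ok <- if (length(req)) !Reduce(`|`, lapply(req, function(cv) is.na(rs[[cv]])))
        else rep(TRUE, nrow(rs))
  scored <- rs[ok, , drop = FALSE]
  prob <- if (!nrow(scored)) numeric(0)
          else if (inherits(model, "logistic_model_spec")) {
            predict_risk(model, scored)
          } else {
            as.numeric(model(scored))
          }
  list(
    predictions = tibble::tibble(
      .imp = as.integer(imp),
      day = as.integer(day),
      patient_id = scored$patient_id,
      probability = prob,
      group = stratify_risk(prob, scheme),
      label = scored$label
    )[seq_len(nrow(scored)), ],
    dropped = tibble::tibble(.imp = as.integer(imp),
                             day = as.integer(day),
                             n_dropped = sum(!ok))
  )
}

#' @export
print.serial_prediction <- function(x, ...) {
  cat("<serial_prediction> days 0-", x$horizon - 1L,
      ", m = ", x$m, " dataset(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-day summary of a serial prediction
#'
#' @param x A `serial_prediction`.
#' @param ... Unused.
#' @return Tibble: `day`, `n_members`, `n_events`, `fraction_of_positives`
#'   (members and events averaged over imputations when `m > 1`).
#' @export
glance.serial_prediction <- function(x, ...) {
  x$predictions |>
    dplyr::group_by(.data$.imp, .data$day) |>
    dplyr::summarise(n_members = dplyr::n(), n_events = sum(.data$label),
                     .groups = "drop") |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n_members = mean(.data$n_members),
                     n_events = mean(.data$n_events), .groups = "drop") |>
    dplyr::mutate(fraction_of_positives = .data$n_events / .data$n_members)
}

#' @rdname glance.serial_prediction
#' @export
tidy.serial_prediction <- function(x, ...) x$predictions

#' Mean predicted-probability trajectories by final outcome status
#'
#' Splits each day's risk-set members by the patient's FINAL status —
#' adverse outcome at any time during follow-up versus an uncomplicated
#' course — and returns the mean predicted probability and member count per
#' day per group: the serial analogue of plotting mean risk trajectories
#' for the two groups. Days on which a group is empty carry `NA` (not 0)
#' as the mean.
#'
#' @param predictions A `serial_prediction`.
#' @param cohort The cohort it was computed from (for final status).
#' @return Tibble of class `trajectory_summary`: `day`, `final_status`,
#'   `mean_probability`, `n`.
#' @export
mean_trajectories <- function(predictions, cohort) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (inherits(cohort, "imputation_set")) cohort <- cohort$datasets[[1]]
  status <- cohort$patients |>
    dplyr::transmute(
      .data$patient_id,
      final_status = ifelse(is.na(.data$outcome_day),
                            "uncomplicated", "adverse")
    )
  out <- predictions$predictions |>
    dplyr::inner_join(status, by = "patient_id") |>
    dplyr::group_by(.data$.imp, .data$day, .data$final_status) |>
    dplyr::summarise(mean_probability = mean(.data$probability),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$day, .data$final_status) |>
    dplyr::summarise(mean_probability = mean(.data$mean_probability),
                     n = mean(.data$n), .groups = "drop") |>
    tidyr::complete(day = unique(predictions$predictions$day),
                    final_status = c("adverse", "uncomplicated"),
                    fill = list(n = 0)) |>
    dplyr::arrange(.data$day, .data$final_status)
  class(out) <- c("trajectory_summary", class(out))
  out
}
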