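#' Assign per-day patient states over risk groups and absorbing states
#'
#' Builds each patient's daily state sequence over days `0 .. horizon - 1`
#' for transition (Sankey) accounting. The state space is the scheme's
#' risk groups plus three display states: `outcome` (absorbing from
#' `outcome_day` on; outcome takes precedence over delivery), `delivered`
#' (absorbing from `delivery_day` on, for patients who never reach the
#' outcome within the horizon — a display convention: the serial-evaluation
#' risk sets deliberately keep delivered-but-followed patients, this view
#' does not), and `unscored` for patients present in neither a risk set nor
#' an absorbing state that day (e.g., required covariate unresolvable, or
#' censored without delivery).
#'
#' @param predictions A `serial_prediction` (first imputation's group
#'   assignments are used when `m > 1`).
#' @param cohort The cohort the predictions came from.
#' @return Tibble of class `state_sequences`: `patient_id`, `day`, `state`
#'   (factor: groups, then `unscored`, `delivered`, `outcome`).
#' @export
assign_daily_states <- function(predictions, cohort) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (inherits(cohort, "imputation_set")) cohort <- cohort$datasets[[1]]
  horizon <- predictions$horizon
  pred <- dplyr::filter(predictions$predictions, .data$.imp == 1L)
  extra <- setdiff(unique(pred$patient_id), cohort$patients$patient_id)
  if (length(extra)) {
    abort(paste0("prediction for patient absent from cohort: ", extra[1]))
  }
  levels_all <- c(predictions$scheme$labels, "unscored", "delivered", "outcome")

  grid <- tidyr::expand_grid(
    patient_id = cohort$patients$patient_id,
    day = seq_len(horizon) - 1L
  )
  out <- grid |>
    dplyr::left_join(
      dplyr::select(pred, "patient_id", "day", group_state = "group"),
      by = c("patient_id", "day")
    ) |>
    dplyr::left_join(cohort$patients, by = "patient_id") |>
    dplyr::mutate(
      has_outcome = !is.na(.data$outcome_day) &
        .data$outcome_day <= horizon - 1L,
      state = dplyr::case_when(
        .data$has_outcome & .data$day >= .data$outcome_day ~ "outcome",
        !.data$has_outcome & !is.na(.data$delivery_day) &
          .data$day >= .data$delivery_day ~ "delivered",
        !is.na(.data$group_state) ~ as.character(.data$group_state),
        TRUE ~ "unscored"
      ),
      state = factor(.data$state, levels = levels_all)
    ) |>
    dplyr::select("patient_id", "day", "state") |>
    dplyr::arrange(.data$patient_id, .data$day)
  class(out) <- c("state_sequences", class(out))
  attr(out, "scheme") <- predictions$scheme
  # first classification per (patient, group) from the predictions: unlike
  # the display states, this sees a classification made on the outcome day
  # itself (the patient is still a risk-set member that day)
  attr(out, "first_classification") <- pred |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(first_day = min(.data$day), .groups = "drop")
  out
}

#' Day-to-day flow table over patient states
#'
#' Counts, for each consecutive day pair `(d, d+1)`, the transitions
#' between states, plus the per-day state occupancy. Conservation holds by
#' construction: every patient occupies exactly one state each day, so
#' occupancy sums to the number of patients on every day and flows out of
#' day `d` sum to day-`d` occupancy.
#'
#' @param sequences A `state_sequences` tibble from [assign_daily_states()].
#' @return A `flow_table`: list with `flows` (tibble `day`, `from`, `to`,
#'   `n`), `occupancy` (tibble `day`, `state`, `n`), `n_patients`.
#' @export
build_flow_table <- function(sequences) {
  if (!nrow(sequences)) abort("sequences must be nonempty")
  per_pat <- dplyr::count(sequences, .data$patient_id)
  if (length(unique(per_pat$n)) != 1) {
    abort("ragged horizons: every patient needs a state for every day")
  }
  occupancy <- sequences |>
    dplyr::count(.data$day, .data$state, .drop = FALSE, name = "n")
  flows <- sequences |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(to = dplyr::lead(.data$state)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to)) |>
    dplyr::count(.data$day, from = .data$state, .data$to, name = "n")
  structure(list(flows = flows, occupancy = occupancy,
                 n_patients = nrow(per_pat)),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("<flow_table>", x$n_patients, "patients,",
      length(unique(x$occupancy$day)), "days\n")
  invisible(x)
}

#' Episode summary for one risk group
#'
#' First classification into a group is taken from the daily risk-group
#' predictions (carried on the sequences by [assign_daily_states()]), so a
#' classification made on the outcome day itself counts — the display
#' states, where the absorbing `outcome` state takes precedence that day,
#' would miss it.
#'
#' Summarizes the patients ever classified into a given risk group:
#' how many there were (`n_ever`), how many of them had the adverse
#' outcome (`n_outcome`), how many reached it within `window` days of
#' FIRST classification into the group (`n_outcome_within_window`:
#' `outcome_day - first_day < window`), how many had an uncomplicated
#' course (`n_uncomplicated`), how many of the uncomplicated delivered
#' within the window of first classification (`n_delivered_within_window`),
#' and how many moved to a higher risk group before their outcome
#' (`n_escalated_before_outcome`).
#'
#' @param sequences A `state_sequences` tibble.
#' @param cohort The source cohort.
#' @param group Risk-group label to summarize.
#' @param window Days after first classification (default 2: "within
#'   2 days of first being classified").
#' @return One-row tibble.
#' @export
group_episode_summary <- function(sequences, cohort, group, window = 2) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (inherits(cohort, "imputation_set")) cohort <- cohort$datasets[[1]]
  scheme <- attr(sequences, "scheme")
  labs <- if (!is.null(scheme)) scheme$labels else
    setdiff(levels(sequences$state), c("unscored", "delivered", "outcome"))
  if (!group %in% labs) abort(paste0("unknown risk group: ", group))
  g_idx <- match(group, labs)

  fc <- attr(sequences, "first_classification")
  first_in <- if (!is.null(fc)) {
    fc |>
      dplyr::filter(.data$group == !!group) |>
      dplyr::select("patient_id", "first_day")
  } else {
    # hand-built sequences: fall back to the display states
    in_group <- dplyr::filter(sequences, .data$state == group)
    in_group |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_day = min(.data$day), .groups = "drop")
  }
  if (!nrow(first_in)) {
    return(tibble::tibble(group = group, n_ever = 0L, n_outcome = 0L,
                          n_outcome_within_window = 0L, n_uncomplicated = 0L,
                          n_delivered_within_window = 0L,
                          n_escalated_before_outcome = 0L))
  }
  info <- dplyr::inner_join(first_in, cohort$patients, by = "patient_id")

  higher <- if (g_idx < length(labs)) labs[(g_idx + 1):length(labs)] else character()
  escalated <- sequences |>
    dplyr::inner_join(dplyr::select(info, "patient_id", "first_day",
                                    "outcome_day"), by = "patient_id") |>
    dplyr::filter(!is.na(.data$outcome_day),
                  .data$state %in% higher,
                  .data$day > .data$first_day,
                  .data$day < .data$outcome_day) |>
    dplyr::distinct(.data$patient_id)

  has_outcome <- !is.na(info$outcome_day)
  tibble::tibble(
    group = group,
    n_ever = nrow(info),
    n_outcome = sum(has_outcome),
    n_outcome_within_window =
      sum(has_outcome & info$outcome_day - info$first_day < window),
    n_uncomplicated = sum(!has_outcome),
    n_delivered_within_window =
      sum(!has_outcome & !is.na(info$delivery_day) &
            info$delivery_day - info$first_day < window),
    n_escalated_before_outcome = nrow(escalated)
  )
}

#' Export a flow table as Sankey JSON
#'
#' Writes `{nodes: [{id, day, state}], links: [{source, target, value}]}`
#' with node ids `"d<day>:<state>"`; only links with positive counts are
#' emitted, and link values re-aggregate exactly to the flow table. Any
#' Sankey renderer consuming a nodes/links schema can draw it.
#'
#' @param flow A `flow_table`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
export_sankey <- function(flow, path) {
  f <- dplyr::filter(flow$flows, .data$n > 0)
  node_id <- function(day, state) paste0("d", day, ":", state)
  occ <- dplyr::filter(flow$occupancy, .data$n > 0)
  nodes <- purrr::pmap(occ, function(day, state, n) {
    list(id = node_id(day, state), day = day, state = as.character(state),
         occupancy = n)
  })
  links <- purrr::pmap(f, function(day, from, to, n) {
    list(source = node_id(day, from), target = node_id(day + 1L, to),
         value = n)
  })
  jsonlite::write_json(list(nodes = nodes, links = links), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
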