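two_day_prediction <- function(tbl, scheme = stratification_scheme(),
                               horizon = 5L) {
  # build a serial_prediction object from a hand-specified tibble
  structure(list(
    predictions = dplyr::mutate(
      tbl, .imp = 1L,
      group = factor(group, levels = scheme$labels, ordered = TRUE)
    ),
    dropped = tibble::tibble(.imp = integer(), day = integer(),
                             n_dropped = integer()),
    scheme = scheme, horizon = as.integer(horizon), m = 1L
  ), class = "serial_prediction")
}

simple_cohort <- function(pats) {
  meas <- tibble::tibble(patient_id = pats$patient_id, day = 0L,
                         sbp_max = 150, platelets = 200, ast = 30)
  longitudinal_cohort(meas, pats, schema = mini_schema())
}

test_that("states follow predictions until absorption by outcome", {
  pats <- tibble::tibble(patient_id = "a", outcome_day = 2L,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 2L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0:2, patient_id = "a", probability = c(0.1, 0.3, 0.5),
    group = c("moderate", "high", "very_high"), label = c(0L, 1L, 1L)
  ))
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  expect_equal(as.character(seqs$state),
               c("moderate", "high", "outcome", "outcome", "outcome"))
})

test_that("delivery absorbs uncomplicated patients from the delivery day", {
  pats <- tibble::tibble(patient_id = "b", outcome_day = NA_integer_,
                         delivery_day = 1L, end_of_followup_day = 3L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0:3, patient_id = "b", probability = 0.1,
    group = "moderate", label = 0L
  ))
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  expect_equal(as.character(seqs$state),
               c("moderate", "delivered", "delivered", "delivered",
                 "delivered"))
})

test_that("outcome takes precedence over an earlier delivery", {
  pats <- tibble::tibble(patient_id = "c", outcome_day = 3L,
                         delivery_day = 1L, end_of_followup_day = 3L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0:3, patient_id = "c", probability = 0.1,
    group = "moderate", label = c(0L, 0L, 1L, 1L)
  ))
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  expect_equal(as.character(seqs$state),
               c("moderate", "moderate", "moderate", "outcome", "outcome"))
})

test_that("patients without predictions or absorption show as unscored", {
  pats <- tibble::tibble(patient_id = "d", outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 0L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0L, patient_id = "d", probability = 0.1,
    group = "low", label = 0L
  ), horizon = 3L)
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  expect_equal(as.character(seqs$state), c("low", "unscored", "unscored"))
})

test_that("a prediction for an unknown patient is a consistency error", {
  pats <- tibble::tibble(patient_id = "e", outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 1L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0L, patient_id = "ghost", probability = 0.1,
    group = "low", label = 0L
  ), horizon = 2L)
  expect_error(assign_daily_states(pred, simple_cohort(pats)),
               "absent from cohort")
})

test_that("stationary patients produce constant flows", {
  pats <- tibble::tibble(patient_id = c("f", "g"),
                         outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 2L)
  pred <- two_day_prediction(
    tidyr::expand_grid(day = 0:2, patient_id = c("f", "g")) |>
      dplyr::mutate(probability = 0.1, group = "moderate", label = 0L),
    horizon = 3L
  )
  flow <- build_flow_table(assign_daily_states(pred, simple_cohort(pats)))
  mm <- dplyr::filter(flow$flows, from == "moderate", to == "moderate")
  expect_equal(mm$n, c(2L, 2L))
  expect_equal(nrow(dplyr::filter(flow$flows, n > 0)), 2)
})

test_that("occupancy plus cumulative absorption conserves patients", {
  sim <- generate_cohort(sim_config(n_patients = 250, seed = 15))
  imp <- multiple_impute(locf_fill(sim$cohort), m = 1, seed = 16)
  pred <- run_consecutive_prediction(imp, sim$config$truth_model)
  flow <- build_flow_table(assign_daily_states(pred, sim$cohort))
  totals <- flow$occupancy |>
    dplyr::group_by(day) |>
    dplyr::summarise(n = sum(n))
  expect_true(all(totals$n == flow$n_patients))
  # flows out of day d sum to day-d occupancy
  out_flows <- flow$flows |>
    dplyr::group_by(day) |>
    dplyr::summarise(n = sum(n))
  expect_true(all(out_flows$n == flow$n_patients))
  # absorbing permanence: no flow leaves outcome or delivered
  leaks <- dplyr::filter(flow$flows,
                         from %in% c("outcome", "delivered"),
                         as.character(from) != as.character(to), n > 0)
  expect_equal(nrow(leaks), 0)
})

test_that("episode summaries count outcomes within the window of first classification", {
  pats <- tibble::tibble(
    patient_id = c("h1", "h2", "h3"),
    outcome_day = c(2L, 3L, NA),
    delivery_day = c(NA, NA, 2L),
    end_of_followup_day = c(2L, 3L, 3L)
  )
  # h1 first very_high on day 1, outcome day 2: within the 2-day window
  # h2 first very_high on day 1, outcome day 3: outside the window
  # h3 first very_high on day 0, uncomplicated, delivered day 2: outside
  pred <- two_day_prediction(tibble::tribble(
    ~day, ~patient_id, ~probability, ~group, ~label,
    0L, "h1", 0.2, "moderate", 0L,
    1L, "h1", 0.6, "very_high", 1L,
    2L, "h1", 0.6, "very_high", 1L,
    0L, "h2", 0.2, "moderate", 0L,
    1L, "h2", 0.6, "very_high", 0L,
    2L, "h2", 0.6, "very_high", 1L,
    3L, "h2", 0.6, "very_high", 1L,
    0L, "h3", 0.5, "very_high", 0L,
    1L, "h3", 0.2, "moderate", 0L
  ), horizon = 4L)
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  s <- group_episode_summary(seqs, simple_cohort(pats), "very_high",
                             window = 2)
  expect_equal(s$n_ever, 3L)
  expect_equal(s$n_outcome, 2L)
  expect_equal(s$n_outcome_within_window, 1L)   # h1 only: 2 - 1 < 2
  expect_equal(s$n_uncomplicated, 1L)
  expect_equal(s$n_delivered_within_window, 0L) # h3: 2 - 0 = 2, not < 2
})

test_that("an unoccupied group yields an all-zero summary", {
  pats <- tibble::tibble(patient_id = "i", outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 1L)
  pred <- two_day_prediction(tibble::tibble(
    day = 0:1, patient_id = "i", probability = 0.1,
    group = "low", label = 0L
  ), horizon = 2L)
  seqs <- assign_daily_states(pred, simple_cohort(pats))
  s <- group_episode_summary(seqs, simple_cohort(pats), "very_high")
  expect_equal(s$n_ever, 0L)
  expect_equal(s$n_outcome, 0L)
})

test_that("episode inequalities hold across random runs", {
  set.seed(17)
  for (s in 1:5) {
    sim <- generate_cohort(sim_config(n_patients = 150, seed = 60 + s))
    imp <- multiple_impute(locf_fill(sim$cohort), m = 1, seed = s)
    pred <- run_consecutive_prediction(imp, sim$config$truth_model)
    seqs <- assign_daily_states(pred, sim$cohort)
    for (g in pred$scheme$labels) {
      es <- group_episode_summary(seqs, sim$cohort, g)
      expect_lte(es$n_outcome_within_window, es$n_outcome)
      expect_lte(es$n_outcome, es$n_ever)
      expect_equal(es$n_outcome + es$n_uncomplicated, es$n_ever)
    }
  }
})

test_that("sankey JSON re-aggregates to the flow table", {
  sim <- generate_cohort(sim_config(n_patients = 80, seed = 18,
                                    missingness = NULL))
  pred <- run_consecutive_prediction(sim$cohort, sim$config$truth_model,
                                     horizon = 5)
  flow <- build_flow_table(assign_daily_states(pred, sim$cohort))
  path <- withr::local_tempfile(fileext = ".json")
  export_sankey(flow, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(all(js$links$value > 0))
  back <- tibble::tibble(
    day = as.integer(sub("^d(\\d+):.*$", "\\1", js$links$source)),
    from = sub("^d\\d+:", "", js$links$source),
    to = sub("^d\\d+:", "", js$links$target),
    n = js$links$value
  ) |> dplyr::arrange(day, from, to)
  fl <- dplyr::filter(flow$flows, n > 0) |>
    dplyr::mutate(from = as.character(from), to = as.character(to)) |>
    dplyr::arrange(day, from, to)
  expect_equal(back$n, fl$n)
  expect_equal(back$from, fl$from)
})
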