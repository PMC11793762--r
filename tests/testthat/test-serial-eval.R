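three_patient_cohort <- function() {
  # A: outcome day 2; B: delivered day 1, followed to day 3; C: full follow-up
  meas <- tibble::tribble(
    ~patient_id, ~day, ~sbp_max, ~platelets, ~ast,
    "A", 0, 160, 150, 60,
    "A", 2, 170, 120, 80,
    "B", 0, 145, 230, 25,
    "B", 3, 140, 235, 24,
    "C", 0, 150, 210, 30,
    "C", 6, 152, NA,  33
  )
  pats <- tibble::tribble(
    ~patient_id, ~outcome_day, ~delivery_day, ~end_of_followup_day,
    "A", 2L, NA_integer_, 2L,
    "B", NA_integer_, 1L, 3L,
    "C", NA_integer_, NA_integer_, 13L
  )
  longitudinal_cohort(meas, pats, schema = mini_schema())
}

test_that("risk-set membership follows the outcome/follow-up/measurement rule", {
  co <- three_patient_cohort()
  expect_setequal(build_daily_risk_set(co, 0)$patient_id, c("A", "B", "C"))
  # A's outcome is on day 2: still a member that day, gone from day 3
  expect_setequal(build_daily_risk_set(co, 2)$patient_id, c("A", "B", "C"))
  expect_setequal(build_daily_risk_set(co, 3)$patient_id, c("B", "C"))
  # B's follow-up ends day 3
  expect_setequal(build_daily_risk_set(co, 4)$patient_id, "C")
})

test_that("48-h labels cover the day and the next day only", {
  meas <- tibble::tibble(patient_id = "x", day = 0L, sbp_max = 150,
                         platelets = 200, ast = 30)
  pats <- tibble::tibble(patient_id = "x", outcome_day = 4L,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 4L)
  co <- longitudinal_cohort(meas, pats, schema = mini_schema())
  labels <- vapply(0:4, function(d) build_daily_risk_set(co, d)$label,
                   integer(1))
  expect_equal(labels, c(0L, 0L, 0L, 1L, 1L))  # days 3 and 4 within 48 h
})

test_that("effective covariates equal a brute-force carry-forward scan", {
  set.seed(21)
  for (i in 1:20) {
    co <- random_cohort(n_patients = 6, horizon = 7, miss_prob = 0.35)
    for (d in c(0, 2, 5)) {
      rs <- build_daily_risk_set(co, d)
      for (r in seq_len(nrow(rs))) {
        for (cv in c("sbp_max", "platelets", "ast")) {
          expect_identical(rs[[cv]][r],
                           brute_effective(co, rs$patient_id[r], cv, d))
        }
      }
    }
  }
})

test_that("a constant-probability model lands every member in one group", {
  co <- three_patient_cohort()
  stub <- function(covs) rep(0.05, nrow(covs))  # inside the moderate band
  pred <- run_consecutive_prediction(co, stub, horizon = 4)
  expect_true(all(pred$predictions$group == "moderate"))
  expect_true(all(pred$dropped$n_dropped == 0))
})

test_that("members with unresolvable required covariates are dropped, not scored", {
  meas <- tibble::tibble(patient_id = c("p1", "p2"), day = 0L,
                         sbp_max = c(150, 151), platelets = c(NA, 200),
                         ast = c(30, 31))
  pats <- tibble::tibble(patient_id = c("p1", "p2"),
                         outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 1L)
  co <- longitudinal_cohort(meas, pats, schema = mini_schema())
  m <- logistic_model_spec(0, list(list(covariates = "platelets",
                                        exponents = 1, coef = 0.001)))
  pred <- run_consecutive_prediction(co, m, horizon = 1)
  expect_equal(pred$predictions$patient_id, "p2")
  expect_equal(pred$dropped$n_dropped, 1L)
})

test_that("day-0 fraction of positives equals a direct event count", {
  sim <- generate_cohort(sim_config(n_patients = 600, seed = 8,
                                    missingness = NULL))
  pred <- run_consecutive_prediction(sim$cohort, sim$config$truth_model)
  g <- glance(pred)
  p <- sim$cohort$patients
  # day-0 members are all patients (everyone has a day-0 record)
  expect_equal(g$n_members[1], nrow(p))
  expect_equal(g$n_events[1],
               sum(!is.na(p$outcome_day) & p$outcome_day <= 1))
  expect_equal(g$fraction_of_positives[1], g$n_events[1] / g$n_members[1])
})

test_that("patients with day-0 outcomes never re-enter later risk sets", {
  meas <- tibble::tibble(patient_id = c("p1", "p2"), day = 0L,
                         sbp_max = 150, platelets = 200, ast = 30)
  pats <- tibble::tibble(patient_id = c("p1", "p2"),
                         outcome_day = c(0L, NA),
                         delivery_day = NA_integer_,
                         end_of_followup_day = c(0L, 5L))
  co <- longitudinal_cohort(meas, pats, schema = mini_schema())
  for (d in 1:5) {
    expect_false("p1" %in% build_daily_risk_set(co, d)$patient_id)
  }
})

test_that("risk sets deplete monotonically on generated cohorts", {
  sim <- generate_cohort(sim_config(n_patients = 300, seed = 9))
  ids_by_day <- lapply(0:13, function(d) {
    build_daily_risk_set(sim$cohort, d)$patient_id
  })
  p <- sim$cohort$patients
  for (d in 1:13) {
    eligible <- p$patient_id[
      (is.na(p$outcome_day) | p$outcome_day >= d) &
        p$end_of_followup_day >= d
    ]
    expect_true(all(ids_by_day[[d + 1]] %in% eligible))
    # every generated patient has a day-0 record, so sets are nested:
    # nobody re-enters after leaving
    expect_true(all(ids_by_day[[d + 1]] %in% ids_by_day[[d]]))
  }
})

test_that("distinct first-positive labels sum to the cohort's outcome count", {
  sim <- generate_cohort(sim_config(n_patients = 500, seed = 10,
                                    missingness = NULL))
  pred <- run_consecutive_prediction(sim$cohort, sim$config$truth_model)
  labelled <- pred$predictions |>
    dplyr::filter(label == 1) |>
    dplyr::distinct(patient_id)
  p <- sim$cohort$patients
  with_outcome_in_risk_set <- sum(!is.na(p$outcome_day) &
                                    p$outcome_day <= 13)
  expect_equal(nrow(labelled), with_outcome_in_risk_set)
})

test_that("mean trajectories split by final status with NA for empty groups", {
  meas <- tibble::tibble(patient_id = c("u1", "u2"), day = 0L,
                         sbp_max = 150, platelets = 200, ast = 30)
  pats <- tibble::tibble(patient_id = c("u1", "u2"),
                         outcome_day = NA_integer_,
                         delivery_day = NA_integer_,
                         end_of_followup_day = 0L)
  co <- longitudinal_cohort(meas, pats, schema = mini_schema())
  stub <- function(covs) c(0.2, 0.4)[seq_len(nrow(covs))]
  traj <- mean_trajectories(run_consecutive_prediction(co, stub, horizon = 1),
                            co)
  unc <- traj[traj$final_status == "uncomplicated", ]
  adv <- traj[traj$final_status == "adverse", ]
  expect_equal(unc$mean_probability, 0.3)
  expect_equal(unc$n, 2)
  expect_true(is.na(adv$mean_probability))  # undefined, not zero
  expect_equal(adv$n, 0)
})

test_that("the adverse group carries higher mean predicted risk on day 0", {
  for (s in 1:5) {
    sim <- generate_cohort(sim_config(n_patients = 700, seed = 50 + s,
                                      missingness = NULL))
    pred <- run_consecutive_prediction(sim$cohort, sim$config$truth_model)
    traj <- mean_trajectories(pred, sim$cohort)
    d0 <- traj[traj$day == 0, ]
    expect_gt(d0$mean_probability[d0$final_status == "adverse"],
              d0$mean_probability[d0$final_status == "uncomplicated"])
  }
})

test_that("imputation sets are evaluated per dataset and pooled", {
  set.seed(77)
  co <- locf_fill(random_cohort(n_patients = 30, horizon = 5,
                                miss_prob = 0.3), "platelets")
  imp <- multiple_impute(co, m = 3, seed = 1)
  m <- logistic_model_spec(-2, list(list(covariates = "ast", exponents = 1,
                                         coef = 0.02)))
  pred <- run_consecutive_prediction(imp, m, horizon = 3)
  expect_equal(sort(unique(pred$predictions$.imp)), 1:3)
  expect_equal(pred$m, 3L)
})
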