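# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately brute-force and independent of the package's
# implementation path.

mini_schema <- function() {
  cohort_schema(
    covariate = c("sbp_max", "platelets", "ast"),
    unit = c("mmHg", "1e9/L", "U/L"),
    type = "continuous",
    missing_class = c("none", "mnar", "mar")
  )
}

# two patients, two days each, fully observed
tiny_cohort <- function() {
  longitudinal_cohort(
    measurements = tibble::tribble(
      ~patient_id, ~day, ~sbp_max, ~platelets, ~ast,
      "p1", 0, 150, 210, 30,
      "p1", 1, 155, 200, 35,
      "p2", 0, 140, 250, 22,
      "p2", 1, 142, 240, 25
    ),
    patients = tibble::tribble(
      ~patient_id, ~outcome_day, ~delivery_day, ~end_of_followup_day,
      "p1", NA, 1L, 2L,
      "p2", NA, NA, 13L
    ),
    schema = mini_schema()
  )
}

# random valid cohort for property tests
random_cohort <- function(n_patients = 5, horizon = 6, miss_prob = 0.2) {
  pats <- purrr::map_dfr(seq_len(n_patients), function(i) {
    eof <- sample(0:(horizon - 1), 1)
    has_out <- runif(1) < 0.3
    out_day <- if (has_out) sample(0:eof, 1) else NA_integer_
    if (has_out) eof <- out_day
    del <- if (runif(1) < 0.4) sample(0:eof, 1) else NA_integer_
    tibble::tibble(patient_id = sprintf("r%02d", i),
                   outcome_day = as.integer(out_day),
                   delivery_day = as.integer(del),
                   end_of_followup_day = as.integer(eof))
  })
  meas <- purrr::map_dfr(seq_len(nrow(pats)), function(i) {
    last <- pats$end_of_followup_day[i]
    days <- sort(unique(c(0L, sample(0:last, sample(1:(last + 1), 1)))))
    tibble::tibble(
      patient_id = pats$patient_id[i], day = days,
      sbp_max = round(rnorm(length(days), 150, 10), 2),
      platelets = ifelse(runif(length(days)) < miss_prob, NA_real_,
                         round(rlnorm(length(days), log(210), 0.25), 1)),
      ast = ifelse(runif(length(days)) < miss_prob, NA_real_,
                   round(rlnorm(length(days), log(30), 0.4), 1))
    )
  })
  longitudinal_cohort(meas, pats, schema = mini_schema())
}

# --- independent metric oracles -------------------------------------

# AUC-PRC by explicit threshold enumeration over distinct scores
brute_auc_prc <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    flag <- scores >= t
    prec <- sum(labels[flag]) / sum(flag)
    rec <- sum(labels[flag]) / P
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# AUC-ROC by exhaustive positive-negative pair counting
brute_auc_roc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# brute-force carry-forward: latest non-missing value at day <= d
brute_effective <- function(cohort, pid, covariate, day) {
  m <- cohort$measurements
  rows <- m[m$patient_id == pid & m$day <= day & !is.na(m[[covariate]]), ]
  if (!nrow(rows)) return(NA_real_)
  rows[[covariate]][which.max(rows$day)]
}
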