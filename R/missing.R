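#' Last observation carried forward within patients
#'
#' Fills missing values of the named covariates with the patient's most
#' recent earlier observation — the standard treatment for labs missing not
#' at random, where a clinician may skip a measurement because the biomarker
#' is assumed unchanged (e.g., platelet counts). Leading missingness (no
#' prior observation) is preserved; all other covariates are untouched.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param cohort A `longitudinal_cohort` (a single patient timeline is just
#'   a 1-patient cohort).
#' @param covariates Covariate names to fill; defaults to the schema's
#'   MNAR class.
#' @return The cohort with the named covariates filled.
#' @export
locf_fill <- function(cohort, covariates = NULL) {
  covariates <- covariates %||% schema_class(cohort$schema, "mnar")
  unknown <- setdiff(covariates, schema_covariates(cohort$schema))
  if (length(unknown)) {
    abort(paste0("unknown covariate(s): ", paste(unknown, collapse = ", ")))
  }
  covariates <- intersect(covariates, names(cohort$measurements))
  m <- dplyr::arrange(cohort$measurements, .data$patient_id, .data$day)
  m <- m |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(covariates), carry_forward)) |>
    dplyr::ungroup()
  cohort$measurements <- m
  cohort
}

# vectorized LOCF on one ordered series
carry_forward <- function(x) {
  obs <- which(!is.na(x))
  if (!length(obs)) return(x)
  idx <- findInterval(seq_along(x), obs)
  out <- x
  fill <- idx > 0
  out[fill] <- x[obs[idx[fill]]]
  out
}

#' Multiple imputation of MAR covariates by chained equations
#'
#' Produces `m` completed datasets by chained univariate regression
#' imputation over the MAR-class covariates: each covariate is regressed on
#' all other covariates plus `day`, with Gaussian residual draws for
#' continuous covariates and Bernoulli draws from fitted probabilities for
#' binary ones, over a fixed number of chained sweeps. Observed values are
#' preserved exactly in every dataset; datasets differ only in their draws.
#' MNAR-class covariates must already be LOCF-filled ([locf_fill()]);
#' non-leading missingness remaining in an MNAR covariate is an error.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param m Number of completed datasets (conventionally 20).
#' @param seed Integer seed; the result is deterministic under `(m, seed)`.
#' @param sweeps Chained sweeps per dataset.
#' @return An `imputation_set`: list with `m`, `datasets` (list of completed
#'   cohorts), `seed`.
#' @export
multiple_impute <- function(cohort, m = 20, seed = 1L, sweeps = 5) {
  if (m < 1) abort("m must be >= 1")
  schema <- cohort$schema
  meas <- dplyr::arrange(cohort$measurements, .data$patient_id, .data$day)
  covs <- intersect(schema_covariates(schema), names(meas))

  mnar <- intersect(schema_class(schema, "mnar"), covs)
  for (cv in mnar) {
    x <- meas[[cv]]
    bad <- meas |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(bad = any(is.na(.data[[cv]]) &
                                   cumsum(!is.na(.data[[cv]])) > 0),
                       .groups = "drop")
    if (any(bad$bad)) {
      abort(paste0("MNAR covariate '", cv,
                   "' has non-leading missingness; run locf_fill() first"))
    }
  }

  targets <- intersect(schema_class(schema, "mar"), covs)
  targets <- targets[vapply(targets, function(cv) anyNA(meas[[cv]]), TRUE)]
  # leading missingness surviving LOCF in MNAR covariates is imputed too
  mnar_open <- mnar[vapply(mnar, function(cv) anyNA(meas[[cv]]), TRUE)]
  targets <- c(targets, mnar_open)
  for (cv in targets) {
    if (all(is.na(meas[[cv]]))) {
      abort(paste0("covariate '", cv, "' is 100% missing; cannot impute"))
    }
  }

  types <- setNames(schema$type[match(covs, schema$covariate)], covs)
  set.seed(as.integer(seed))
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    datasets[[k]] <- impute_once(meas, covs, targets, types, sweeps)
  }
  datasets <- lapply(datasets, function(d) {
    out <- cohort
    out$measurements <- d
    out
  })
  structure(list(m = as.integer(m), datasets = datasets,
                 seed = as.integer(seed)),
            class = "imputation_set")
}

impute_once <- function(meas, covs, targets, types, sweeps) {
  if (!length(targets)) return(meas)
  filled <- meas
  miss_idx <- lapply(targets, function(cv) which(is.na(meas[[cv]])))
  names(miss_idx) <- targets
  # initialize gaps from random observed draws
  for (cv in targets) {
    obs <- meas[[cv]][!is.na(meas[[cv]])]
    filled[[cv]][miss_idx[[cv]]] <- sample(obs, length(miss_idx[[cv]]),
                                           replace = TRUE)
  }
  preds_all <- c(covs, "day")
  for (s in seq_len(sweeps)) {
    for (cv in targets) {
      rows <- miss_idx[[cv]]
      if (!length(rows)) next
      preds <- setdiff(preds_all, cv)
      dat <- filled[, c(cv, preds)]
      obs_rows <- which(!is.na(meas[[cv]]))
      fml <- stats::reformulate(preds, response = cv)
      if (types[[cv]] == "binary") {
        fit <- suppressWarnings(glm(fml, data = dat[obs_rows, ],
                                    family = binomial()))
        p <- plogis(predict(fit, newdata = dat[rows, ]))
        filled[[cv]][rows] <- as.numeric(rbinom(length(rows), 1L, p))
      } else {
        fit <- lm(fml, data = dat[obs_rows, ])
        mu <- predict(fit, newdata = dat[rows, ])
        sigma <- sqrt(max(mean(fit$residuals^2), 1e-12))
        filled[[cv]][rows] <- mu + rnorm(length(rows), sd = sigma)
      }
    }
  }
  filled
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "completed datasets, seed", x$seed, "\n")
  invisible(x)
}

#' Pool per-dataset estimates from multiple imputation
#'
#' Downstream metrics (AUCs, likelihood ratios, net benefit) are computed
#' per completed dataset and pooled as their mean; the between-imputation
#' standard deviation is reported alongside. With `m = 1` the SD is 0.
#'
#' @param per_dataset_values Numeric vector, one value per completed
#'   dataset.
#' @return A tibble with columns `estimate`, `between_sd`, `m`.
#' @export
pool_estimates <- function(per_dataset_values) {
  x <- as.numeric(per_dataset_values)
  if (!length(x)) abort("need at least one per-dataset value")
  tibble::tibble(
    estimate = mean(x),
    between_sd = if (length(x) == 1L) 0 else sd(x),
    m = length(x)
  )
}
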