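#' Define a configurable logistic risk score
#'
#' The model is a logistic regression on the linear predictor
#' `eta = intercept + sum_k coef_k * prod_j covariate_j ^ exponent_j`, where
#' each term references one covariate (linear or squared) or the product of
#' two covariates — the functional form of published logistic risk scores
#' for adverse maternal outcome in preeclampsia, which include squared and
#' pairwise-interaction terms. Coefficients are configuration, not code:
#' published model coefficients are transcribed into a JSON/YAML file and
#' loaded with [load_model_spec()].
#'
#' @param intercept Intercept on the logit scale.
#' @param terms A list of terms, each a list with elements `covariates`
#'   (character, length 1 or 2), `exponents` (integer 1 or 2, same length)
#'   and `coef` (numeric scalar).
#' @param label Optional free-text name carried into output manifests.
#' @return A `logistic_model_spec`.
#' @examples
#' m <- logistic_model_spec(
#'   intercept = -1,
#'   terms = list(list(covariates = "platelets", exponents = 1, coef = 0.01))
#' )
#' predict_risk(m, tibble::tibble(platelets = 100)) # 0.5
#' @export
logistic_model_spec <- function(intercept = 0, terms = list(), label = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1, is.list(terms))
  terms <- lapply(terms, function(tm) {
    cov <- as.character(tm$covariates)
    expo <- as.integer(tm$exponents %||% rep(1L, length(cov)))
    if (length(cov) < 1 || length(cov) > 2) {
      abort("each term references 1 or 2 covariates")
    }
    if (length(expo) != length(cov) || !all(expo %in% c(1L, 2L))) {
      abort("exponents must match covariates and be 1 or 2")
    }
    if (!is.numeric(tm$coef) || length(tm$coef) != 1 || !is.finite(tm$coef)) {
      abort("term coefficient must be a finite number")
    }
    list(covariates = cov, exponents = expo, coef = as.numeric(tm$coef))
  })
  structure(
    list(intercept = as.numeric(intercept), terms = terms, label = label),
    class = "logistic_model_spec"
  )
}

#' @export
print.logistic_model_spec <- function(x, ...) {
  cat("<logistic_model_spec>", if (!is.null(x$label)) x$label, "\n")
  cat("  intercept:", format(x$intercept), "\n")
  for (tm in x$terms) {
    cat("  + ", format(tm$coef), " * ",
        paste0(tm$covariates, ifelse(tm$exponents == 2, "^2", ""),
               collapse = " * "), "\n", sep = "")
  }
  invisible(x)
}

#' Covariates a model spec requires
#' @param model A `logistic_model_spec`.
#' @return Character vector of covariate names.
#' @export
model_requirements <- function(model) {
  unique(unlist(lapply(model$terms, `[[`, "covariates")))
}

#' Predicted probability under a logistic risk score
#'
#' Applies the model to one or more complete covariate rows. A missing
#' required covariate is an explicit error (never a silent zero-fill): in
#' the serial evaluation engine, members that remain unresolvable after
#' carry-forward and imputation are dropped with logging, not scored.
#'
#' @param model A [logistic_model_spec()].
#' @param covariates A data frame (or single named list) with one column per
#'   required covariate; extra columns are ignored.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict_risk <- function(model, covariates) {
  if (!is.data.frame(covariates)) covariates <- tibble::as_tibble(covariates)
  req <- model_requirements(model)
  miss <- setdiff(req, names(covariates))
  if (length(miss)) {
    abort(paste0("missing required covariate(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(covariates)) {
    for (nm in req) {
      if (anyNA(covariates[[nm]])) {
        abort(paste0("missing (NA) value for required covariate: ", nm))
      }
    }
  }
  eta <- rep(model$intercept, nrow(covariates))
  for (tm in model$terms) {
    piece <- rep(tm$coef, nrow(covariates))
    for (j in seq_along(tm$covariates)) {
      piece <- piece * covariates[[tm$covariates[j]]]^tm$exponents[j]
    }
    eta <- eta + piece
  }
  plogis(eta)
}

#' Load / write a model spec as JSON or YAML
#'
#' The on-disk format is `{label, intercept, terms: [{covariates,
#' exponents, coef}, ...]}`. Format is chosen by file extension
#' (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @param schema Optional [cohort_schema()]; when given, terms naming a
#'   covariate outside the schema are rejected.
#' @return A `logistic_model_spec`.
#' @export
load_model_spec <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  terms <- lapply(raw$terms %||% list(), function(tm) {
    list(covariates = unlist(tm$covariates),
         exponents = unlist(tm$exponents %||% rep(1L, length(unlist(tm$covariates)))),
         coef = unlist(tm$coef))
  })
  spec <- logistic_model_spec(intercept = raw$intercept %||% 0,
                              terms = terms, label = raw$label)
  if (!is.null(schema)) {
    unknown <- setdiff(model_requirements(spec), schema_covariates(schema))
    if (length(unknown)) {
      abort(paste0("model term names covariate(s) absent from schema: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  spec
}

#' @rdname load_model_spec
#' @param model A `logistic_model_spec` to serialize.
#' @export
write_model_spec <- function(model, path) {
  obj <- list(label = model$label, intercept = model$intercept,
              terms = lapply(model$terms, function(tm) {
                list(covariates = as.list(tm$covariates),
                     exponents = as.list(tm$exponents),
                     coef = tm$coef)
              }))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Define an ordered risk-group stratification scheme
#'
#' Maps predicted probabilities to ordered risk groups by cut-offs on the
#' probability scale. The default is the published five-group scheme for
#' adverse maternal outcome within 48 h: very low (< 0.6%), low (0.6% to
#' 3.1%), moderate (> 3.1% to < 18.8%), high (18.8% to 45.6%) and very high
#' (> 45.6%). Boundary membership follows the printed interval sides: 0.6%
#' and 3.1% belong to *low*, 18.8% and 45.6% to *high*. The intervals
#' partition [0, 1]: every probability maps to exactly one group. A
#' dichotomizing rule is the degenerate 2-group scheme with one cut-off.
#'
#' @param labels Ordered group labels, lowest risk first.
#' @param cutoffs Strictly increasing cut-offs (proportions, length
#'   `length(labels) - 1`).
#' @param closed Character vector, one per cut-off: `"left"` if the cut-off
#'   value itself belongs to the group below, `"right"` if to the group
#'   above.
#' @return A `stratification_scheme`.
#' @export
stratification_scheme <- function(labels = c("very_low", "low", "moderate",
                                             "high", "very_high"),
                                  cutoffs = c(0.006, 0.031, 0.188, 0.456),
                                  closed = c("right", "left", "right", "left")) {
  labels <- as.character(labels)
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != length(labels) - 1) {
    abort("need exactly one fewer cut-off than labels")
  }
  if (any(diff(cutoffs) <= 0)) abort("cut-offs must be strictly increasing")
  if (any(cutoffs <= 0 | cutoffs >= 1)) abort("cut-offs must lie inside (0, 1)")
  closed <- rep_len(match.arg(closed, c("left", "right"), several.ok = TRUE),
                    length(cutoffs))
  structure(list(labels = labels, cutoffs = cutoffs, closed = closed),
            class = "stratification_scheme")
}

#' @export
print.stratification_scheme <- function(x, ...) {
  cat("<stratification_scheme> ", length(x$labels), " groups\n", sep = "")
  lo <- c(0, x$cutoffs)
  hi <- c(x$cutoffs, 1)
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-10s %s%s, %s%s\n", x$labels[i],
                if (i == 1) "[" else if (x$closed[i - 1] == "left") "(" else "[",
                format(lo[i]),
                format(hi[i]),
                if (i == length(x$labels)) "]" else
                  if (x$closed[i] == "left") "]" else ")"))
  }
  invisible(x)
}

#' Assign probabilities to risk groups
#'
#' @param p Numeric vector of probabilities in [0, 1].
#' @param scheme A [stratification_scheme()].
#' @return A factor with the scheme's labels as ordered levels; every
#'   probability maps to exactly one group.
#' @examples
#' stratify_risk(c(0.005, 0.031, 0.0311, 0.456, 0.4561))
#' @export
stratify_risk <- function(p, scheme = stratification_scheme()) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  idx <- rep(1L, length(p))
  for (k in seq_along(scheme$cutoffs)) {
    above <- if (scheme$closed[k] == "left") p > scheme$cutoffs[k]
             else p >= scheme$cutoffs[k]
    idx[above] <- k + 1L
  }
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
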