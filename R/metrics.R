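#' Area under the precision-recall curve (average precision)
#'
#' The average-precision estimator: with members ranked by descending
#' score, the sum over positives of the precision at that rank, divided by
#' the number of positives. Tied scores are handled by the tie-block rule —
#' every observation in a block of equal scores is assigned the precision
#' computed at the end of the block — which makes the estimator invariant
#' to the ordering within ties. This step-function estimator is used rather
#' than trapezoidal PR interpolation (known to be biased). The natural
#' comparison baseline is the fraction of positives: a label-independent
#' scorer attains AUC-PRC equal to the prevalence in expectation.
#'
#' @param scores Numeric scores (higher = more at risk).
#' @param labels Binary labels (0/1), same length.
#' @return AUC-PRC in [0, 1]; `NA` if there are no positives.
#' @examples
#' auc_prc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)) # (1 + 2/3) / 2
#' @export
auc_prc <- function(scores, labels) {
  check_scores(scores, labels)
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # block boundaries of tied scores
  ends <- cumsum(rle(s)$lengths)
  cum_tp <- cumsum(y)
  prec_at_end <- cum_tp[ends] / ends
  tp_in_block <- diff(c(0L, cum_tp[ends]))
  sum(tp_in_block * prec_at_end) / P
}

#' Area under the ROC curve (pairwise concordance)
#'
#' Mann-Whitney estimator: the fraction of (positive, negative) pairs in
#' which the positive scores higher, counting ties as 1/2.
#'
#' @inheritParams auc_prc
#' @return AUC-ROC in [0, 1]; `NA` unless both classes are present.
#' @export
auc_roc <- function(scores, labels) {
  check_scores(scores, labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

check_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  if (!length(scores)) abort("need at least one observation")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  invisible(TRUE)
}

#' Percentile-bootstrap confidence interval for a daily AUC
#'
#' Patient-level resampling with replacement, stratified by label so every
#' resample preserves the day's positive count (a day with a single-digit
#' event count would otherwise frequently lose all its positives and leave
#' the metric undefined). Percentile 2.5/97.5 bounds; deterministic under
#' `seed`. If the metric is undefined on more than half of the resamples,
#' the CI is reported as `NA` with an attached reason.
#'
#' @inheritParams auc_prc
#' @param metric `auc_prc`, `auc_roc`, or any function
#'   `f(scores, labels) -> scalar`.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Tibble with columns `lower`, `upper`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auc_prc, B = 2000,
                         seed = 1L, level = 0.95) {
  check_scores(scores, labels)
  if (B < 100) abort("B must be >= 100")
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(B), function(b) {
    idx <- c(
      if (length(pos)) sample(pos, length(pos), replace = TRUE),
      if (length(neg)) sample(neg, length(neg), replace = TRUE)
    )
    metric(scores[idx], labels[idx])
  }, numeric(1))
  if (mean(is.na(vals)) > 0.5) {
    return(tibble::tibble(lower = NA_real_, upper = NA_real_))
  }
  a <- (1 - level) / 2
  q <- quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7)
  tibble::tibble(lower = q[1], upper = q[2])
}

#' Per-group likelihood ratios under a stratification scheme
#'
#' For each risk group g, with flagging rule "member of g":
#' `LR(g) = P(flag | outcome) / P(flag | no outcome)`. Groups above the
#' middle band are reported as positive LRs (rule-in strength), groups
#' below it as negative LRs (rule-out strength). Edge semantics mirror the
#' conventional presentation: `Inf` when the group holds at least one
#' outcome and no non-outcomes, `NA` ("not applicable") when the group is
#' empty, `0` when it holds non-outcomes only. The 95% CI uses the standard
#' log-LR normal method with SE
#' `sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` on the flagged/unflagged
#' 2x2 table, and is suppressed (`NA`) for the Inf/NA/0 edge cases rather
#' than continuity-corrected away.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary outcome labels.
#' @param scheme A [stratification_scheme()].
#' @param groups Optional precomputed group factor (overrides
#'   stratification of `probabilities`).
#' @param level Confidence level.
#' @return Tibble: `group`, `type` (`"+LR"`/`"-LR"`/`""` for the middle
#'   band), `tp`, `fp`, `lr`, `lr_lower`, `lr_upper`, `n_in_group`.
#' @export
group_likelihood_ratios <- function(probabilities, labels,
                                    scheme = stratification_scheme(),
                                    groups = NULL, level = 0.95) {
  if (is.null(groups)) groups <- stratify_risk(probabilities, scheme)
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) abort("need at least one outcome and one non-outcome")
  z <- qnorm(1 - (1 - level) / 2)
  mid <- (length(scheme$labels) + 1) / 2

  purrr::imap_dfr(scheme$labels, function(lab, i) {
    flag <- groups == lab
    tp <- sum(flag & labels == 1)
    fp <- sum(flag & labels == 0)
    fn <- P - tp
    tn <- N - fp
    n_in <- tp + fp
    if (n_in == 0) {
      lr <- NA_real_
    } else if (fp == 0) {
      lr <- if (tp > 0) Inf else NA_real_   # tp==0 unreachable when n_in>0
    } else {
      lr <- (tp / P) / (fp / N)
    }
    ci <- c(NA_real_, NA_real_)
    if (is.finite(lr) && lr > 0 && tp > 0 && fp > 0) {
      se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      ci <- exp(log(lr) + c(-1, 1) * z * se)
    }
    tibble::tibble(
      group = lab,
      type = if (i > mid) "+LR" else if (i < mid) "-LR" else "",
      tp = tp, fp = fp, lr = lr,
      lr_lower = ci[1], lr_upper = ci[2],
      n_in_group = n_in
    )
  })
}

#' Net benefit of a flagging rule at a threshold probability
#'
#' `net_benefit = tp/n - fp/n * pt / (1 - pt)`: the true-positive rate
#' credited against the false-positive rate weighted by the odds of the
#' threshold probability `pt` — the decision-curve measure of clinical
#' utility. At `pt = 0` it equals the captured prevalence; "treat none"
#' (flagging nobody) has net benefit 0 at every threshold; "treat all" has
#' `rho - (1 - rho) * pt / (1 - pt)` at prevalence `rho`.
#'
#' @param tp,fp,fn,tn Confusion counts (non-negative; `n = tp+fp+fn+tn > 0`).
#' @param pt Threshold probability in `[0, 1)`.
#' @return Net benefit (real; can be negative).
#' @export
net_benefit <- function(tp, fp, fn, tn, pt) {
  if (any(pt < 0 | pt >= 1)) abort("threshold probability must lie in [0, 1)")
  n <- tp + fp + fn + tn
  if (any(n <= 0)) abort("confusion counts must sum to a positive n")
  tp / n - fp / n * pt / (1 - pt)
}

#' Decision curve: net benefit across a threshold grid
#'
#' Computes the net benefit of the model (flag = predicted probability
#' `>= pt`, closed at the threshold to match the stratification scheme's
#' closed sides at its printed cut-offs), of "treat all" and of "treat
#' none" (identically 0), across a threshold grid limited by convention to
#' 0-60% — wide enough to cover clinically plausible intervention
#' thresholds. The scheme's stratification cut-offs are flagged in the
#' output as reference thresholds.
#'
#' @inheritParams group_likelihood_ratios
#' @param grid Threshold probabilities; defaults to 0 to 0.60 by 0.01 with
#'   the scheme cut-offs inserted.
#' @param day Evaluation day carried into the output (annotation only).
#' @return Tibble of class `decision_curve`: `day`, `threshold`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`,
#'   `is_scheme_cutoff`.
#' @export
decision_curve <- function(probabilities, labels,
                           scheme = stratification_scheme(),
                           grid = NULL, day = NA_integer_) {
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    abort("labels must contain both classes")
  }
  cutoffs <- scheme$cutoffs
  if (is.null(grid)) grid <- sort(unique(c(seq(0, 0.60, by = 0.01), cutoffs)))
  if (any(grid < 0 | grid >= 1)) abort("grid thresholds must lie in [0, 1)")
  n <- length(labels)
  P <- sum(labels == 1)
  rho <- P / n
  rows <- purrr::map_dfr(grid, function(pt) {
    flag <- probabilities >= pt
    tp <- sum(flag & labels == 1)
    fp <- sum(flag & labels == 0)
    tibble::tibble(
      day = as.integer(day),
      threshold = pt,
      net_benefit_model = net_benefit(tp, fp, P - tp, (n - P) - fp, pt),
      net_benefit_all = net_benefit(P, n - P, 0, 0, pt),
      net_benefit_none = 0,
      is_scheme_cutoff = pt %in% cutoffs
    )
  })
  class(rows) <- c("decision_curve", class(rows))
  rows
}

#' Daily performance metrics of a serial prediction
#'
#' For each evaluation day: AUC-PRC and AUC-ROC with percentile-bootstrap
#' CIs, the day's fraction of positives (the AUC-PRC comparison baseline),
#' and per-group likelihood ratios with log-method CIs. With multiple
#' imputations, every metric is computed per completed dataset and pooled
#' as the across-dataset mean ([pool_estimates()]); bootstrap CIs are then
#' computed on the first dataset's predictions (between-imputation spread
#' is available from the per-dataset values).
#'
#' @param predictions A `serial_prediction` from
#'   [run_consecutive_prediction()].
#' @param B Bootstrap resamples per day (set `B = 0` to skip CIs).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return A tibble of class `daily_metrics`: `day`, `n_members`,
#'   `n_events`, `fraction_of_positives`, `auc_prc`, `auc_prc_lower/_upper`,
#'   `auc_roc`, `auc_roc_lower/_upper`, plus one `lr_<group>` (and CI)
#'   column set per risk group.
#' @export
daily_metrics <- function(predictions, B = 2000, seed = 1L, level = 0.95) {
  scheme <- predictions$scheme
  pred <- predictions$predictions
  days <- sort(unique(pred$day))

  purrr::map_dfr(days, function(d) {
    pd <- dplyr::filter(pred, .data$day == d)
    per_imp <- split(pd, pd$.imp)

    base <- purrr::map_dfr(per_imp, function(x) {
      tibble::tibble(
        n_members = nrow(x),
        n_events = sum(x$label),
        fraction_of_positives = mean(x$label),
        auc_prc = auc_prc(x$probability, x$label),
        auc_roc = auc_roc(x$probability, x$label)
      )
    }) |>
      dplyr::summarise(dplyr::across(dplyr::everything(),
                                     ~ mean(.x, na.rm = FALSE)))

    x1 <- per_imp[[1]]
    ci_prc <- ci_roc <- tibble::tibble(lower = NA_real_, upper = NA_real_)
    if (B > 0 && sum(x1$label) >= 1 && nrow(x1) >= 2) {
      ci_prc <- bootstrap_ci(x1$probability, x1$label, auc_prc, B = B,
                             seed = seed + d, level = level)
      if (sum(x1$label == 0) >= 1) {
        ci_roc <- bootstrap_ci(x1$probability, x1$label, auc_roc, B = B,
                               seed = seed + d + 10000L, level = level)
      }
    }

    lr <- NULL
    if (any(pd$label == 1) && any(pd$label == 0)) {
      lr_imp <- purrr::map(per_imp, function(x) {
        group_likelihood_ratios(x$probability, x$label, scheme,
                                groups = x$group, level = level)
      })
      lr <- dplyr::bind_rows(lr_imp) |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(
          lr = mean(.data$lr), lr_lower = mean(.data$lr_lower),
          lr_upper = mean(.data$lr_upper), .groups = "drop"
        )
      lr_wide <- purrr::reduce(purrr::pmap(lr, function(group, lr, lr_lower,
                                                        lr_upper) {
        setNames(tibble::tibble(lr, lr_lower, lr_upper),
                 paste0(c("lr_", "lr_lower_", "lr_upper_"), group))
      }), dplyr::bind_cols)
    } else {
      lr_wide <- NULL
    }

    out <- dplyr::bind_cols(
      tibble::tibble(day = d), base,
      tibble::tibble(auc_prc_lower = ci_prc$lower, auc_prc_upper = ci_prc$upper,
                     auc_roc_lower = ci_roc$lower, auc_roc_upper = ci_roc$upper)
    )
    if (!is.null(lr_wide)) out <- dplyr::bind_cols(out, lr_wide)
    out
  }) -> res
  class(res) <- c("daily_metrics", class(res))
  res
}

#' @export
tidy.daily_metrics <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-"day", names_to = "metric", values_to = "value")
}
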