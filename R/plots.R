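#' Plot mean risk trajectories by final outcome status
#'
#' Lines: mean predicted probability per day in the adverse-outcome and
#' uncomplicated-course groups. Bars (secondary layer): number of scored
#' patients per day in each group.
#'
#' @param x A `trajectory_summary` from [mean_trajectories()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_summary <- function(x, ...) {
  scale <- max(x$n, na.rm = TRUE)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$day, colour = .data$final_status,
                                  fill = .data$final_status)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n / scale),
                      position = "dodge", alpha = 0.3, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_probability),
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_probability), na.rm = TRUE) +
    ggplot2::scale_y_continuous(
      "mean predicted probability (48 h)",
      sec.axis = ggplot2::sec_axis(~ .x * scale, name = "patients scored")
    ) +
    ggplot2::labs(x = "days since first assessment", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot daily AUC-PRC against the fraction-of-positives baseline
#'
#' @param x A `daily_metrics` tibble.
#' @param metric `"auc_prc"` or `"auc_roc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.daily_metrics <- function(x, metric = c("auc_prc", "auc_roc"), ...) {
  metric <- match.arg(metric)
  lo <- paste0(metric, "_lower")
  hi <- paste0(metric, "_upper")
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_events /
                                     max(.data$n_events, na.rm = TRUE) *
                                     max(.data[[metric]], na.rm = TRUE)),
                      alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[lo]],
                                        ymax = .data[[hi]]),
                           width = 0.2, linetype = 2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[metric]]), na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[metric]]), na.rm = TRUE) +
    ggplot2::labs(x = "days since first assessment", y = toupper(metric)) +
    ggplot2::theme_minimal()
  if (metric == "auc_prc") {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$fraction_of_positives),
      colour = "#d4527b", na.rm = TRUE
    )
  }
  p
}

#' Plot a decision curve
#'
#' Net benefit of the model against "treat all" and "treat none" across
#' the threshold grid; scheme cut-offs are drawn as vertical reference
#' lines.
#'
#' @param x A `decision_curve` tibble (possibly several days).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decision_curve <- function(x, ...) {
  cuts <- unique(x$threshold[x$is_scheme_cutoff])
  long <- x |>
    tidyr::pivot_longer(dplyr::starts_with("net_benefit_"),
                        names_prefix = "net_benefit_",
                        names_to = "policy", values_to = "net_benefit")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                          y = .data$net_benefit,
                                          colour = .data$policy,
                                          linetype = .data$policy)) +
    ggplot2::geom_vline(xintercept = cuts, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(
      ylim = c(-0.02, max(long$net_benefit, na.rm = TRUE) * 1.05)
    ) +
    ggplot2::labs(x = "threshold probability", y = "net benefit") +
    ggplot2::theme_minimal()
  if (length(unique(x$day[!is.na(x$day)])) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$day),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot per-day state occupancy as a stacked area (Sankey-style overview)
#'
#' @param x A `flow_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_table <- function(x, ...) {
  ggplot2::ggplot(x$occupancy,
                  ggplot2::aes(x = .data$day, y = .data$n,
                               fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "days since first assessment", y = "patients") +
    ggplot2::theme_minimal()
}
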