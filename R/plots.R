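#' Plot a simulated trajectory
#'
#' One panel per state variable over time.
#'
#' @param object A `prostimm_trajectory`.
#' @param states Subset of state names to show (default all 15).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prostimm_trajectory
#' @export
autoplot.prostimm_trajectory <- function(object, states = NULL, ...) {
  long <- tidy(object)
  if (!is.null(states)) long <- long[long$state %in% states, ]
  long$state <- factor(long$state, levels = state_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "weeks post-treatment", y = "relative level",
                  title = attr(object, "regimen")$label)
}

#' Plot regimen efficacies
#'
#' Horizontal bars of percent tumor-growth inhibition for all 16
#' regimens, ordered by efficacy.
#'
#' @param outcomes Output of [predict_all_regimens()].
#' @param type Outcome type, `"I"` or `"II"`.
#' @return A ggplot.
#' @export
plot_regimen_outcomes <- function(outcomes, type = c("I", "II")) {
  type <- match.arg(type)
  tbl <- rank_regimens(outcomes, type)
  tbl$regimen <- factor(tbl$regimen, levels = rev(tbl$regimen))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$inhibition, y = .data$regimen)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("tumor inhibition, type %s outcome (%%)", type),
                  y = NULL)
}

#' Heatmap of the Bliss combination-index matrix
#'
#' Blank cells are inapplicable (overlapping) group pairs; values below 1
#' indicate synergy.
#'
#' @param cim A [ci_matrix()].
#' @return A ggplot.
#' @export
plot_ci_matrix <- function(cim) {
  m <- cim$matrix
  long <- tibble(
    group_a = rep(rownames(m), times = ncol(m)),
    group_b = rep(colnames(m), each = nrow(m)),
    ci = as.vector(m)
  )
  long$group_a <- factor(long$group_a, levels = rownames(m))
  long$group_b <- factor(long$group_b, levels = colnames(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                     fill = .data$ci)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("Bliss CI\n(type %s)", cim$type)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cross-validation fold predictions
#'
#' Predicted means with 95% bands against the observed held-out values.
#'
#' @param folds Output of [leave_one_condition_out()] or
#'   [leave_one_box_out()].
#' @return A ggplot.
#' @export
plot_cv_folds <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = factor(.data$time_weeks))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                           width = 0.2, color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), color = "black",
                        shape = 4, size = 2) +
    ggplot2::facet_grid(observable ~ condition, scales = "free_y") +
    ggplot2::labs(x = "weeks post-treatment", y = "relative level")
}
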