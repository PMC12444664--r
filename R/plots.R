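## ggplot2 displays for the pipeline's result objects.

#' Attrition waterfall plot
#'
#' Bar chart of patients remaining after each selection filter.
#'
#' @param cohort output of [select_cohort()] (or an attrition tibble from
#'   [attrition_log()]).
#' @return a ggplot object.
#' @export
plot_attrition <- function(cohort) {
  log <- if (inherits(cohort, "hnc_cohort")) attrition_log(cohort) else cohort
  log$step <- factor(log$step, levels = log$step)
  ggplot(log, aes(x = .data$step, y = .data$remaining)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = .data$remaining), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "patients remaining",
         title = "Selection cascade attrition") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 40, hjust = 1))
}

#' @describeIn tabulate_patterns autoplot method: pattern share per stratum.
#' @param object a `hnc_pattern_table`.
#' @param ... unused.
#' @export
autoplot.hnc_pattern_table <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$stratum, y = .data$pct, fill = .data$label)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "% of stratum", fill = "pattern",
         title = "Treatment patterns") +
    theme_minimal()
}

#' Regimen distribution bar chart
#'
#' @param regimens output of [regimen_distribution()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_regimen_distribution <- function(regimens, title = "Regimen mix") {
  df <- regimens
  df$regimen <- stats::reorder(df$regimen, df$n)
  ggplot(df, aes(x = .data$regimen, y = .data$pct)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "% of subgroup", title = title) +
    theme_minimal()
}

#' @describeIn summarize_utilization autoplot method: median event counts
#'   among users per category and stratum.
#' @param object a `hnc_utilization`.
#' @param ... unused.
#' @export
autoplot.hnc_utilization <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$category, y = .data$median, fill = .data$stratum)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "median events per user",
         title = "Resource utilization (12-month window)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 40, hjust = 1))
}
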