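#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a 30-day cost accrual series
#'
#' Mean allowed cost per enrolled patient by 30-day bin from the index
#' date, one line per cost series (total / inpatient / outpatient).
#'
#' @param object A `cost_bin_series` from [cost_accrual_30d()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cost_bin_series
#' @export
autoplot.cost_bin_series <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$bin, y = .data$mean_cost,
             colour = .data$setting_group)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "30-day bin from index date",
         y = "Mean allowed cost per enrolled patient (USD)",
         colour = "Series") +
    theme_minimal()
}

#' Plot covariate balance for a match result
#'
#' Pre- versus post-match L1 multivariate imbalance.
#'
#' @param object A `match_result` from [cem_match_k2k()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot match_result
#' @export
autoplot.match_result <- function(object, ...) {
  df <- tibble(stage = factor(c("pre-match", "post-match"),
                              levels = c("pre-match", "post-match")),
               l1 = c(object$pre_l1, object$post_l1))
  ggplot(df, aes(x = .data$stage, y = .data$l1)) +
    geom_col(width = 0.5, fill = "steelblue") +
    labs(x = NULL, y = "L1 multivariate imbalance") +
    theme_minimal()
}

#' Plot case and control cost curves together
#'
#' @param cases,controls `cost_bin_series` tibbles for the matched case and
#'   control groups.
#' @param setting Which series to show (default `"total"`).
#' @return A ggplot.
#' @export
plot_cost_comparison <- function(cases, controls, setting = "total") {
  df <- bind_rows(
    as_tibble(cases) |> mutate(group = "cases"),
    as_tibble(controls) |> mutate(group = "matched controls")
  ) |> filter(.data$setting_group == setting)
  ggplot(df, aes(x = .data$bin, y = .data$mean_cost, colour = .data$group)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "30-day bin from index date",
         y = "Mean allowed cost per enrolled patient (USD)",
         colour = NULL) +
    theme_minimal()
}
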