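#' Plot a method-comparison report
#'
#' Dot plot of the chosen statistic with methods ordered by value, in the
#' style of the benchmark's accuracy figures; the TBV reference row is
#' highlighted.
#'
#' @param object A `gs_report`.
#' @param statistic Column to plot (`"Acc"`, `"Rank"`, `"Regr"`, `"Var"`,
#'   `"MSEP"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_report <- function(object, statistic = "Acc", ...) {
  df <- tibble::as_tibble(object)
  if (!statistic %in% names(df)) abort(sprintf("no column `%s`", statistic))
  df$value <- df[[statistic]]
  df$is_ref <- df$Method == "TBV"
  df$Method <- factor(df$Method, levels = df$Method[order(df$value)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$Method,
                                   shape = .data$is_ref)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(x = statistic, y = NULL,
                  title = sprintf("Methods ordered by %s", statistic)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gs_report
#' @export
autoplot.gs_benchmark <- function(object, statistic = "Acc", ...) {
  autoplot(object$report, statistic = statistic, ...)
}

#' Predicted against true breeding values
#'
#' @param gebv A `gs_gebv` tibble.
#' @param tbv A tibble (`individual_id`, `tbv`).
#' @return A ggplot object with the identity line for reference.
#' @export
plot_gebv_vs_tbv <- function(gebv, tbv) {
  j <- dplyr::inner_join(tibble::as_tibble(gebv), tibble::as_tibble(tbv),
                         by = "individual_id")
  ggplot2::ggplot(j, ggplot2::aes(x = .data$gebv, y = .data$tbv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Predicted breeding value", y = "True breeding value",
                  title = attr(gebv, "method") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of observed growth curves
#'
#' @param phenotypes A `gs_phenotypes` table.
#' @param n Number of individuals to draw (first `n` rows).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(phenotypes, n = 25) {
  times <- phenotype_times(phenotypes)
  df <- utils::head(tibble::as_tibble(phenotypes), n) |>
    tidyr::pivot_longer(dplyr::starts_with("y_"), names_to = "time",
                        values_to = "yield") |>
    dplyr::mutate(time = as.numeric(sub("^y_", "", .data$time)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$yield,
                                   group = .data$individual_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time", y = "Cumulative yield") +
    ggplot2::theme_minimal()
}
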