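# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @export
tidy.benchmark_report <- function(x, ...) {
  select(x$metrics, "metric", "percent", "numerator", "denominator")
}

#' @export
glance.benchmark_report <- function(x, ...) {
  wide <- setNames(as.list(x$metrics$percent), x$metrics$metric)
  as_tibble(c(wide, list(n_responses = x$n_responses, n_parse_ok = x$n_parse_ok)))
}

#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(df$metric, levels = rev(df$metric))
  ggplot(df, aes(x = .data$metric, y = .data$percent)) +
    geom_col(fill = "#2c7fb8") +
    geom_hline(yintercept = 100, linetype = "dashed", colour = "grey40") +
    scale_y_continuous(limits = c(0, 100.5)) +
    coord_flip() +
    labs(x = NULL, y = "percent of responses / reactions",
         title = "Response-quality benchmarks") +
    theme_minimal()
}

#' @export
tidy.similarity_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$best_similarity), , drop = FALSE]
  ggplot(df, aes(x = .data$best_similarity,
                 fill = .data$exact_match)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05)) +
    labs(x = "best-analog Tanimoto similarity to target", y = "targets",
         fill = "exact match",
         title = "Reconstruction similarity distribution") +
    theme_minimal()
}
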