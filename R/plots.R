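# ggplot2 displays for the three result types. Each autoplot() returns a
# plain ggplot object for further styling.

#' @exportS3Method ggplot2::autoplot
autoplot.feature_distribution <- function(object, ...) {
  df <- as_tibble(unclass_profile(object))
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "peaks (%)",
                  title = "Peak distribution across gene-regulatory regions") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.position_profile <- function(object, ...) {
  df <- as_tibble(unclass_profile(object))
  anchor <- toupper(attr(object, "anchor"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$percent_of_max)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = sprintf("distance from %s (bp, 5' to 3')", anchor),
                  y = "peaks passing position (% of max)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coloc_profile <- function(object, ...) {
  df <- as_tibble(unclass_profile(object))
  df$bin <- factor(sprintf("%g-%g", df$bin_lower, df$bin_upper),
                   levels = sprintf("%g-%g", df$bin_lower, df$bin_upper))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$hmd)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "distance from anchor peak center (bp)",
                  y = "query density (per 100 anchor peaks per kb)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.feature_distribution <- function(x, ...) {
  as_tibble(unclass_profile(x))
}

#' @exportS3Method generics::glance
glance.feature_distribution <- function(x, ...) {
  tibble(
    n_peaks = attr(x, "n_peaks"),
    n_categories = nrow(x),
    top_category = x$category[which.max(x$count)],
    top_percentage = max(x$percentage)
  )
}

#' @exportS3Method generics::tidy
tidy.position_profile <- function(x, ...) {
  as_tibble(unclass_profile(x))
}

#' @exportS3Method generics::glance
glance.position_profile <- function(x, ...) {
  tibble(
    anchor = attr(x, "anchor"),
    n_genes = attr(x, "n_genes"),
    n_peaks = attr(x, "n_peaks"),
    max_count = max(x$count),
    peak_offset = x$offset[which.max(x$count)]
  )
}
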