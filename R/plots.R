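#' Trend plot for one category
#'
#' Mean mapped-read count against time for a single category, one series per
#' condition, with SEM error bars where available.
#'
#' @param tc A `trf_timecourse`.
#' @param category Category label to plot.
#' @return A ggplot object.
#' @export
plot_category_trend <- function(tc, category) {
  dat <- tc %>% filter(as.character(.data$category) == !!category)
  if (!nrow(dat)) abort(paste0("no rows for category ", category))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_min, y = .data$mean_count,
                                    colour = .data$condition,
                                    group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_count - .data$sem,
                   ymax = .data$mean_count + .data$sem),
      width = 2, na.rm = TRUE) +
    ggplot2::labs(x = "Time after germination initiation (min)",
                  y = "Mean mapped reads",
                  colour = "Condition",
                  title = paste("Category", category)) +
    ggplot2::theme_bw()
}

#' @method autoplot trf_timecourse
#' @export
autoplot.trf_timecourse <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_min, y = .data$mean_count,
                               colour = .data$condition,
                               group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_count - .data$sem,
                   ymax = .data$mean_count + .data$sem),
      width = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "Time after germination initiation (min)",
                  y = "Mean mapped reads", colour = "Condition") +
    ggplot2::theme_bw()
}

#' @method autoplot trf_profile
#' @export
autoplot.trf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category, y = .data$count,
                                       fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Category", y = "Mapped reads", fill = "Sample") +
    ggplot2::theme_bw()
}
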