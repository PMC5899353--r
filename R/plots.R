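#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves with censoring tick marks, one per group if
#' the curve was estimated by group.
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  has_group <- "group" %in% names(df)
  if (!has_group) df$group <- "all"
  # prepend t = 0, S = 1 per group so the step starts at 1
  lead <- dplyr::distinct(df, .data$group)
  lead$time <- 0; lead$survival <- 1; lead$n_event <- 0L; lead$n_censor <- 0L
  if ("cutpoint_label" %in% names(df)) lead$cutpoint_label <- df$cutpoint_label[1]
  plot_df <- dplyr::bind_rows(lead, df)
  p <- ggplot2::ggplot(plot_df,
                       ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$n_censor > 0),
                        shape = 3, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Recurrence-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!has_group) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot the stage-2 centroid kinetic curves of a METV result
#'
#' Shows the mean relative-enhancement curve of each stage-2 cluster over the
#' post-contrast acquisition times; the most-enhancing cluster defines METV.
#'
#' @param x A [exam_metv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_kinetic_centroids <- function(x, ...) {
  if (!inherits(x, "metv_result")) {
    abort("`x` must be a metv_result.", class = "metvolume_input_error")
  }
  v <- x$centroid_curves
  times <- x$times_min[-1]
  df <- tibble::tibble(
    cluster = factor(rep(seq_len(nrow(v)), each = ncol(v))),
    time_min = rep(times, times = nrow(v)),
    rel_enhancement = as.vector(t(v))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$rel_enhancement,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Time post contrast (min)", y = "Relative enhancement",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}
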