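#' Plot a normalized diameter trace
#'
#' Normalized trace (percent of basal) against time with the stimulation
#' window shaded and the 100% basal line drawn.
#'
#' @param object A [normalize_trace()] / [average_trials()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_trace <- function(object, ...) {
  p <- attr(object, "protocol")
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$pct))
  if (!is.null(p)) {
    gg <- gg + ggplot2::annotate(
      "rect", xmin = p$stim_onset_s, xmax = p$stim_onset_s + p$stim_duration_s,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
    )
  }
  gg +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "diameter (% of basal)")
}

#' Plot a diameter trace in physical units
#'
#' @param object An [extract_diameter_trace()] tibble.
#' @param ... Unused.
#' @return A ggplot object with flagged frames marked.
#' @export
autoplot.diameter_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$diameter_um)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(
      data = object[object$quality != "ok", ],
      ggplot2::aes(colour = .data$quality), size = 1
    ) +
    ggplot2::labs(x = "time (s)", y = "diameter (µm)", colour = "flag")
}

#' Plot an IOS activity map
#'
#' @param object An [ios_activity_map()] result.
#' @param ... Unused.
#' @return A ggplot raster of the summed dR/R map.
#' @export
autoplot.ios_activity_map <- function(object, ...) {
  d <- dim(object$map)
  df <- tibble(
    row = rep(0:(d[1] - 1), d[2]),
    col = rep(0:(d[2] - 1), each = d[1]),
    value = as.vector(object$map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  fill = expression(Sigma ~ Delta * R / R))
}

#' Mouse-level summary plot of a response parameter
#'
#' Mouse means (points) by group, with group mean +/- SD overlaid — the
#' mean ± SD-by-independent-unit convention of nested designs.
#'
#' @param table A metric table (see [nested_compare()]).
#' @param metric Metric column name.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(table, metric) {
  mm <- summarize_by_mouse(table, metric)
  stopifnot("group" %in% names(mm))
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1),
                          geom = "pointrange", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = metric,
                  subtitle = "points: mouse means; bar: group mean ± SD")
}
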