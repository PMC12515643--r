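# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_tile geom_text
#'   geom_col facet_wrap scale_color_gradient2 scale_fill_gradient2 labs
#'   theme_minimal autoplot coord_fixed
NULL

#' Plot microstate template maps
#'
#' Draws each class map as coloured electrodes at their approximate scalp
#' positions (built-in 16-channel motor montage), faceted by class. Red and
#' blue mark opposite polarities; under the microstate convention the sign is
#' arbitrary.
#'
#' @param object A `topography_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topography_model <- function(object, ...) {
  xy <- .montage_xy()
  if (!all(object$channel_labels %in% rownames(xy))) {
    # fall back to a class x channel heatmap for unknown montages
    td <- generics::tidy(object)
    return(
      ggplot(td, aes(x = .data$channel, y = .data$class, fill = .data$value)) +
        geom_tile() +
        scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
        labs(x = "channel", y = "class", fill = "a.u.") +
        theme_minimal()
    )
  }
  xy <- xy[object$channel_labels, , drop = FALSE]
  td <- generics::tidy(object)
  td$x <- xy[td$channel, "x"]
  td$y <- xy[td$channel, "y"]
  ggplot(td, aes(x = .data$x, y = .data$y, color = .data$value)) +
    geom_point(size = 5) +
    facet_wrap(~class) +
    scale_color_gradient2(low = "blue", mid = "grey95", high = "red") +
    coord_fixed() +
    labs(title = "Microstate template maps", x = NULL, y = NULL,
         color = "a.u.") +
    theme_minimal()
}

#' Plot a GFP trace with its peaks
#'
#' @param object A `gfp_series` (run [find_gfp_peaks()] first to mark peaks).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gfp_series <- function(object, ...) {
  df <- as_tibble(object)
  df$t <- if (is.null(object$fs)) df$sample else (df$sample - 1) / object$fs
  p <- ggplot(df, aes(x = .data$t, y = .data$gfp_uV)) +
    geom_line() +
    labs(x = if (is.null(object$fs)) "sample" else "time (s)",
         y = "GFP (uV)") +
    theme_minimal()
  if (any(df$is_peak)) {
    p <- p + geom_point(data = df[df$is_peak, ], color = "red", size = 1.5)
  }
  p
}

#' Plot temporal microstate parameters
#'
#' Bar panels of mean duration, coverage and occurrence per class, optionally
#' coloured by a grouping column (e.g. subject group or session).
#'
#' @param params A tibble from [microstate_parameters()], possibly row-bound
#'   across subjects with extra columns.
#' @param group Optional name of a column to map to fill.
#' @return A ggplot object.
#' @export
plot_parameters <- function(params, group = NULL) {
  long <- tidyr::pivot_longer(
    params,
    cols = c("mean_duration_ms", "coverage_pct", "occurrence_per_s"),
    names_to = "metric", values_to = "value"
  )
  mapping <- if (is.null(group)) {
    aes(x = .data$class, y = .data$value)
  } else {
    aes(x = .data$class, y = .data$value, fill = .data[[group]])
  }
  ggplot(long, mapping) +
    geom_col(position = "dodge") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "microstate class", y = NULL) +
    theme_minimal()
}

#' Plot a change-score correlation matrix
#'
#' Heatmap of the parameter x muscle correlation table from
#' [correlation_matrix()], with significance stars at adjusted p < 0.05 (`*`)
#' and < 0.01 (`**`).
#'
#' @param corr Output of [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(corr) {
  ggplot(corr, aes(x = .data$muscle, y = .data$parameter, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$sig), size = 3) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    labs(x = "muscle", y = "microstate parameter", fill = "r") +
    theme_minimal()
}
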