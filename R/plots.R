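# ggplot2 views of the main result types. Display smoothing (moving-average
# windows) is a plotting option only and is never applied before statistics.

#' @importFrom ggplot2 ggplot aes geom_line geom_tile geom_point geom_col
#'   labs scale_fill_gradient2 scale_fill_viridis_c theme_minimal
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metric time series
#'
#' @param series Tibble with `time_ns` and a value column (e.g. from
#'   [rmsd_series()] or [kink_angle()]).
#' @param value Name of the value column.
#' @param smooth_ns Optional centred moving-average window (ns) for display.
#' @return A ggplot object.
#' @export
plot_series <- function(series, value = "rmsd", smooth_ns = NULL) {
  df <- series
  if (!is.null(smooth_ns) && nrow(df) > 1) {
    dt <- diff(df$time_ns[1:2])
    w <- max(1L, round(smooth_ns / dt))
    df[[value]] <- stats::filter(df[[value]], rep(1 / w, w), sides = 2)
  }
  ggplot(df, aes(x = .data$time_ns, y = .data[[value]])) +
    geom_line(na.rm = TRUE) +
    labs(x = "time (ns)", y = value) +
    theme_minimal()
}

#' Plot a displacement map
#'
#' @param map Matrix from [displacement_map()].
#' @return A ggplot object (diverging scale centred at zero; positive =
#'   moving apart).
#' @export
plot_displacement_map <- function(map) {
  df <- as_tibble(as.table(map), .name_repair = "minimal")
  names(df) <- c("i", "j", "displacement")
  df$i <- as.integer(as.character(df$i))
  df$j <- as.integer(as.character(df$j))
  ggplot(df, aes(.data$i, .data$j, fill = .data$displacement)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "residue", y = "residue", fill = "Δd (Å)") +
    theme_minimal()
}

#' Plot an occurrence-weighted interaction network as an edge heat strip
#'
#' @param object An `interaction_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_network <- function(object, ...) {
  df <- tidy.interaction_network(object)
  ggplot(df, aes(.data$i, .data$j, fill = .data$occurrence)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "residue i", y = "residue j", fill = "occurrence") +
    theme_minimal()
}

#' Plot cluster assignments on the first two feature coordinates
#'
#' @param object A `cluster_result`.
#' @param observations The feature matrix the result was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, observations = NULL, ...) {
  df <- tidy.cluster_result(object)
  if (!is.null(observations)) {
    df$x <- observations[, 1]
    df$y <- if (ncol(observations) > 1) observations[, 2] else 0
  } else {
    df$x <- df$observation
    df$y <- df$log_density
  }
  ggplot(df, aes(.data$x, .data$y, colour = factor(.data$cluster))) +
    geom_point(size = 0.8) +
    labs(colour = "cluster") +
    theme_minimal()
}

#' Scree plot of an essential subspace
#'
#' @param object An `essential_subspace`.
#' @param n_components Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.essential_subspace <- function(object, n_components = 30, ...) {
  df <- tidy.essential_subspace(object) |>
    filter(.data$component <= n_components)
  ggplot(df, aes(.data$component, .data$eigenvalue)) +
    geom_col() +
    labs(x = "principal component", y = "variance (Å²)") +
    theme_minimal()
}
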