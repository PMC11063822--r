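#' Plot a multi-channel recording with optional detected bursts
#'
#' One facet per channel; detected burst extents can be overlaid as shaded
#' rectangles.
#'
#' @param recording Tibble with `time_s` plus channel columns.
#' @param events Optional named list of `burst_events` tibbles (one per
#'   channel) to overlay.
#' @param window Optional `(start_s, end_s)` to crop the display.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, events = NULL, window = NULL) {
  long <- tidyr::pivot_longer(recording, -"time_s",
                              names_to = "channel", values_to = "amplitude")
  if (!is.null(window)) {
    long <- dplyr::filter(long, .data$time_s >= window[1],
                          .data$time_s <= window[2])
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "rectified amplitude (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- dplyr::bind_rows(purrr::imap(events, function(e, ch) {
      dplyr::mutate(as_tibble(e), channel = ch)
    }))
    if (!is.null(window)) {
      ev <- dplyr::filter(ev, .data$offset_s >= window[1],
                          .data$onset_s <= window[2])
    }
    p <- p + ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

# Shared heatmap scaffold for the per-ROI maps.
map_heatmap <- function(map, value_col, title, limits = NULL) {
  ggplot2::ggplot(map, ggplot2::aes(.data$col_c, .data$row_c,
                                    fill = .data[[value_col]])) +
    ggplot2::geom_tile(width = 25, height = 16) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(limits = limits) +
    ggplot2::labs(x = "medio-lateral (px)", y = "dorso-ventral (px)",
                  fill = value_col, title = title) +
    ggplot2::theme_minimal()
}

#' @describeIn normalize_index_map Heatmap of the normalized oscillation
#'   index over the 500-ROI grid.
#' @param object An `oscillation_map`.
#' @param ... Unused.
#' @export
autoplot.oscillation_map <- function(object, ...) {
  map_heatmap(object, "norm", "Oscillation index (normalized)", c(0, 1))
}

#' @describeIn phase_map Heatmap of per-ROI phase (locomotor-cycle units)
#'   over the 500-ROI grid.
#' @param object A `phase_map`.
#' @param ... Unused.
#' @export
autoplot.phase_map <- function(object, ...) {
  map_heatmap(object, "phase", "Phase (locomotor cycles)", c(0, 1))
}

#' @describeIn summarize_coordination Circular plot of per-preparation mean
#'   angles (points at radius `r`) with the grand mean; 0 degrees =
#'   synchrony, 180 degrees = alternation.
#' @param object A `circular_summary`.
#' @export
autoplot.circular_summary <- function(object, ...) {
  pp <- object$per_prep
  gm <- tibble(mean_deg = object$grand_mean_deg, r = object$grand_r)
  ggplot2::ggplot(pp, ggplot2::aes(.data$mean_deg, .data$r)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mean_deg, yend = 0),
                          alpha = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = gm, colour = "red", size = 3) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "mean angle (deg)", y = "vector length r") +
    ggplot2::theme_minimal()
}
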