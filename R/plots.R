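#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_col geom_vline labs theme_minimal facet_wrap
NULL

#' Plot a midpoint-aligned maturation average
#'
#' Mean normalized fluorescence per role against time relative to the
#' early-to-late transition midpoint, with SEM ribbons.
#'
#' @param object A `vt_aligned` from [align_and_average()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_aligned <- function(object, ...) {
  ggplot(object, aes(x = .data$rel_time_s, y = .data$mean,
                     colour = .data$role, fill = .data$role)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                alpha = 0.25, colour = NA, na.rm = TRUE) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "time relative to transition midpoint (s)",
         y = "normalized fluorescence (a.u.)",
         colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot per-cell vacuolar accumulation curves
#'
#' @param traces Tidy per-cell vacuole cargo traces (`structure`, `time_s`,
#'   `value`).
#' @param curve Optional population curve from [population_average()] to
#'   overlay (mean +/- SEM).
#' @return A ggplot.
#' @export
plot_delivery_curves <- function(traces, curve = NULL) {
  if (!"structure" %in% names(traces) && "cell" %in% names(traces)) {
    traces$structure <- traces$cell
  }
  p <- ggplot(traces, aes(x = .data$time_s / 60, y = .data$value,
                          group = .data$structure)) +
    geom_line(alpha = 0.35, colour = "grey40") +
    labs(x = "time after cargo release (min)",
         y = "vacuolar cargo fluorescence (a.u.)") +
    theme_minimal()
  if (!is.null(curve)) {
    p <- p +
      geom_ribbon(data = curve,
                  aes(x = .data$time_s / 60, ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  inherit.aes = FALSE, alpha = 0.3, fill = "firebrick") +
      geom_line(data = curve, aes(x = .data$time_s / 60, y = .data$mean),
                inherit.aes = FALSE, colour = "firebrick", linewidth = 1)
  }
  p
}

#' Plot a remaining-cargo series with its burst calls
#'
#' @param table A `vt_burst_table` from [detect_bursts()].
#' @return A ggplot.
#' @export
plot_burst_timeline <- function(table) {
  stopifnot(inherits(table, "vt_burst_table"))
  series <- tibble::tibble(
    time_s = c(table$t_start, table$t_end[nrow(table)]),
    value = c(table$remaining_before,
              attr(table, "final_remaining") %||%
                (table$remaining_before[nrow(table)] -
                   table$transferred[nrow(table)]))
  )
  bursts <- table[table$is_burst, ]
  ggplot(series, aes(x = .data$time_s / 60, y = .data$value)) +
    geom_line() +
    geom_point(data = bursts,
               aes(x = .data$t_end / 60,
                   y = .data$remaining_before - .data$transferred),
               colour = "firebrick", size = 2) +
    labs(x = "time (min)", y = "remaining PVE cargo (a.u.)",
         subtitle = "points mark intervals scored as kiss-and-run bursts") +
    theme_minimal()
}
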