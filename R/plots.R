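#' Heatmap of a ring-by-time count matrix
#'
#' Renders the normalized event-density matrix as the familiar
#' ring-by-time heatmap, innermost ring at the top, with an optional
#' vertical marker at the wounding or resealing time (the dotted guide
#' line of such heatmaps).
#'
#' @param object a `wound_count_matrix`.
#' @param marker_time time (s) of the vertical guide line; `NULL` for none.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wound_count_matrix <- function(object, marker_time = 0, ...) {
  df <- as_tibble(object)
  df$ring <- factor(df$ring, levels = rev(sort(unique(df$ring))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$ring,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = switch(attr(object, "normalization"),
      baseline_and_area = "events\n(norm.)",
      area_only = "events/\num^2",
      raw = "events")) +
    ggplot2::labs(x = "time after wounding (s)", y = "circle ROI") +
    ggplot2::theme_minimal()
  if (!is.null(marker_time)) {
    p <- p + ggplot2::geom_vline(xintercept = marker_time,
                                 linetype = "dotted", colour = "green4")
  }
  p
}

#' Resealing-curve plot
#'
#' @param object a `wound_resealing_curve`.
#' @param call optional [classify_resealing()] result to annotate.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wound_resealing_curve <- function(object, call = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$normalized_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time after wounding (s)",
                  y = "normalized dye intensity") +
    ggplot2::theme_minimal()
  if (!is.null(call)) {
    p <- p + ggplot2::labs(subtitle = paste("classification:", call$classification))
  }
  p
}

#' Nearest-neighbor series plot
#'
#' @param object a `wound_nn_series`.
#' @param reseal_time optional resealing-phase marker (s).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wound_nn_series <- function(object, reseal_time = 30, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$normalized_distance)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::labs(x = "time after wounding (s)",
                  y = "normalized NN distance",
                  subtitle = attr(object, "region_label")) +
    ggplot2::theme_minimal()
  if (!is.null(reseal_time)) {
    p <- p + ggplot2::geom_vline(xintercept = reseal_time,
                                 linetype = "dotted", colour = "green4")
  }
  p
}

#' Tether-trace plot with the extracted plateau window
#'
#' @param object a `wound_tether_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wound_tether_fit <- function(object, ...) {
  tr <- object$trace
  win <- tr[object$plateau_start:nrow(tr), , drop = FALSE]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$force_pN)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_line(data = win, colour = "red") +
    ggplot2::geom_hline(yintercept = object$plateau_pN, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "force (pN)",
                  subtitle = sprintf("peak %.1f pN, plateau %.1f pN",
                                     object$peak_pN, object$plateau_pN)) +
    ggplot2::theme_minimal()
}

#' Hole-enthalpy curve with the critical radius
#'
#' Plots `H(R)` over a radius range and marks the barrier at
#' `R_c = lambda / sigma`.
#'
#' @param params a [membrane_params()].
#' @param r_max largest radius to draw, m (default 3 R_c).
#' @param n number of curve points.
#' @return A ggplot object.
#' @export
plot_hole_enthalpy <- function(params = membrane_params(), r_max = NULL,
                               n = 400) {
  rc <- critical_radius(params)
  if (is.null(r_max)) r_max <- 3 * rc
  df <- hole_enthalpy(seq(0, r_max, length.out = n), params)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$R_m * 1e9,
                                   y = .data$enthalpy_J)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = rc * 1e9, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "hole radius (nm)", y = "enthalpy H (J)",
                  subtitle = sprintf("critical radius %.0f nm", rc * 1e9)) +
    ggplot2::theme_minimal()
}
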