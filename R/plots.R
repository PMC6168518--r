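#' Plot a fluctuation profile
#'
#' B-factor (default) or RMSF per residue, the standard flexibility
#' profile.
#'
#' @param object A `cadyn_fluct` from [rmsf()].
#' @param metric `"bfactor"` or `"rmsf"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cadyn_fluct <- function(object, metric = c("bfactor", "rmsf"),
                                 ...) {
  metric <- match.arg(metric)
  lab <- if (metric == "bfactor") "B-factor (Å²)" else "RMSF (Å)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_number,
                                       y = .data[[metric]])) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "residue", y = lab) +
    ggplot2::theme_minimal()
}

#' Heatmap of a cross-correlation matrix
#'
#' @param object A `cadyn_dccm`.
#' @param ... Unused.
#' @return A ggplot with a blue-white-red scale over `[-1, 1]`.
#' @export
autoplot.cadyn_dccm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "atom i", y = "atom j", fill = "C(i,j)") +
    ggplot2::theme_minimal()
}

#' Plot landmark time series
#'
#' @param series Tidy tibble from [landmark_timeseries()].
#' @return A ggplot, one facet per landmark (free y scales: distances and
#'   angles share the panel grid, not the axis).
#' @export
plot_landmarks <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_ps / 1000,
                                       y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time (ns)", y = "distance (Å) / angle (°)") +
    ggplot2::theme_minimal()
}

#' Plot a per-TM contact profile
#'
#' @param profile A `cadyn_contact_profile` from [aggregate_per_tm()].
#' @return A ggplot bar chart of contact-residue counts per TM helix.
#' @export
plot_contact_profile <- function(profile) {
  df <- profile$per_tm
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region,
                                   y = .data$n_residues)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contact residues") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
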