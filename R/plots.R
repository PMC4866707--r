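# ggplot2 visualizations for each result type. The secondary-structure
# color code follows the conventional timeline palette: pink alpha-helix,
# dark blue 3-10 helix, yellow beta, turquoise turn, white coil.

ss_palette <- c(H = "#f48fb1", G = "#1a237e", E = "#fdd835",
                T = "#4dd0e1", C = "#ffffff")

#' Plot a secondary-structure timeline
#'
#' Residues vertical (N-terminus at top), simulation time horizontal, one
#' tile per residue-frame colored by secondary-structure class.
#'
#' @param object An [ss_timeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ss_timeline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                       y = .data$residue_index,
                                       fill = .data$ss)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = ss_palette, name = "structure",
                               drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time [ns]", y = "residue") +
    ggplot2::theme_minimal()
}

#' Plot occupancy distance traces with state classification
#'
#' @param object A [classify_occupancy()] result.
#' @param ... Unused.
#' @return A ggplot: both anchor distances over frames, the hysteresis
#'   thresholds, and a state strip along the bottom.
#' @export
autoplot.occupancy_states <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("d_a", "d_b"),
                              names_to = "anchor", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$distance,
                                     color = .data$anchor)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = attr(object, "d_in"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "d_out"),
                        linetype = "dotted") +
    ggplot2::geom_rug(data = as_tibble(object),
                      ggplot2::aes(x = .data$frame, color = NULL),
                      sides = "b", alpha = 0.3) +
    ggplot2::scale_color_manual(values = c(d_a = "#1565c0",
                                           d_b = "#2e7d32"),
                                labels = c("anchor A", "anchor B")) +
    ggplot2::labs(x = "frame", y = "pocket distance [A]") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue energy decomposition
#'
#' Sequence horizontal, snapshots vertical, colored by the van der Waals
#' (default) or electrostatic contribution.
#'
#' @param object A [decomposition_matrix()] result.
#' @param component `"vdw"` or `"elec"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_decomposition <- function(object,
                                          component = c("vdw", "elec"),
                                          ...) {
  component <- match.arg(component)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_index,
                                       y = .data$time_ns,
                                       fill = .data[[component]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("%s [kcal/mol]",
                                                 component),
                                  direction = -1) +
    ggplot2::labs(x = "residue", y = "time [ns]") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D projection of the phase-space density
#'
#' @param density A [phase_density()].
#' @param axes Length-2 integer: axes to keep (1 = angle, 2 = d_a, 3 = d_b).
#' @param reference Optional tibble of reference points (columns `angle`,
#'   `d_a`, `d_b`), drawn over the density.
#' @return A ggplot.
#' @export
plot_phase_projection <- function(density, axes = c(2, 1),
                                  reference = NULL) {
  stopifnot(inherits(density, "phase_density"))
  axis_names <- c("angle", "d_a", "d_b")
  axis_labs <- c("helix angle [deg]", "distance A [A]", "distance B [A]")
  m <- project_density(density, sort(axes))
  e1 <- density$edges[[sort(axes)[1]]]
  e2 <- density$edges[[sort(axes)[2]]]
  grid <- expand.grid(
    v1 = (head(e1, -1) + tail(e1, -1)) / 2,
    v2 = (head(e2, -1) + tail(e2, -1)) / 2)
  grid$count <- as.vector(m)
  if (sort(axes)[1] != axes[1]) {
    names(grid)[1:2] <- c("v2", "v1")
  }
  p <- ggplot2::ggplot(grid[grid$count > 0, ],
                       ggplot2::aes(x = .data$v1, y = .data$v2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = axis_labs[axes[1]], y = axis_labs[axes[2]]) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- tibble(v1 = reference[[axis_names[axes[1]]]],
                  v2 = reference[[axis_names[axes[2]]]])
    p <- p + ggplot2::geom_point(data = ref, color = "red", size = 2)
  }
  p
}

#' Plot a per-residue helicity profile
#'
#' @param object A [helicity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.helicity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$p_helix)) +
    ggplot2::geom_col(fill = "#7b1fa2") +
    ggplot2::scale_x_continuous(breaks = object$position,
                                labels = object$aa) +
    ggplot2::labs(x = "sequence", y = "P(helical)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the helicity-activity regression
#'
#' Scatter of variants with the fitted line and prediction-interval band.
#'
#' @param object An [correlate_activity()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activity_fit <- function(object, ...) {
  d <- object$data
  d$.helicity <- d[[object$helicity_col]]
  d$.activity <- d[[object$activity_col]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.helicity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.pi_lower,
                                      ymax = .data$.pi_upper),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted),
                       color = "red", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$.activity)) +
    ggplot2::labs(x = "mean helicity [%]",
                  y = "fold activation",
                  subtitle = sprintf("r² = %.2f, %d%% prediction interval",
                                     glance(object)$r.squared,
                                     round(object$level * 100))) +
    ggplot2::theme_minimal()
}
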