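# ggplot2 views of tissues, field maps and trajectories, plus broom-style
# tidiers for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tissue outline plot
#'
#' @param object an [epi_tissue()].
#' @param ... unused.
#' @return a ggplot of the cell polygons.
#' @exportS3Method ggplot2::autoplot
autoplot.epi_tissue <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$cell)) +
    ggplot2::geom_polygon(fill = "grey90", colour = "grey30",
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.epi_tissue <- function(x, ...) {
  tibble::tibble(cell = x$cell, vertex = seq_len(x$n),
                 x = x$V[, 1], y = x$V[, 2],
                 boundary = x$bnd, junction = !is.na(x$junc))
}

#' @exportS3Method generics::glance
glance.epi_tissue <- function(x, ...) {
  A <- tissue_areas(x)
  tibble::tibble(n_cells = x$ncell, n_vertices = x$n,
                 n_junctions = sum(!is.na(x$junc)) %/% 2L,
                 mean_area = mean(A), sd_area = stats::sd(A))
}

#' Field-map heat map
#'
#' @param object an `epi_fieldmap`.
#' @param ... unused.
#' @return a ggplot raster of the map magnitude.
#' @exportS3Method ggplot2::autoplot
autoplot.epi_fieldmap <- function(object, ...) {
  df <- as_tibble(object)
  df$mag <- if ("magnitude" %in% names(df)) df$magnitude else df$value
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "transparent") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "|u|") +
    ggplot2::theme_minimal()
}

#' Micromanipulation trajectory summaries
#'
#' `tidy()` returns one row per cell with original centroid and
#' displacement; `glance()` one row with the headline numbers.
#'
#' @param x an `epi_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.epi_trajectory <- function(x, ...) {
  cp <- traj_cell_points(x)
  tibble::tibble(cell = seq_len(nrow(cp$points)),
                 x0 = cp$points[, 1], y0 = cp$points[, 2],
                 ux = cp$disp[, 1], uy = cp$disp[, 2],
                 displacement = sqrt(cp$disp[, 1]^2 + cp$disp[, 2]^2),
                 manipulated = seq_len(nrow(cp$points)) == x$cell)
}

#' @rdname tidy.epi_trajectory
#' @exportS3Method generics::glance
glance.epi_trajectory <- function(x, ...) {
  cp <- traj_cell_points(x)
  lat <- x$after$lattice
  tibble::tibble(
    n_cells = x$before$tissue$ncell,
    manipulated_cell = x$cell,
    cell_center_displacement = sqrt(sum(cp$disp[x$cell, ]^2)),
    max_substrate_displacement =
      max(sqrt(rowSums((lat$S - lat$S0)^2))),
    n_ruptures = sum(x$after$fa$ruptured),
    pipette_distance = x$protocol$distance
  )
}

#' Optogenetic trajectory summaries
#'
#' `tidy()` returns the L/L0 time series; `glance()` the endpoint metrics.
#'
#' @param x an `opto_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.opto_trajectory <- function(x, ...) x$L_series

#' @rdname tidy.opto_trajectory
#' @exportS3Method generics::glance
glance.opto_trajectory <- function(x, ...) {
  jm <- junction_metrics(x)
  tibble::tibble(L0 = x$L0, L_rel_end = jm$L_rel_end, dL = jm$dL,
                 peak_mean = jm$peak_mean,
                 peak_per_half_dL = jm$peak_per_half_dL,
                 destroyed = x$destroyed)
}

#' Relative junction length over time
#'
#' @param object an `opto_trajectory`.
#' @param ... unused.
#' @return a ggplot of L/L0 against time with the activation window shaded.
#' @exportS3Method ggplot2::autoplot
autoplot.opto_trajectory <- function(object, ...) {
  pr <- object$protocol
  ggplot2::ggplot(object$L_series,
                  ggplot2::aes(x = .data$time / 60, y = .data$L_rel)) +
    ggplot2::annotate("rect", xmin = pr$t_on / 60, xmax = pr$t_off / 60,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "L / L0") +
    ggplot2::theme_minimal()
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
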