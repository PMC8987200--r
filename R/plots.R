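#' Plot a lattice configuration
#'
#' Raster view of the label grid: medium black, substrate steel blue, wall
#' grey, cells coloured by id.
#'
#' @param object A `cpm_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpm_state
#' @export
autoplot.cpm_state <- function(object, ...) {
  labels <- object$labels
  W <- nrow(labels); H <- ncol(labels)
  df <- tibble::tibble(
    x = rep(seq_len(W) - 1L, times = H),
    z = rep(seq_len(H) - 1L, each = W),
    label = as.vector(labels))
  pal <- grDevices::hcl(h = seq(15, 375, length.out = 13)[-13], l = 65, c = 100)
  df$fill <- ifelse(df$label == CPM_WALL, "#555555",
             ifelse(df$label == CPM_SUBSTRATE, "#4682B4",
             ifelse(df$label == CPM_MEDIUM, "#000000",
                    pal[(df$label - 1L) %% length(pal) + 1L])))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (pixels, along substrate)",
                  y = "z (pixels, perpendicular)") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' `type = "counts"`: basal and suprabasal cell counts versus time;
#' `"energy"`: total energy versus time; `"area"`: mean cell area (with an
#' `A0` reference line) versus time.
#'
#' @param object A `cpm_trajectory`.
#' @param type One of `"counts"`, `"energy"`, `"area"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpm_trajectory
#' @export
autoplot.cpm_trajectory <- function(object, type = c("counts", "energy", "area"),
                                    ...) {
  type <- match.arg(type)
  if (type == "energy") {
    return(ggplot2::ggplot(object$stats, ggplot2::aes(.data$mcs, .data$energy)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "MCS", y = "total energy") +
             ggplot2::theme_minimal())
  }
  if (type == "area") {
    return(ggplot2::ggplot(object$reports,
                           ggplot2::aes(.data$mcs, .data$mean_area)) +
             ggplot2::geom_line() +
             ggplot2::geom_hline(yintercept = object$params$A0,
                                 linetype = "dashed") +
             ggplot2::labs(x = "MCS", y = "mean cell area (pixels)") +
             ggplot2::theme_minimal())
  }
  long <- tidyr::pivot_longer(
    object$reports[, c("mcs", "n_basal", "n_suprabasal")],
    cols = c("n_basal", "n_suprabasal"),
    names_to = "layer", values_to = "n")
  long$layer <- sub("^n_", "", long$layer)
  ggplot2::ggplot(long, ggplot2::aes(.data$mcs, .data$n,
                                     colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MCS", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phase-diagram tile plot of a sweep master table
#'
#' Tiles the (x, y) parameter plane with the majority classification label
#' per grid point (ties broken alphabetically).
#'
#' @param master A master tibble from [run_sweep()].
#' @param x,y Names of the two axis columns (default contractility versus
#'   substrate adhesion).
#' @return A ggplot.
#' @export
plot_phase_diagram <- function(master, x = "lambda_adh_cs", y = "lambda_cont") {
  stopifnot(is.data.frame(master), all(c(x, y, "label") %in% names(master)))
  agg <- master |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(x, y)))) |>
    dplyr::summarise(label = names(sort(table(.data$label),
                                        decreasing = TRUE))[1],
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(factor(.data[[x]]), factor(.data[[y]]),
                                    fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = x, y = y, fill = "structure") +
    ggplot2::theme_minimal()
}

#' Plot the analytic phase surface
#'
#' Tile plot of the rectangular-cell equilibrium aspect ratio (or any other
#' response column) over a parameter grid from [analytic_phase_surface()].
#'
#' @param surface Output of [analytic_phase_surface()].
#' @param response Column to map to fill.
#' @param x,y Axis columns.
#' @return A ggplot.
#' @export
plot_phase_surface <- function(surface, response = "aspect_ratio",
                               x = "lambda_adh_cs", y = "lambda_cont") {
  stopifnot(is.data.frame(surface), all(c(x, y, response) %in% names(surface)))
  ggplot2::ggplot(surface, ggplot2::aes(factor(.data[[x]]),
                                        factor(.data[[y]]),
                                        fill = .data[[response]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = x, y = y, fill = response) +
    ggplot2::theme_minimal()
}
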