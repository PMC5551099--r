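#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

surface_base <- function(x) {
  ggplot2::ggplot(tibble::as_tibble(x),
                  ggplot2::aes(x = .data$temperature_c,
                               y = .data$pco2_uatm)) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(italic(p) * CO[2] ~ "(µatm)")) +
    ggplot2::theme_minimal()
}

#' Plot a performance surface
#'
#' Filled raster of performance over the temperature-by-pCO2 grid.
#'
#' @param object A `perf_surface`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.perf_surface <- function(object, ...) {
  surface_base(object) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(
      name = if (is_scaled(object)) "Scaled\nperformance" else "Performance")
}

#' Plot a net production surface
#'
#' Diverging raster of production minus consumption, with the zero isocline
#' (tipping boundary) overlaid as a dashed line.
#'
#' @param object A `net_surface`.
#' @param isoclines Logical; overlay the zero isocline(s). Default `TRUE`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.net_surface <- function(object, isoclines = TRUE, ...) {
  p <- surface_base(object) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(name = "Net\nproduction",
                                  low = "#8c510a", mid = "#f5f5f5",
                                  high = "#01665e", midpoint = 0)
  if (isTRUE(isoclines)) {
    for (line in extract_isocline(object)) {
      p <- p + ggplot2::geom_path(
        data = line,
        ggplot2::aes(x = .data$temperature_c, y = .data$pco2_uatm),
        linetype = "dashed", linewidth = 0.6, colour = "black")
    }
  }
  p
}

#' Plot a phase map
#'
#' Two-state map (accumulating vs depleted) with attached isoclines
#' overlaid.
#'
#' @param object A `phase_map` from [classify_regions()] or
#'   [run_scenario()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.phase_map <- function(object, ...) {
  p <- surface_base(object) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$state)) +
    ggplot2::scale_fill_manual(name = "State",
                               values = c(accumulating = "#4daf4a",
                                          depleted = "#d8b365"))
  for (line in isoclines(object) %||% list()) {
    p <- p + ggplot2::geom_path(
      data = line,
      ggplot2::aes(x = .data$temperature_c, y = .data$pco2_uatm),
      linetype = "dashed", linewidth = 0.6, colour = "black")
  }
  p
}

#' Plot the four panels of a scenario result
#'
#' Producer, consumer, net, and realized secondary production surfaces. If
#' the patchwork package is installed the four panels are assembled into one
#' figure; otherwise a list of ggplot objects is returned.
#'
#' @param object A `scenario_result` from [run_scenario()].
#' @param ... Ignored.
#' @return A patchwork object, or a named list of ggplots.
#' @export
autoplot.scenario_result <- function(object, ...) {
  panels <- list(
    producer = autoplot(object$producer_surface) +
      ggplot2::ggtitle("(a) Producer performance"),
    consumer = autoplot(object$consumer_surface) +
      ggplot2::ggtitle("(b) Consumer performance"),
    net = autoplot(object$net_surface) +
      ggplot2::ggtitle("(c) Net production"),
    secondary = autoplot(object$secondary_surface) +
      ggplot2::ggtitle("(d) Realized secondary production"))
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(panels, ncol = 2)
  } else {
    panels
  }
}

#' Plot a curve fit against its observations
#'
#' @param object A `curve_fit` from [fit_curve()].
#' @param obs The observation data frame the curve was fitted to; optional
#'   but recommended.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.curve_fit <- function(object, obs = NULL, ...) {
  rng <- if (!is.null(obs)) range(obs$driver) else
    curve_support(object$curve)
  d <- seq(rng[1L], rng[2L], length.out = 400L)
  line <- tibble::tibble(driver = d,
                         performance = eval_curve(object$curve, d))
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$driver,
                                          y = .data$performance))
  if (!is.null(obs)) {
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(obs),
                                 alpha = 0.4, size = 1)
  }
  p + ggplot2::geom_line(colour = "#d73027", linewidth = 0.8) +
    ggplot2::labs(x = "Driver", y = "Performance",
                  title = sprintf("%s fit (RMSE %.3g)", object$family,
                                  object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a driver-performance curve
#'
#' Line plot of any curve family over its support (or a supplied range).
#'
#' @param curve A [tpc()], [saturating_response()], [threshold_response()],
#'   or [hormetic_response()].
#' @param from,to Optional driver range; defaults to the curve's support.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, from = NULL, to = NULL) {
  rng <- curve_support(curve)
  d <- seq(from %||% rng[1L], to %||% rng[2L], length.out = 400L)
  tbl <- tibble::tibble(driver = d, performance = eval_curve(curve, d))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$driver,
                                    y = .data$performance)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Driver", y = "Performance") +
    ggplot2::theme_minimal()
}
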