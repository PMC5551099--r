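#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a curve fit
#'
#' @param x A `curve_fit` from [fit_curve()].
#' @param ... Ignored.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @export
tidy.curve_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate))
}

#' Summarize a curve fit in one row
#'
#' @param x A `curve_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: `family`, `n`, `rmse`, `sse`, `converged`.
#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, rmse = x$rmse, sse = x$sse,
                 converged = x$convergence == 0L)
}

#' Tidy a perturbation result
#'
#' @param x A `perturbation_result` from [classify_perturbation()].
#' @param ... Ignored.
#' @return A one-row tibble with start, delta, class, net values, and the
#'   (dP, dG) arrow components.
#' @export
tidy.perturbation_result <- function(x, ...) {
  tibble::tibble(
    temperature_c = unname(x$start["temperature_c"]),
    pco2_uatm = unname(x$start["pco2_uatm"]),
    d_temperature = unname(x$delta["d_temperature"]),
    d_pco2 = unname(x$delta["d_pco2"]),
    class = x$class,
    net_start = x$net_start,
    net_end = x$net_end,
    dP = unname(x$vectors["dP"]),
    dG = unname(x$vectors["dG"]))
}

#' Tidy a scenario result into one long table
#'
#' Stacks the four result surfaces into a single tibble keyed by `panel`
#' (`producer`, `consumer`, `net`, `secondary`), with the phase `state`
#' attached to the net panel rows.
#'
#' @param x A `scenario_result` from [run_scenario()].
#' @param ... Ignored.
#' @return A tibble `panel, temperature_c, pco2_uatm, value, state`.
#' @export
tidy.scenario_result <- function(x, ...) {
  grab <- function(s, which_panel) {
    st <- if (which_panel == "net") x$phase_map$state else
      factor(rep(NA, nrow(s)), levels = levels(x$phase_map$state))
    tibble::tibble(panel = which_panel,
                   temperature_c = s$temperature_c,
                   pco2_uatm = s$pco2_uatm,
                   value = s$value,
                   state = st)
  }
  dplyr::bind_rows(grab(x$producer_surface, "producer"),
                   grab(x$consumer_surface, "consumer"),
                   grab(x$net_surface, "net"),
                   grab(x$secondary_surface, "secondary"))
}

#' Summarize a scenario result in one row
#'
#' @param x A `scenario_result`.
#' @param ... Ignored.
#' @return A one-row tibble: scenario name, grid size, fraction of
#'   accumulating cells, the net-surface minimum and its location, and the
#'   number of isocline polylines.
#' @export
glance.scenario_result <- function(x, ...) {
  net <- x$net_surface
  i <- which.min(net$value)
  tibble::tibble(
    name = x$spec$name,
    n_t = length(t_axis(net)),
    n_c = length(c_axis(net)),
    frac_accumulating = mean(x$phase_map$state == "accumulating"),
    net_min = net$value[i],
    net_min_temperature_c = net$temperature_c[i],
    net_min_pco2_uatm = net$pco2_uatm[i],
    n_isoclines = length(isoclines(x$phase_map)))
}
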