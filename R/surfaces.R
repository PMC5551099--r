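#' Temperature-by-pCO2 evaluation grid
#'
#' A rectangular lattice of driver levels on which performance surfaces are
#' evaluated. Axis values are cell-center driver levels, not bin edges.
#'
#' @param t_axis Strictly ascending temperatures (degrees C), length >= 2.
#' @param c_axis Strictly ascending pCO2 levels (micro-atm), length >= 2.
#' @return An object of class `driver_grid`.
#' @export
driver_grid <- function(t_axis, c_axis) {
  check_axis <- function(x, nm) {
    if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x))) {
      stop("`", nm, "` must be a finite numeric vector of length >= 2",
           call. = FALSE)
    }
    if (any(diff(x) <= 0)) {
      stop("`", nm, "` must be strictly increasing", call. = FALSE)
    }
    as.numeric(x)
  }
  structure(list(t_axis = check_axis(t_axis, "t_axis"),
                 c_axis = check_axis(c_axis, "c_axis")),
            class = "driver_grid")
}

#' Default evaluation grid
#'
#' Temperature from 10 to 32 degrees C in 0.2-degree steps (111 levels) by
#' pCO2 from 280 to 1500 micro-atm in 20 micro-atm steps (62 levels): fine
#' enough to resolve the preset curves, fast at desk scale. The pCO2 span
#' runs from the pre-industrial atmospheric level to a high-emission
#' end-of-century coastal value.
#'
#' @return A [driver_grid()].
#' @export
default_grid <- function() {
  driver_grid(seq(10, 32, by = 0.2), seq(280, 1500, by = 20))
}

#' @export
print.driver_grid <- function(x, ...) {
  cat(sprintf(
    "<driver_grid> %d temperatures [%g, %g] degC x %d pCO2 levels [%g, %g] uatm\n",
    length(x$t_axis), min(x$t_axis), max(x$t_axis),
    length(x$c_axis), min(x$c_axis), max(x$c_axis)))
  invisible(x)
}

## internal surface-tibble plumbing -----------------------------------------

new_surface_tbl <- function(values, grid, class, scaled = NULL, rho = NULL) {
  tbl <- tidyr::expand_grid(temperature_c = grid$t_axis,
                            pco2_uatm = grid$c_axis)
  tbl$value <- as.vector(t(values))
  attrs <- list(t_axis = grid$t_axis, c_axis = grid$c_axis)
  if (!is.null(scaled)) attrs$scaled <- scaled
  if (!is.null(rho)) attrs$rho <- rho
  out <- tibble::new_tibble(tbl, nrow = nrow(tbl),
                            class = c(class, "phasetip_surface"))
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  out
}

#' Axes and value matrix of a surface
#'
#' Surfaces are stored as long tibbles (`temperature_c`, `pco2_uatm`,
#' `value`, row-major with temperature varying slowest); these helpers
#' recover the grid axes and the temperature-by-pCO2 value matrix.
#'
#' @param x A surface (`perf_surface`, `net_surface`, or `phase_map`).
#' @return `t_axis()`/`c_axis()`: numeric axis vectors. `surface_matrix()`:
#'   a matrix with one row per temperature and one column per pCO2 level.
#' @export
t_axis <- function(x) attr(x, "t_axis")

#' @rdname t_axis
#' @export
c_axis <- function(x) attr(x, "c_axis")

#' @rdname t_axis
#' @export
surface_matrix <- function(x) {
  matrix(x$value, nrow = length(t_axis(x)), ncol = length(c_axis(x)),
         byrow = TRUE)
}

#' @rdname t_axis
#' @export
is_scaled <- function(x) isTRUE(attr(x, "scaled"))

surface_grid <- function(x) driver_grid(t_axis(x), c_axis(x))

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(t_axis(a), t_axis(b))) ||
      !isTRUE(all.equal(c_axis(a), c_axis(b)))) {
    stop("surfaces are defined on different grids", call. = FALSE)
  }
  invisible(TRUE)
}

check_scaled <- function(...) {
  for (s in list(...)) {
    if (!is_scaled(s)) {
      stop("expected a scaled surface; call scale_to_max() first",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## stress weight for the pCO2-temperature interaction ------------------------

#' pCO2 stress weight over a grid
#'
#' Linear ramp from 0 at the lowest modeled pCO2 to 1 at the highest,
#' clipped to `[0, 1]`. This is the weight by which an
#' [interaction_modulator()] shifts a thermal curve; it is isolated here so
#' an alternative ramp can be substituted.
#'
#' @param c pCO2 value(s), micro-atm.
#' @param grid A [driver_grid()] supplying the modeled pCO2 range.
#' @return Stress weight(s) in `[0, 1]`.
#' @export
stress_weight <- function(c, grid) {
  stopifnot(inherits(grid, "driver_grid"))
  rng <- range(grid$c_axis)
  w <- (c - rng[1]) / (rng[2] - rng[1])
  pmin(1, pmax(0, w))
}

#' Evaluate a species response at arbitrary driver values
#'
#' Multiplicative combination of the thermal performance curve and the pCO2
#' multiplier, with the interaction modulator (if any) applied at the
#' pCO2-dependent stress weight. Vectorized over paired `(t, c)` values.
#'
#' @param sp A [species_response()].
#' @param t Temperature(s), degrees C.
#' @param c pCO2 value(s), micro-atm (recycled against `t`).
#' @param grid A [driver_grid()]; required when `sp` has an interaction
#'   modulator (the stress weight is defined over the modeled pCO2 range).
#' @return Numeric performance values (unscaled).
#' @export
eval_species <- function(sp, t, c, grid = NULL) {
  stopifnot(inherits(sp, "species_response"))
  n <- max(length(t), length(c))
  t <- rep_len(t, n)
  c <- rep_len(c, n)
  co2_mult <- eval_co2_response(sp$co2, c)
  if (is.null(sp$interaction)) {
    return(eval_tpc(sp$thermal, t) * co2_mult)
  }
  if (is.null(grid)) {
    stop("`grid` is required to evaluate a species with an interaction ",
         "modulator (stress weight spans the modeled pCO2 range)",
         call. = FALSE)
  }
  w <- stress_weight(c, grid)
  vapply(seq_len(n), function(i) {
    eval_tpc(modulate_tpc(sp$thermal, sp$interaction, w[i]), t[i]) *
      co2_mult[i]
  }, numeric(1))
}

#' Performance surface of one species over a driver grid
#'
#' Evaluates a species' multiplicative temperature-by-pCO2 response at every
#' grid cell. When the species carries an interaction modulator, the thermal
#' curve used in each pCO2 column is shifted by the column's stress weight.
#'
#' @param sp A [species_response()].
#' @param grid A [driver_grid()].
#' @return A `perf_surface`: a long tibble (`temperature_c`, `pco2_uatm`,
#'   `value`) with grid attributes, unscaled.
#' @examples
#' sp <- species_response("producer",
#'   tpc(24, 5, 32, 6), saturating_response(600, 0.6))
#' s <- species_surface(sp, default_grid())
#' @export
species_surface <- function(sp, grid) {
  stopifnot(inherits(sp, "species_response"), inherits(grid, "driver_grid"))
  co2_mult <- eval_co2_response(sp$co2, grid$c_axis)
  if (is.null(sp$interaction)) {
    vals <- outer(eval_tpc(sp$thermal, grid$t_axis), co2_mult)
  } else {
    w <- stress_weight(grid$c_axis, grid)
    cols <- lapply(seq_along(grid$c_axis), function(j) {
      crv <- modulate_tpc(sp$thermal, sp$interaction, w[j])
      eval_tpc(crv, grid$t_axis) * co2_mult[j]
    })
    vals <- do.call(cbind, cols)
  }
  new_surface_tbl(vals, grid, class = "perf_surface", scaled = FALSE)
}

#' Scale a performance surface to its maximum
#'
#' Divides every cell by the grid maximum so values span 0-1 with the
#' maximum exactly 1. Idempotent. Each species is scaled to its own maximum
#' over the modeled grid, not to a joint maximum.
#'
#' @param s A `perf_surface`.
#' @return The scaled `perf_surface`.
#' @export
scale_to_max <- function(s) {
  stopifnot(inherits(s, "perf_surface"))
  m <- max(s$value)
  if (m <= 0) {
    stop("degenerate surface: all values are zero, cannot scale ",
         "(curve support does not intersect the grid)", call. = FALSE)
  }
  if (is_scaled(s)) return(s)
  s$value <- s$value / m
  attr(s, "scaled") <- TRUE
  s
}

#' Net production surface
#'
#' Production minus demand-weighted consumption, `p - rho * g`, element-wise
#' over a shared grid. `rho` is the ratio of maximum potential consumption
#' to maximum potential production; with both surfaces scaled to their own
#' maxima and `rho = 1` (the default) the two species are compared on equal
#' footing. Positive cells accumulate producer biomass ("green" state);
#' non-positive cells are production deficits ("barren" state).
#'
#' @param p Scaled producer `perf_surface`.
#' @param g Scaled consumer (grazer) `perf_surface`.
#' @param rho Consumption-to-production capacity ratio, > 0; default 1.
#' @return A `net_surface` tibble with `rho` attached as an attribute.
#' @export
net_production <- function(p, g, rho = 1) {
  stopifnot(inherits(p, "perf_surface"), inherits(g, "perf_surface"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single number > 0", call. = FALSE)
  }
  check_same_grid(p, g)
  check_scaled(p, g)
  out <- new_surface_tbl(surface_matrix(p) - rho * surface_matrix(g),
                         surface_grid(p), class = "net_surface", rho = rho)
  out
}

#' Realized secondary production
#'
#' The consumer realizes the smaller of its physiological capacity
#' (`rho * g`) and the available production (`p`, floored at zero), times a
#' trophic transfer `efficiency`:
#' `efficiency * pmin(rho * g, pmax(p, 0))`. Never negative — the consumer
#' starts from zero biomass, so an unfavorable balance cannot produce
#' negative secondary production.
#'
#' @inheritParams net_production
#' @param efficiency Trophic transfer efficiency in `(0, 1]`; default 1.
#' @return A `perf_surface` (unscaled values in `[0, rho]`).
#' @export
realized_secondary <- function(p, g, rho = 1, efficiency = 1) {
  stopifnot(inherits(p, "perf_surface"), inherits(g, "perf_surface"))
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single number > 0", call. = FALSE)
  }
  check_same_grid(p, g)
  check_scaled(p, g)
  vals <- efficiency * pmin(rho * surface_matrix(g),
                            pmax(surface_matrix(p), 0))
  new_surface_tbl(vals, surface_grid(p), class = "perf_surface",
                  scaled = FALSE)
}

#' Consumer limitation map
#'
#' Labels each grid cell by what limits the consumer there:
#' `resource_limited` where potential demand exceeds available production
#' (`rho * g > p`), `physiology_limited` otherwise (ties count as
#' physiology-limited).
#'
#' @inheritParams net_production
#' @return A tibble `temperature_c, pco2_uatm, limitation` where
#'   `limitation` is a factor with levels `resource_limited`,
#'   `physiology_limited`.
#' @export
limitation_map <- function(p, g, rho = 1) {
  stopifnot(inherits(p, "perf_surface"), inherits(g, "perf_surface"))
  check_same_grid(p, g)
  check_scaled(p, g)
  lab <- ifelse(rho * g$value > p$value, "resource_limited",
                "physiology_limited")
  tibble::tibble(
    temperature_c = p$temperature_c,
    pco2_uatm = p$pco2_uatm,
    limitation = factor(lab, levels = c("resource_limited",
                                        "physiology_limited"))
  )
}
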