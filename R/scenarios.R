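#' Scenario specification
#'
#' Bundles a producer, a consumer, an evaluation grid, the
#' consumption-to-production capacity ratio `rho`, and the trophic transfer
#' `efficiency` into a runnable scenario.
#'
#' @param producer Producer [species_response()].
#' @param consumer Consumer [species_response()].
#' @param grid A [driver_grid()]; default [default_grid()].
#' @param rho Consumption-to-production capacity ratio, > 0; default 1.
#' @param efficiency Trophic transfer efficiency in (0, 1]; default 1.
#' @param name Scenario identifier; default `"custom"`.
#' @return An object of class `scenario_spec`.
#' @seealso [build_preset()], [run_scenario()]
#' @export
scenario_spec <- function(producer, consumer, grid = default_grid(),
                          rho = 1, efficiency = 1, name = "custom") {
  stopifnot(inherits(producer, "species_response"),
            inherits(consumer, "species_response"),
            inherits(grid, "driver_grid"))
  if (producer$role != "producer") {
    stop("`producer` must have role \"producer\"", call. = FALSE)
  }
  if (consumer$role != "consumer") {
    stop("`consumer` must have role \"consumer\"", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single number > 0", call. = FALSE)
  }
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.character(name) || length(name) != 1L) {
    stop("`name` must be a single string", call. = FALSE)
  }
  structure(list(name = name, producer = producer, consumer = consumer,
                 grid = grid, rho = rho, efficiency = efficiency),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> \"%s\" (rho = %g, efficiency = %g)\n",
              x$name, x$rho, x$efficiency))
  print(x$grid)
  cat("producer: "); print(x$producer)
  cat("consumer: "); print(x$consumer)
  invisible(x)
}

# Frozen preset constants. The thermal optima (and the fig8 interaction
# shifts of 2 and 4 degrees C) define each scenario; all other parameters
# are repository constants chosen so each scenario's qualitative geometry
# holds on the default grid. Changing any value here is a breaking change.
.preset_co2_producer <- function() saturating_response(k_half = 800,
                                                       baseline = 0.2)
.preset_co2_consumer <- function() threshold_response(c_mid = 1200,
                                                      steepness = 0.012,
                                                      floor = 0.3)

.preset_table <- function() {
  pco2_p <- .preset_co2_producer()
  pco2_g <- .preset_co2_consumer()
  sp <- function(role, t_opt, ct_min, ct_max, sigma_rise, co2,
                 interaction = NULL) {
    species_response(role, tpc(t_opt, ct_min, ct_max, sigma_rise),
                     co2 = co2, interaction = interaction)
  }
  list(
    # warm-adapted producer, cool-adapted consumer
    fig4 = list(
      producer = sp("producer", 24, 5, 32, 8, pco2_p),
      consumer = sp("consumer", 20, 6, 26, 3.5, pco2_g)),
    # warm-adapted consumer, cool-adapted producer
    fig5 = list(
      producer = sp("producer", 20, 2, 30, 6, pco2_p),
      consumer = sp("consumer", 24, 6, 30, 4, pco2_g)),
    # matched optima, producer thermally broader
    fig6 = list(
      producer = sp("producer", 20, 2, 30, 7, pco2_p),
      consumer = sp("consumer", 20, 6, 25, 3, pco2_g)),
    # matched optima, consumer thermally broader
    fig7 = list(
      producer = sp("producer", 20, 6, 25, 3, pco2_p),
      consumer = sp("consumer", 20, 2, 30, 7, pco2_g)),
    # fig4 pair plus a pCO2-temperature interaction on the consumer:
    # at full pCO2 stress its optimum drops 2 degC and its foraging-stop
    # temperature (ct_max) drops 4 degC
    fig8 = list(
      producer = sp("producer", 24, 5, 32, 8, pco2_p),
      consumer = sp("consumer", 20, 6, 26, 3.5, pco2_g,
                    interaction = interaction_modulator(d_topt = 2,
                                                        d_ctmax = 4)))
  )
}

#' Named preset scenarios
#'
#' Five frozen producer-consumer scenarios spanning the canonical
#' configurations of thermal mismatch:
#'
#' * `fig4` — producer optimum 24 degC, consumer optimum 20 degC; producer
#'   benefits from pCO2, consumer is harmed. Deficit trough near the
#'   consumer optimum at low pCO2.
#' * `fig5` — consumer optimum (24 degC) above the producer's (20 degC);
#'   stable until a sharp warm-side decline.
#' * `fig6` — matched optima (20 degC), producer thermally broader; stable
#'   over a wide driver range.
#' * `fig7` — matched optima (20 degC), consumer thermally broader; stable
#'   only at high pCO2 where the producer does well and the consumer does
#'   not.
#' * `fig8` — as `fig4`, plus an interactive pCO2 effect on the consumer:
#'   at the highest modeled pCO2 its thermal optimum is 2 degC lower and
#'   its foraging-stop temperature 4 degC lower.
#'
#' Presets are immutable; every parameter is a frozen repository constant.
#'
#' @param name One of `"fig4"`, `"fig5"`, `"fig6"`, `"fig7"`, `"fig8"`.
#' @return A [scenario_spec()].
#' @examples
#' build_preset("fig4")$producer$thermal$t_opt  # 24
#' @export
build_preset <- function(name) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(tab))) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  pair <- tab[[name]]
  scenario_spec(pair$producer, pair$consumer, grid = default_grid(),
                rho = 1, efficiency = 1, name = name)
}

#' Run a scenario
#'
#' Deterministic pipeline: evaluate each species' surface, scale each to its
#' own grid maximum, form the net production surface, the realized secondary
#' production surface, and the phase map with extracted zero isoclines.
#'
#' @param spec A [scenario_spec()] (e.g. from [build_preset()]).
#' @return A `scenario_result` list: `spec`, `producer_surface`,
#'   `consumer_surface` (both scaled), `net_surface`, `secondary_surface`,
#'   and `phase_map` (with isoclines attached; see [isoclines()]).
#' @examples
#' res <- run_scenario(build_preset("fig4"))
#' dplyr::slice_min(res$net_surface, value, n = 1)
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  p <- scale_to_max(species_surface(spec$producer, spec$grid))
  g <- scale_to_max(species_surface(spec$consumer, spec$grid))
  net <- net_production(p, g, rho = spec$rho)
  sec <- realized_secondary(p, g, rho = spec$rho,
                            efficiency = spec$efficiency)
  pm <- classify_regions(net)
  attr(pm, "isoclines") <- extract_isocline(net)
  structure(list(spec = spec, producer_surface = p, consumer_surface = g,
                 net_surface = net, secondary_surface = sec,
                 phase_map = pm),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  pm <- x$phase_map
  cat(sprintf(
    "<scenario_result> \"%s\": %d x %d grid, %.1f%% accumulating, %d isocline(s)\n",
    x$spec$name, length(t_axis(pm)), length(c_axis(pm)),
    100 * mean(pm$state == "accumulating"), length(isoclines(pm))))
  invisible(x)
}
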