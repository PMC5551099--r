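#' Thermal performance curve
#'
#' Constructs a unimodal, typically left-skewed thermal performance curve
#' (TPC): performance rises along a Gaussian limb from the lower critical
#' temperature `ct_min` to a peak `p_max` at the thermal optimum `t_opt`,
#' then falls along a quadratic limb to zero at the upper critical
#' temperature `ct_max`. Performance is hard-zero at and beyond both
#' critical temperatures. The curve is left-skewed whenever the fall span
#' `ct_max - t_opt` is shorter than the rise scale `2 * sigma_rise`.
#'
#' The Gaussian limb does not itself reach zero at `ct_min`; performance is
#' clipped to zero there, so a small discontinuity at `ct_min` is accepted
#' by construction.
#'
#' @param t_opt Thermal optimum (degrees C), where performance peaks.
#' @param ct_min Lower critical temperature (degrees C); performance is 0 for
#'   temperatures at or below it.
#' @param ct_max Upper critical temperature (degrees C); performance is 0 for
#'   temperatures at or above it.
#' @param sigma_rise Breadth of the sub-optimal Gaussian rise (degrees C).
#' @param p_max Peak performance (dimensionless rate), default 1.
#' @return An object of class `tpc`.
#' @examples
#' crv <- tpc(t_opt = 24, ct_min = 5, ct_max = 32, sigma_rise = 6)
#' eval_tpc(crv, c(12, 24, 32))
#' @seealso [eval_tpc()], [thermal_breadth()], [modulate_tpc()]
#' @export
tpc <- function(t_opt, ct_min, ct_max, sigma_rise, p_max = 1) {
  for (nm in c("t_opt", "ct_min", "ct_max", "sigma_rise", "p_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (!(ct_min < t_opt && t_opt < ct_max)) {
    stop("invalid thermal curve: need ct_min < t_opt < ct_max (got ct_min = ",
         ct_min, ", t_opt = ", t_opt, ", ct_max = ", ct_max, ")",
         call. = FALSE)
  }
  if (sigma_rise <= 0) stop("`sigma_rise` must be > 0", call. = FALSE)
  if (p_max <= 0) stop("`p_max` must be > 0", call. = FALSE)
  structure(
    list(t_opt = t_opt, ct_min = ct_min, ct_max = ct_max,
         sigma_rise = sigma_rise, p_max = p_max),
    class = "tpc"
  )
}

#' @export
print.tpc <- function(x, ...) {
  cat(sprintf(
    "<tpc> t_opt = %g degC, ct_min = %g, ct_max = %g, sigma_rise = %g, p_max = %g\n",
    x$t_opt, x$ct_min, x$ct_max, x$sigma_rise, x$p_max))
  invisible(x)
}

#' Evaluate a thermal performance curve
#'
#' Closed form: `p_max * exp(-((t - t_opt) / (2 * sigma_rise))^2)` on the
#' rising limb (`ct_min < t <= t_opt`),
#' `p_max * (1 - ((t - t_opt) / (ct_max - t_opt))^2)` on the falling limb
#' (`t_opt < t < ct_max`), and 0 outside `(ct_min, ct_max)`.
#'
#' @param curve A [tpc()] object.
#' @param t Temperature(s), degrees C; must be finite.
#' @return Numeric vector of performance values in `[0, p_max]`.
#' @export
eval_tpc <- function(curve, t) {
  stopifnot(inherits(curve, "tpc"))
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stop("`t` must be finite numeric temperature(s)", call. = FALSE)
  }
  out <- numeric(length(t))
  rise <- t > curve$ct_min & t <= curve$t_opt
  fall <- t > curve$t_opt & t < curve$ct_max
  out[rise] <- curve$p_max *
    exp(-((t[rise] - curve$t_opt) / (2 * curve$sigma_rise))^2)
  out[fall] <- curve$p_max *
    (1 - ((t[fall] - curve$t_opt) / (curve$ct_max - curve$t_opt))^2)
  out
}

#' Saturating pCO2 response (resource benefit)
#'
#' Michaelis-Menten-with-baseline multiplier describing a producer that
#' benefits from added dissolved inorganic carbon: the multiplier rises from
#' `baseline` at zero pCO2 toward an asymptote of 1.
#'
#' @param k_half Half-saturation pCO2 (micro-atm); the multiplier is midway
#'   between `baseline` and 1 at this level.
#' @param baseline Multiplier at zero pCO2, in `[0, 1)`.
#' @return An object of class `co2_saturating`.
#' @examples
#' eval_co2_response(saturating_response(600, 0.6), 600)  # 0.8
#' @export
saturating_response <- function(k_half, baseline = 0) {
  if (!is.numeric(k_half) || length(k_half) != 1L || !is.finite(k_half) ||
      k_half <= 0) {
    stop("`k_half` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(baseline) || length(baseline) != 1L ||
      !is.finite(baseline) || baseline < 0 || baseline >= 1) {
    stop("`baseline` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(k_half = k_half, baseline = baseline),
            class = "co2_saturating")
}

#' Threshold-decline pCO2 response (stressor)
#'
#' Descending logistic multiplier describing a consumer harmed by elevated
#' pCO2 (lowered pH): near 1 at low pCO2, declining through an inflection at
#' `c_mid` toward an asymptotic `floor`.
#'
#' @param c_mid Inflection pCO2 (micro-atm).
#' @param steepness Decline rate (per micro-atm), > 0.
#' @param floor Asymptotic minimum multiplier, in `[0, 1)`.
#' @return An object of class `co2_threshold`.
#' @examples
#' eval_co2_response(threshold_response(900, 0.01, 0.3), 900)  # 0.65
#' @export
threshold_response <- function(c_mid, steepness, floor = 0) {
  if (!is.numeric(c_mid) || length(c_mid) != 1L || !is.finite(c_mid) ||
      c_mid <= 0) {
    stop("`c_mid` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(steepness) || length(steepness) != 1L ||
      !is.finite(steepness) || steepness <= 0) {
    stop("`steepness` must be > 0", call. = FALSE)
  }
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor < 0 || floor >= 1) {
    stop("`floor` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(c_mid = c_mid, steepness = steepness, floor = floor),
            class = "co2_threshold")
}

#' Evaluate a pCO2 response multiplier
#'
#' Dispatches on the response family. `NULL` denotes "no pCO2 response" and
#' evaluates to 1 everywhere. Saturating:
#' `baseline + (1 - baseline) * c / (k_half + c)`. Threshold decline:
#' `floor + (1 - floor) / (1 + exp(steepness * (c - c_mid)))`.
#'
#' @param resp A [saturating_response()], [threshold_response()], or `NULL`.
#' @param c pCO2 value(s), micro-atm; must be non-negative and finite.
#' @return Numeric vector of dimensionless multipliers.
#' @export
eval_co2_response <- function(resp, c) {
  if (!is.numeric(c) || length(c) == 0L || any(!is.finite(c)) || any(c < 0)) {
    stop("`c` must be finite non-negative pCO2 value(s)", call. = FALSE)
  }
  if (is.null(resp)) return(rep(1, length(c)))
  UseMethod("eval_co2_response")
}

#' @export
eval_co2_response.co2_saturating <- function(resp, c) {
  resp$baseline + (1 - resp$baseline) * c / (resp$k_half + c)
}

#' @export
eval_co2_response.co2_threshold <- function(resp, c) {
  resp$floor + (1 - resp$floor) /
    (1 + exp(resp$steepness * (c - resp$c_mid)))
}

#' @export
eval_co2_response.default <- function(resp, c) {
  stop("unknown pCO2 response family: ", paste(class(resp), collapse = "/"),
       call. = FALSE)
}

#' Hormetic dose response
#'
#' Low-dose stimulation with high-dose decline:
#' `(1 + alpha * dose) * exp(-(dose / lam)^kappa)`. The response is exactly 1
#' at zero dose; with `alpha > 0` it exceeds 1 at small doses (hormesis);
#' with `alpha = 0` it is a monotone toxin decline.
#'
#' @param alpha Low-dose stimulation coefficient (per dose unit), >= 0.
#' @param lam Decline scale (dose units), > 0.
#' @param kappa Decline shape (dimensionless), >= 1.
#' @return An object of class `hormetic`.
#' @examples
#' h <- hormetic_response(alpha = 2, lam = 5, kappa = 2)
#' eval_hormetic(h, c(0, 0.5, 20))
#' @export
hormetic_response <- function(alpha, lam, kappa = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stop("`alpha` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be > 0", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 1) {
    stop("`kappa` must be >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha, lam = lam, kappa = kappa),
            class = "hormetic")
}

#' Evaluate a hormetic dose response
#'
#' @param h A [hormetic_response()] object.
#' @param dose Dose value(s), >= 0.
#' @return Numeric vector of performance multipliers.
#' @export
eval_hormetic <- function(h, dose) {
  stopifnot(inherits(h, "hormetic"))
  if (!is.numeric(dose) || length(dose) == 0L || any(!is.finite(dose)) ||
      any(dose < 0)) {
    stop("`dose` must be finite non-negative value(s)", call. = FALSE)
  }
  (1 + h$alpha * dose) * exp(-(dose / h$lam)^h$kappa)
}

#' Thermal performance breadth
#'
#' Width (degrees C) of the temperature interval over which performance is at
#' least a fraction `q` of the peak. Each boundary is located by root-finding
#' on its limb of the curve; when the rising limb is still above `q * p_max`
#' at `ct_min` the interval is clipped there (performance drops to zero
#' discontinuously at `ct_min`).
#'
#' @param curve A [tpc()] object.
#' @param q Fraction of peak performance, in (0, 1).
#' @return Breadth in degrees C.
#' @export
thermal_breadth <- function(curve, q) {
  stopifnot(inherits(curve, "tpc"))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("`q` must be a single number in (0, 1)", call. = FALSE)
  }
  target <- q * curve$p_max
  f <- function(t) eval_tpc(curve, t) - target
  eps <- 1e-10 * max(1, abs(curve$ct_min))
  lo_edge <- curve$ct_min + eps
  lower <- if (f(lo_edge) >= 0) {
    curve$ct_min
  } else {
    stats::uniroot(f, c(lo_edge, curve$t_opt), tol = 1e-12)$root
  }
  upper <- stats::uniroot(f, c(curve$t_opt, curve$ct_max - eps),
                          tol = 1e-12)$root
  upper - lower
}

#' Driver-interaction modulator
#'
#' Describes an interactive effect of a co-driver (pCO2) on a species'
#' thermal curve: at full co-driver stress the thermal optimum shifts down by
#' `d_topt` and the upper critical temperature (for a consumer, the
#' temperature at which foraging stops, identified here with `ct_max`) shifts
#' down by `d_ctmax`. Intermediate stress interpolates linearly; zero stress
#' leaves the curve unchanged.
#'
#' @param d_topt Downward shift of `t_opt` at full stress (degrees C), >= 0.
#' @param d_ctmax Downward shift of `ct_max` at full stress (degrees C), >= 0.
#' @return An object of class `interaction_modulator`.
#' @export
interaction_modulator <- function(d_topt, d_ctmax) {
  for (nm in c("d_topt", "d_ctmax")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single number >= 0", call. = FALSE)
    }
  }
  structure(list(d_topt = d_topt, d_ctmax = d_ctmax),
            class = "interaction_modulator")
}

#' Shift a thermal curve under co-driver stress
#'
#' Returns a copy of `curve` with `t_opt` lowered by
#' `stress_weight * d_topt` and `ct_max` lowered by
#' `stress_weight * d_ctmax`. Errors if the shifted curve violates
#' `ct_min < t_opt < ct_max`.
#'
#' @param curve A [tpc()] object.
#' @param mod An [interaction_modulator()].
#' @param stress_weight Co-driver stress weight in `[0, 1]` (0 = no stress,
#'   1 = full stress).
#' @return A shifted [tpc()] object.
#' @export
modulate_tpc <- function(curve, mod, stress_weight) {
  stopifnot(inherits(curve, "tpc"), inherits(mod, "interaction_modulator"))
  if (!is.numeric(stress_weight) || length(stress_weight) != 1L ||
      !is.finite(stress_weight) || stress_weight < 0 || stress_weight > 1) {
    stop("`stress_weight` must be a single number in [0, 1]", call. = FALSE)
  }
  t_opt2 <- curve$t_opt - stress_weight * mod$d_topt
  ct_max2 <- curve$ct_max - stress_weight * mod$d_ctmax
  if (!(curve$ct_min < t_opt2 && t_opt2 < ct_max2)) {
    stop("inconsistent modulator: shifted curve violates ",
         "ct_min < t_opt < ct_max (t_opt' = ", t_opt2,
         ", ct_max' = ", ct_max2, ")", call. = FALSE)
  }
  tpc(t_opt = t_opt2, ct_min = curve$ct_min, ct_max = ct_max2,
      sigma_rise = curve$sigma_rise, p_max = curve$p_max)
}

#' Species response to temperature and pCO2
#'
#' Bundles a species' trophic role with its thermal performance curve, an
#' optional pCO2 response multiplier, and an optional temperature-by-pCO2
#' interaction modulator. The joint response to the two drivers is
#' multiplicative: thermal performance times the pCO2 multiplier, the null
#' expectation for independent stressors.
#'
#' @param role `"producer"` or `"consumer"`.
#' @param thermal A [tpc()] object.
#' @param co2 A [saturating_response()], [threshold_response()], or `NULL`
#'   (no pCO2 sensitivity).
#' @param interaction An [interaction_modulator()] or `NULL`. When set, the
#'   thermal curve is shifted by the pCO2-dependent stress weight before
#'   evaluation (see [species_surface()]).
#' @return An object of class `species_response`.
#' @export
species_response <- function(role = c("producer", "consumer"), thermal,
                             co2 = NULL, interaction = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(thermal, "tpc"))
  if (!is.null(co2) &&
      !inherits(co2, c("co2_saturating", "co2_threshold"))) {
    stop("`co2` must be a saturating_response(), threshold_response(), ",
         "or NULL", call. = FALSE)
  }
  if (!is.null(interaction) &&
      !inherits(interaction, "interaction_modulator")) {
    stop("`interaction` must be an interaction_modulator() or NULL",
         call. = FALSE)
  }
  structure(list(role = role, thermal = thermal, co2 = co2,
                 interaction = interaction),
            class = "species_response")
}

#' @export
print.species_response <- function(x, ...) {
  cat(sprintf("<species_response> role = %s\n", x$role))
  print(x$thermal)
  if (is.null(x$co2)) {
    cat("  pCO2 response: none\n")
  } else {
    cat(sprintf("  pCO2 response: %s (%s)\n", class(x$co2)[1],
                paste(sprintf("%s = %g", names(unclass(x$co2)),
                              unlist(unclass(x$co2))), collapse = ", ")))
  }
  if (!is.null(x$interaction)) {
    cat(sprintf("  interaction: d_topt = %g, d_ctmax = %g\n",
                x$interaction$d_topt, x$interaction$d_ctmax))
  }
  invisible(x)
}
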