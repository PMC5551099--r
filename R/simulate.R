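#' Simulate noisy performance observations from a curve
#'
#' Draws driver values uniformly over the curve's support and adds Gaussian
#' observation noise, truncating negative observations at zero (performance
#' rates cannot be negative). Supports parameter-recovery experiments for
#' every curve family.
#'
#' Sampling supports: a [tpc()] is sampled on `[ct_min, ct_max]`; a
#' [saturating_response()] on `[0, 4 * k_half]`; a [threshold_response()] on
#' `[0, 2 * c_mid]`; a [hormetic_response()] on `[0, 3 * lam]` — in each
#' case wide enough that both limbs of the response are represented.
#'
#' @param curve A [tpc()], [saturating_response()], [threshold_response()],
#'   or [hormetic_response()].
#' @param n Number of observations, >= 1.
#' @param noise_sd Standard deviation of additive Gaussian noise, >= 0.
#' @param seed Integer seed; the same seed always reproduces the same set.
#' @return An `observation_set`: a tibble `driver, performance` with the
#'   generating curve, `noise_sd`, and `seed` attached as attributes.
#' @examples
#' obs <- simulate_observations(tpc(24, 5, 32, 6), n = 50,
#'                              noise_sd = 0.02, seed = 1)
#' @export
simulate_observations <- function(curve, n, noise_sd, seed) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  support <- curve_support(curve)
  out <- withr::with_seed(as.integer(seed), {
    d <- stats::runif(n, support[1L], support[2L])
    y_true <- eval_curve(curve, d)
    y <- pmax(0, y_true + stats::rnorm(n, sd = noise_sd))
    tibble::tibble(driver = d, performance = y)
  })
  out <- tibble::new_tibble(out, nrow = n,
                            class = "observation_set")
  attr(out, "curve") <- curve
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- as.integer(seed)
  out
}

curve_support <- function(curve) {
  if (inherits(curve, "tpc")) {
    c(curve$ct_min, curve$ct_max)
  } else if (inherits(curve, "co2_saturating")) {
    c(0, 4 * curve$k_half)
  } else if (inherits(curve, "co2_threshold")) {
    c(0, 2 * curve$c_mid)
  } else if (inherits(curve, "hormetic")) {
    c(0, 3 * curve$lam)
  } else {
    stop("unsupported curve object of class ",
         paste(class(curve), collapse = "/"), call. = FALSE)
  }
}

eval_curve <- function(curve, d) {
  if (inherits(curve, "tpc")) {
    eval_tpc(curve, d)
  } else if (inherits(curve, c("co2_saturating", "co2_threshold"))) {
    eval_co2_response(curve, d)
  } else if (inherits(curve, "hormetic")) {
    eval_hormetic(curve, d)
  } else {
    stop("unsupported curve object of class ",
         paste(class(curve), collapse = "/"), call. = FALSE)
  }
}
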