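#' Fit a driver-performance curve to observations
#'
#' Nonlinear least squares on observed (driver, performance) pairs for one
#' of the four curve families. Parameters are optimized on transformed
#' scales that enforce each family's invariants (e.g. `ct_min < t_opt <
#' ct_max`, positive scales, multipliers in `[0, 1)`), using derivative-free
#' Nelder-Mead minimization of the residual sum of squares from 8
#' deterministic starting points spread over the observation range; the best
#' start is polished by a second optimizer round. The thermal family is
#' piecewise, so its critical temperatures have almost-everywhere-zero
#' derivatives — the reason a derivative-free search is used rather than a
#' gradient-based one.
#'
#' @param obs A data frame with numeric columns `driver` and `performance`
#'   (e.g. an `observation_set` from [simulate_observations()]). At least
#'   `5 * k` rows are required, where `k` is the number of free parameters
#'   of the family.
#' @param family One of `"tpc"` (5 parameters), `"saturating"` (2),
#'   `"threshold"` (3), `"hormetic"` (3).
#' @return A `curve_fit`: list with the fitted `curve` object, named
#'   `estimate` vector, `rmse`, `sse`, `n`, `family`, and `convergence`
#'   (the optimizer code of the winning start; 0 means converged).
#'   [tidy()] returns the parameter table, [glance()] the fit summary.
#' @examples
#' obs <- simulate_observations(tpc(24, 5, 32, 6), n = 100,
#'                              noise_sd = 0.02, seed = 1)
#' fit <- fit_curve(obs, "tpc")
#' tidy(fit)
#' glance(fit)
#' @export
fit_curve <- function(obs, family = c("tpc", "saturating", "threshold",
                                      "hormetic")) {
  family <- match.arg(family)
  if (!is.data.frame(obs) || !all(c("driver", "performance") %in%
                                  names(obs))) {
    stop("`obs` must be a data frame with columns `driver` and ",
         "`performance`", call. = FALSE)
  }
  d <- as.numeric(obs$driver)
  y <- as.numeric(obs$performance)
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  fam <- .fit_family(family)
  if (length(d) < 5L * fam$k) {
    stop("need at least ", 5L * fam$k, " observations to fit the ",
         family, " family (", fam$k, " free parameters); got ", length(d),
         call. = FALSE)
  }
  sse_fn <- function(theta) {
    crv <- tryCatch(fam$build(theta), error = function(e) NULL)
    if (is.null(crv)) return(1e10)
    r <- y - eval_curve(crv, d)
    s <- sum(r^2)
    if (!is.finite(s)) 1e10 else s
  }
  starts <- fam$starts(d, y)
  best <- NULL
  for (theta0 in starts) {
    res <- tryCatch(
      stats::optim(theta0, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value < 1e10 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("curve fit did not converge from any of ", length(starts),
         " starts (family = ", family, ", n = ", length(d), ")",
         call. = FALSE)
  }
  # polish the winning start
  polish <- tryCatch(
    stats::optim(best$par, sse_fn, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) &&
      polish$value <= best$value) {
    best <- polish
  }
  crv <- fam$build(best$par)
  est <- unlist(unclass(crv))
  structure(
    list(family = family, curve = crv, estimate = est,
         sse = best$value, rmse = sqrt(best$value / length(d)),
         n = length(d), convergence = best$convergence,
         n_starts = length(starts)),
    class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> family = %s, n = %d, RMSE = %.4g\n",
              x$family, x$n, x$rmse))
  print(round(x$estimate, 4))
  invisible(x)
}

# Transform-and-start definitions per family. `build` maps the unconstrained
# optimizer vector to a valid curve object; `starts` returns 8 deterministic
# initial vectors derived from the data.
.fit_family <- function(family) {
  clamp01 <- function(x) pmin(1 - 1e-6, pmax(1e-6, x))
  switch(
    family,
    tpc = list(
      k = 5L,
      build = function(th) {
        tpc(t_opt = th[1L],
            ct_min = th[1L] - exp(th[2L]),
            ct_max = th[1L] + exp(th[3L]),
            sigma_rise = exp(th[4L]),
            p_max = exp(th[5L]))
      },
      starts = function(d, y) {
        rng <- range(d)
        peak <- d[which.max(y)]
        cand <- unique(c(peak, stats::quantile(d, seq(0.2, 0.8, by = 0.1),
                                               names = FALSE)))[1:8]
        cand <- cand[!is.na(cand)]
        lapply(cand, function(t0) {
          c(t0,
            log(max(t0 - rng[1L], 0.5)),
            log(max(rng[2L] - t0, 0.5)),
            log(diff(rng) / 4),
            log(max(max(y), 1e-3)))
        })
      }),
    saturating = list(
      k = 2L,
      build = function(th) {
        saturating_response(k_half = exp(th[1L]),
                            baseline = stats::plogis(th[2L]))
      },
      starts = function(d, y) {
        ks <- stats::quantile(d[d > 0], seq(0.1, 0.9, length.out = 8),
                              names = FALSE)
        b0 <- clamp01(min(pmax(y, 0)))
        lapply(ks, function(k) c(log(k), stats::qlogis(b0)))
      }),
    threshold = list(
      k = 3L,
      build = function(th) {
        threshold_response(c_mid = exp(th[1L]),
                           steepness = exp(th[2L]),
                           floor = stats::plogis(th[3L]))
      },
      starts = function(d, y) {
        cs <- stats::quantile(d[d > 0], seq(0.1, 0.9, length.out = 8),
                              names = FALSE)
        f0 <- clamp01(min(pmax(y, 0)))
        lapply(cs, function(cm) {
          c(log(cm), log(4 / max(diff(range(d)), 1e-6)),
            stats::qlogis(f0))
        })
      }),
    hormetic = list(
      k = 3L,
      build = function(th) {
        hormetic_response(alpha = exp(th[1L]), lam = exp(th[2L]),
                          kappa = 1 + exp(th[3L]))
      },
      starts = function(d, y) {
        lams <- stats::quantile(d[d > 0], seq(0.2, 0.9, length.out = 4),
                                names = FALSE)
        alphas <- c(1e-6, 1)
        out <- list()
        for (a in alphas) for (l in lams) {
          out[[length(out) + 1L]] <- c(log(a), log(l), log(1e-6))
        }
        out
      })
  )
}
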