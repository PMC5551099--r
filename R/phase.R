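#' Classify community state over a net surface
#'
#' Labels each cell `accumulating` where net production is strictly
#' positive (producer biomass builds up; "green" state) and `depleted`
#' otherwise (consumption holds producer biomass at or near zero; "barren"
#' state). Cells with net exactly zero are classed as depleted: the boundary
#' belongs to the barren region.
#'
#' @param net A `net_surface` from [net_production()].
#' @return A `phase_map`: a long tibble `temperature_c, pco2_uatm, value,
#'   state` where `value` is the net production and `state` is a factor
#'   with levels `accumulating`, `depleted`. Isocline polylines can be
#'   attached by [run_scenario()] and retrieved with [isoclines()].
#' @export
classify_regions <- function(net) {
  stopifnot(inherits(net, "net_surface"))
  out <- tibble::new_tibble(
    list(temperature_c = net$temperature_c,
         pco2_uatm = net$pco2_uatm,
         value = net$value,
         state = factor(ifelse(net$value > 0, "accumulating", "depleted"),
                        levels = c("accumulating", "depleted"))),
    nrow = nrow(net), class = c("phase_map", "phasetip_surface"))
  attr(out, "t_axis") <- t_axis(net)
  attr(out, "c_axis") <- c_axis(net)
  attr(out, "rho") <- attr(net, "rho")
  out
}

#' Isocline polylines attached to a phase map
#'
#' @param x A `phase_map`.
#' @return A list of polyline tibbles (`temperature_c`, `pco2_uatm`), or
#'   `NULL` if none were attached.
#' @export
isoclines <- function(x) attr(x, "isoclines")

#' Extract the zero isocline of a net surface
#'
#' Traces the tipping boundary where production equals consumption: the
#' zero-level contour of the net surface, computed by marching squares with
#' linear interpolation along grid-cell edges. Saddle cells (two opposite
#' positive corners) are disambiguated by the sign of the bilinear
#' interpolant at the cell center. Vertices therefore satisfy
#' `|interpolated net| <= 1e-9` (exactly zero up to floating-point error).
#'
#' A corner with net exactly 0 is treated as lying on the depleted side,
#' consistent with [classify_regions()].
#'
#' @param net A `net_surface`.
#' @return A list of polyline tibbles (`temperature_c`, `pco2_uatm`), open
#'   or closed; empty list if the net surface does not change sign.
#' @export
extract_isocline <- function(net) {
  stopifnot(inherits(net, "net_surface"))
  z <- surface_matrix(net)
  tv <- t_axis(net)
  cv <- c_axis(net)
  nt <- length(tv)
  nc <- length(cv)
  pos <- z > 0

  # Edge ids: horizontal ("H", i, j) spans t[i]..t[i+1] at c[j];
  # vertical ("V", i, j) spans c[j]..c[j+1] at t[i].
  edge_id <- function(type, i, j) paste0(type, i, "_", j)
  crossing_point <- function(type, i, j) {
    if (type == "H") {
      a <- z[i, j]; b <- z[i + 1L, j]
      frac <- a / (a - b)
      c(tv[i] + frac * (tv[i + 1L] - tv[i]), cv[j])
    } else {
      a <- z[i, j]; b <- z[i, j + 1L]
      frac <- a / (a - b)
      c(tv[i], cv[j] + frac * (cv[j + 1L] - cv[j]))
    }
  }

  seg_a <- character(0)
  seg_b <- character(0)
  add_seg <- function(e1, e2) {
    seg_a[[length(seg_a) + 1L]] <<- e1
    seg_b[[length(seg_b) + 1L]] <<- e2
  }

  for (j in seq_len(nc - 1L)) {
    for (i in seq_len(nt - 1L)) {
      a <- pos[i, j]; b <- pos[i + 1L, j]
      d <- pos[i, j + 1L]; cc <- pos[i + 1L, j + 1L]
      ncross <- (a != b) + (b != cc) + (d != cc) + (a != d)
      if (ncross == 0L) next
      eS <- edge_id("H", i, j)          # between a and b
      eN <- edge_id("H", i, j + 1L)     # between d and cc
      eW <- edge_id("V", i, j)          # between a and d
      eE <- edge_id("V", i + 1L, j)     # between b and cc
      if (ncross == 2L) {
        crossed <- c(eS, eE, eN, eW)[c(a != b, b != cc, d != cc, a != d)]
        add_seg(crossed[1L], crossed[2L])
      } else {
        # saddle: opposite corners share sign; split by cell-center sign
        center_pos <- (z[i, j] + z[i + 1L, j] + z[i, j + 1L] +
                         z[i + 1L, j + 1L]) / 4 > 0
        if (center_pos == a) {
          # corners b and d are each cut off
          add_seg(eS, eE)
          add_seg(eW, eN)
        } else {
          # corners a and cc are each cut off
          add_seg(eS, eW)
          add_seg(eE, eN)
        }
      }
    }
  }
  if (length(seg_a) == 0L) return(list())

  nodes <- unique(c(seg_a, seg_b))
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (k in seq_along(seg_a)) {
    adj[[seg_a[k]]] <- c(adj[[seg_a[k]]], seg_b[k])
    adj[[seg_b[k]]] <- c(adj[[seg_b[k]]], seg_a[k])
  }
  visited_edge <- new.env(parent = emptyenv())
  edge_key <- function(e1, e2) paste(sort(c(e1, e2)), collapse = "|")
  walk <- function(start) {
    path <- start
    current <- start
    prev <- NA_character_
    repeat {
      nxt <- adj[[current]]
      nxt <- nxt[vapply(nxt, function(n) {
        is.null(visited_edge[[edge_key(current, n)]])
      }, logical(1))]
      if (length(nxt) == 0L) break
      n <- nxt[1L]
      visited_edge[[edge_key(current, n)]] <- TRUE
      path <- c(path, n)
      prev <- current
      current <- n
    }
    path
  }
  degrees <- lengths(adj)
  polylines <- list()
  for (start in nodes[degrees == 1L]) {
    if (length(adj[[start]]) == 1L &&
        is.null(visited_edge[[edge_key(start, adj[[start]][1L])]])) {
      polylines[[length(polylines) + 1L]] <- walk(start)
    }
  }
  for (start in nodes) {  # remaining closed loops
    unvisited <- adj[[start]][vapply(adj[[start]], function(n) {
      is.null(visited_edge[[edge_key(start, n)]])
    }, logical(1))]
    if (length(unvisited) > 0L) {
      polylines[[length(polylines) + 1L]] <- walk(start)
    }
  }

  parse_edge <- function(id) {
    type <- substr(id, 1L, 1L)
    ij <- strsplit(substr(id, 2L, nchar(id)), "_", fixed = TRUE)[[1L]]
    crossing_point(type, as.integer(ij[1L]), as.integer(ij[2L]))
  }
  lapply(polylines, function(ids) {
    pts <- t(vapply(ids, parse_edge, numeric(2)))
    tibble::tibble(temperature_c = pts[, 1L], pco2_uatm = pts[, 2L])
  })
}

#' Steepness (instability) map of a net surface
#'
#' Gradient magnitude of the net surface: regions where the surface is
#' steepest are where small driver variability is most likely to flip the
#' production-consumption balance. Because degrees C and micro-atm are
#' incommensurable, each axis is rescaled to `[0, 1]` by its grid range
#' before differencing (central differences in the interior, one-sided at
#' the edges); supply physically scaled axes to change this.
#'
#' @param net A `net_surface` whose axes have at least 3 points each.
#' @return A `steepness_surface` (a `perf_surface` of gradient magnitudes)
#'   with an `argmax` attribute: a list with the `temperature_c`,
#'   `pco2_uatm`, and `value` of the steepest cell.
#' @export
steepness_map <- function(net) {
  stopifnot(inherits(net, "net_surface"))
  tv <- t_axis(net)
  cv <- c_axis(net)
  if (length(tv) < 3L || length(cv) < 3L) {
    stop("steepness_map needs at least 3 points per axis", call. = FALSE)
  }
  z <- surface_matrix(net)
  tu <- (tv - min(tv)) / diff(range(tv))
  cu <- (cv - min(cv)) / diff(range(cv))
  g <- pracma::gradient(z, cu, tu)  # $X = d/dc (columns), $Y = d/dt (rows)
  mag <- sqrt(g$X^2 + g$Y^2)
  out <- new_surface_tbl(mag, surface_grid(net),
                         class = c("steepness_surface", "perf_surface"),
                         scaled = FALSE)
  k <- arrayInd(which.max(mag), dim(mag))
  attr(out, "argmax") <- list(temperature_c = tv[k[1L]],
                              pco2_uatm = cv[k[2L]],
                              value = mag[k[1L], k[2L]])
  out
}

#' Classify an environmental perturbation
#'
#' Evaluates the scaled production `P` and demand `rho * G` at a start point
#' and at the perturbed end point, and classifies the change the way the
#' conceptual production-consumption state space does:
#'
#' * `state_shifting` — the sign of net production flips between start and
#'   end: the community tips between the accumulating and depleted states.
#' * `parallel` — both species change in lockstep: the log balance
#'   `log(P / (rho * G))` moves by at most `tol`.
#' * `reinforcing` — the balance shifts in favor of the already-dominant
#'   process (`|net|` grows without a sign change); a balance shift that
#'   shrinks `|net|` without flipping it is still classed `parallel`.
#'
#' If `P` or `rho * G` is zero at either endpoint the log balance is
#' undefined; classification then falls back to the sign/magnitude rules
#' alone (`state_shifting` on a sign flip, else `reinforcing` when `|net|`
#' grows, else `parallel`).
#'
#' Surfaces are scaled by each species' maximum over `grid`, so `start` and
#' `delta` may land anywhere inside the grid bounds, not only on lattice
#' points.
#'
#' @param p_sp Producer [species_response()].
#' @param g_sp Consumer [species_response()].
#' @param grid A [driver_grid()] (defines scaling maxima, interaction
#'   stress-weight range, and admissible bounds).
#' @param start Numeric length-2, `c(temperature_c, pco2_uatm)`.
#' @param delta Numeric length-2 perturbation, `c(d_temperature, d_pco2)`.
#' @param rho Consumption-to-production capacity ratio; default 1.
#' @param tol Log-balance tolerance separating `parallel` from
#'   `reinforcing`; default 0.05.
#' @return A `perturbation_result`: list with `start`, `delta`, `class`,
#'   `net_start`, `net_end`, and `vectors` (the changes `dP` and `dG` in
#'   scaled production and demand, for arrow plotting).
#' @export
classify_perturbation <- function(p_sp, g_sp, grid, start, delta,
                                  rho = 1, tol = 0.05) {
  stopifnot(inherits(p_sp, "species_response"),
            inherits(g_sp, "species_response"),
            inherits(grid, "driver_grid"))
  if (length(start) != 2L || length(delta) != 2L ||
      any(!is.finite(c(start, delta)))) {
    stop("`start` and `delta` must be finite length-2 numerics",
         call. = FALSE)
  }
  end <- start + delta
  t_rng <- range(grid$t_axis)
  c_rng <- range(grid$c_axis)
  inside <- function(p) {
    p[1L] >= t_rng[1L] && p[1L] <= t_rng[2L] &&
      p[2L] >= c_rng[1L] && p[2L] <= c_rng[2L]
  }
  if (!inside(start) || !inside(end)) {
    stop("perturbation endpoint outside the grid bounds", call. = FALSE)
  }
  max_p <- max(species_surface(p_sp, grid)$value)
  max_g <- max(species_surface(g_sp, grid)$value)
  if (max_p <= 0 || max_g <= 0) {
    stop("degenerate species surface: zero maximum over the grid",
         call. = FALSE)
  }
  P <- eval_species(p_sp, c(start[1L], end[1L]), c(start[2L], end[2L]),
                    grid) / max_p
  G <- rho * eval_species(g_sp, c(start[1L], end[1L]),
                          c(start[2L], end[2L]), grid) / max_g
  net <- P - G
  flip <- (net[1L] > 0) != (net[2L] > 0)
  if (all(delta == 0)) {
    cls <- "parallel"
  } else if (flip) {
    cls <- "state_shifting"
  } else if (all(P > 0) && all(G > 0)) {
    dlb <- log(P[2L] / G[2L]) - log(P[1L] / G[1L])
    if (abs(dlb) <= tol) {
      cls <- "parallel"
    } else if (abs(net[2L]) > abs(net[1L])) {
      cls <- "reinforcing"
    } else {
      cls <- "parallel"
    }
  } else {
    cls <- if (abs(net[2L]) > abs(net[1L])) "reinforcing" else "parallel"
  }
  structure(
    list(start = c(temperature_c = start[1L], pco2_uatm = start[2L]),
         delta = c(d_temperature = delta[1L], d_pco2 = delta[2L]),
         class = cls,
         net_start = net[1L], net_end = net[2L],
         vectors = c(dP = P[2L] - P[1L], dG = G[2L] - G[1L])),
    class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf(
    "<perturbation_result> %s\n  start (%g degC, %g uatm), delta (%+g degC, %+g uatm)\n  net: %.4f -> %.4f; dP = %+.4f, dG = %+.4f\n",
    x$class, x$start[1L], x$start[2L], x$delta[1L], x$delta[2L],
    x$net_start, x$net_end, x$vectors["dP"], x$vectors["dG"]))
  invisible(x)
}
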