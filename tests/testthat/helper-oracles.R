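# Build a net surface directly from a field function f(t, c); used to test
# the phase module against fields with known geometry.
make_net <- function(f, t_axis = seq(0, 10, length.out = 15),
                     c_axis = seq(0, 10, length.out = 12), rho = 1) {
  grid <- driver_grid(t_axis, c_axis)
  vals <- outer(t_axis, c_axis, f)
  phasetip:::new_surface_tbl(vals, grid, class = "net_surface", rho = rho)
}

# Random smooth field: a few Gaussian bumps of either sign plus an offset,
# generically free of exact zeros and grid-aligned contours.
random_smooth_net <- function(seed, nt = 15, nc = 12) {
  withr::with_seed(seed, {
    k <- sample(2:4, 1)
    amp <- runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
    tc <- runif(k, 0, 10)
    cc <- runif(k, 0, 10)
    st <- runif(k, 1, 4)
    sc <- runif(k, 1, 4)
    off <- runif(1, -0.3, 0.3)
    f <- function(t, c) {
      out <- off
      for (i in seq_len(k)) {
        out <- out + amp[i] *
          exp(-((t - tc[i])^2 / (2 * st[i]^2) +
                  (c - cc[i])^2 / (2 * sc[i]^2)))
      }
      out
    }
    make_net(Vectorize(f), seq(0, 10, length.out = nt),
             seq(0, 10, length.out = nc))
  })
}

# Independent brute-force oracle: scan every grid edge for a sign change
# (z > 0 vs z <= 0) and return one "type_i_j" key per crossing edge,
# matching the marching-squares edge labelling.
edge_scan_crossings <- function(net) {
  z <- surface_matrix(net)
  pos <- z > 0
  nt <- nrow(z)
  nc <- ncol(z)
  keys <- character(0)
  for (j in seq_len(nc)) {
    for (i in seq_len(nt - 1)) {
      if (pos[i, j] != pos[i + 1, j]) keys <- c(keys, paste0("H", i, "_", j))
    }
  }
  for (j in seq_len(nc - 1)) {
    for (i in seq_len(nt)) {
      if (pos[i, j] != pos[i, j + 1]) keys <- c(keys, paste0("V", i, "_", j))
    }
  }
  sort(keys)
}

# Map an isocline vertex back to the grid edge it sits on, and linearly
# interpolate the net value there (should be ~0).
vertex_edge_and_value <- function(net, t, c) {
  tv <- t_axis(net)
  cv <- c_axis(net)
  z <- surface_matrix(net)
  tol <- 1e-8
  j_on <- which(abs(cv - c) < tol)
  i_on <- which(abs(tv - t) < tol)
  if (length(j_on) == 1 && length(i_on) == 0) {
    i <- findInterval(t, tv, rightmost.closed = TRUE)
    frac <- (t - tv[i]) / (tv[i + 1] - tv[i])
    val <- (1 - frac) * z[i, j_on] + frac * z[i + 1, j_on]
    list(key = paste0("H", i, "_", j_on), value = val)
  } else if (length(i_on) == 1) {
    j <- findInterval(c, cv, rightmost.closed = TRUE)
    frac <- (c - cv[j]) / (cv[j + 1] - cv[j])
    val <- (1 - frac) * z[i_on, j] + frac * z[i_on, j + 1]
    list(key = paste0("V", i_on, "_", j), value = val)
  } else {
    stop("vertex is not on a grid line")
  }
}

# Fast column argmax / first zero above the argmax, used on preset surfaces.
col_argmax <- function(s, c_val) {
  sub <- s[s$pco2_uatm == c_val, ]
  sub$temperature_c[which.max(sub$value)]
}
col_upper_zero <- function(s, c_val) {
  sub <- s[s$pco2_uatm == c_val, ]
  am <- which.max(sub$value)
  idx <- which(sub$value[am:nrow(sub)] == 0)[1]
  sub$temperature_c[am - 1 + idx]
}

# Small shared fixtures
fig4_producer <- function() {
  species_response("producer", tpc(24, 5, 32, 8),
                   saturating_response(800, 0.2))
}
fig4_consumer <- function() {
  species_response("consumer", tpc(20, 6, 26, 3.5),
                   threshold_response(1200, 0.012, 0.3))
}
small_grid <- function() {
  driver_grid(seq(10, 32, by = 1), seq(280, 1500, by = 122))
}
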