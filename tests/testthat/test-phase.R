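test_that("region labels agree with the sign of net everywhere", {
  net <- random_smooth_net(11)
  pm <- classify_regions(net)
  expect_identical(pm$state == "accumulating", net$value > 0)
  # exact zero is depleted (tie rule)
  net0 <- make_net(function(t, c) 0 * t)
  expect_true(all(classify_regions(net0)$state == "depleted"))
  all_pos <- make_net(function(t, c) 1 + 0 * t)
  expect_true(all(classify_regions(all_pos)$state == "accumulating"))
})

test_that("isocline of a linear field is the exact vertical line", {
  net <- make_net(function(t, c) t - 21 + 0 * c,
                  t_axis = seq(10, 32, by = 1),
                  c_axis = seq(280, 1500, length.out = 12))
  iso <- extract_isocline(net)
  expect_length(iso, 1)
  expect_true(all(abs(iso[[1]]$temperature_c - 21) < 1e-12))
  # spans the whole pCO2 axis
  expect_equal(range(iso[[1]]$pco2_uatm), c(280, 1500))
})

test_that("a surface with no sign change has no isocline", {
  expect_identical(extract_isocline(make_net(function(t, c) 1 + t)), list())
  expect_identical(extract_isocline(make_net(function(t, c) -1 - t)), list())
})

test_that("marching squares matches the brute-force edge-scan oracle", {
  for (seed in 1:15) {
    net <- random_smooth_net(seed)
    iso <- extract_isocline(net)
    expected_edges <- edge_scan_crossings(net)
    got <- character(0)
    for (line in iso) {
      for (k in seq_len(nrow(line))) {
        v <- vertex_edge_and_value(net, line$temperature_c[k],
                                   line$pco2_uatm[k])
        got <- c(got, v$key)
        expect_lt(abs(v$value), 1e-9)
      }
    }
    expect_setequal(unique(got), expected_edges)
  }
})

test_that("isocline vertex sets match the graphics contour tracer", {
  # second independent route: the vertex *set* of the zero contour does not
  # depend on how saddles pair segments, so it must agree with
  # grDevices::contourLines on generic smooth fields
  vertex_keys <- function(d) {
    unique(sort(paste(round(d$temperature_c, 8), round(d$pco2_uatm, 8))))
  }
  for (seed in c(3, 13, 23, 33)) {
    net <- random_smooth_net(seed)
    mine <- dplyr::bind_rows(extract_isocline(net))
    cl <- grDevices::contourLines(t_axis(net), c_axis(net),
                                  surface_matrix(net), levels = 0)
    ref <- dplyr::bind_rows(lapply(cl, function(l) {
      tibble::tibble(temperature_c = l$x, pco2_uatm = l$y)
    }))
    expect_setequal(vertex_keys(mine), vertex_keys(ref))
  }
})

test_that("isocline vertices separate cells of different state labels", {
  # every crossing edge joins a positive and a non-positive grid node, so
  # nudging along the edge toward either node recovers that node's sign
  net <- random_smooth_net(7)
  z <- surface_matrix(net)
  for (key in edge_scan_crossings(net)) {
    type <- substr(key, 1, 1)
    ij <- as.integer(strsplit(substr(key, 2, nchar(key)), "_")[[1]])
    ends <- if (type == "H") c(z[ij[1], ij[2]], z[ij[1] + 1, ij[2]]) else
      c(z[ij[1], ij[2]], z[ij[1], ij[2] + 1])
    expect_true(xor(ends[1] > 0, ends[2] > 0))
  }
})

test_that("saddle cells are resolved by the cell-center sign", {
  # 2x2 checkerboard: corners (+ - / - +), center value decides pairing
  net_pos <- make_net(function(t, c) ifelse((t + c) %% 2 == 0, 1, -0.5),
                      t_axis = c(0, 1), c_axis = c(0, 1))
  iso <- extract_isocline(net_pos)  # center mean = 0.25 > 0
  expect_length(iso, 2)
  net_neg <- make_net(function(t, c) ifelse((t + c) %% 2 == 0, 0.5, -1),
                      t_axis = c(0, 1), c_axis = c(0, 1))
  iso2 <- extract_isocline(net_neg)  # center mean < 0: other pairing
  expect_length(iso2, 2)
  # pairings differ: compare sorted vertex sets of the two solutions
  ends <- function(iso) sort(vapply(iso, function(l) {
    paste(round(l$temperature_c, 6), round(l$pco2_uatm, 6), collapse = ";")
  }, character(1)))
  expect_false(identical(ends(iso), ends(iso2)))
})

test_that("steepness map is zero for constant fields, exact for linear", {
  flat <- make_net(function(t, c) 0.3 + 0 * t)
  expect_true(all(steepness_map(flat)$value == 0))
  # linear in t: after axis normalization the gradient magnitude equals
  # the total rise over the grid range, everywhere
  lin <- make_net(function(t, c) 2 * t + 0 * c,
                  t_axis = seq(0, 5, by = 0.5),
                  c_axis = seq(0, 9, by = 1))
  sm <- steepness_map(lin)
  expect_equal(sm$value, rep(10, nrow(sm)))
})

test_that("steepness argmax matches a brute-force finite-difference scan", {
  net <- random_smooth_net(21)
  sm <- steepness_map(net)
  z <- surface_matrix(net)
  tv <- t_axis(net); cv <- c_axis(net)
  tu <- (tv - min(tv)) / diff(range(tv))
  cu <- (cv - min(cv)) / diff(range(cv))
  brute <- matrix(NA_real_, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(ncol(z))) {
      dt <- if (i == 1) (z[2, j] - z[1, j]) / (tu[2] - tu[1]) else
        if (i == nrow(z)) (z[i, j] - z[i - 1, j]) / (tu[i] - tu[i - 1]) else
          (z[i + 1, j] - z[i - 1, j]) / (tu[i + 1] - tu[i - 1])
      dc <- if (j == 1) (z[i, 2] - z[i, 1]) / (cu[2] - cu[1]) else
        if (j == ncol(z)) (z[i, j] - z[i, j - 1]) / (cu[j] - cu[j - 1]) else
          (z[i, j + 1] - z[i, j - 1]) / (cu[j + 1] - cu[j - 1])
      brute[i, j] <- sqrt(dt^2 + dc^2)
    }
  }
  expect_equal(surface_matrix(sm), brute)
  am <- attr(sm, "argmax")
  k <- arrayInd(which.max(brute), dim(brute))
  expect_equal(am$temperature_c, tv[k[1]])
  expect_equal(am$pco2_uatm, cv[k[2]])
  expect_error(steepness_map(make_net(function(t, c) t, t_axis = c(0, 1),
                                      c_axis = c(0, 1))), "3 points")
})

test_that("steepness is invariant under swapping producer and consumer", {
  p <- scale_to_max(species_surface(fig4_producer(), small_grid()))
  g <- scale_to_max(species_surface(fig4_consumer(), small_grid()))
  s1 <- steepness_map(net_production(p, g, 1))
  s2 <- steepness_map(net_production(g, p, 1))
  expect_equal(s1$value, s2$value)
})

test_that("perturbation classes follow the state-space definitions", {
  spec <- build_preset("fig4")
  p_sp <- spec$producer; g_sp <- spec$consumer; grid <- spec$grid
  # identity perturbation is parallel with zero vectors
  r0 <- classify_perturbation(p_sp, g_sp, grid, start = c(20, 400),
                              delta = c(0, 0))
  expect_identical(r0$class, "parallel")
  expect_equal(unname(r0$vectors), c(0, 0))
  # the fig4 trough: cooling from the warm accumulating flank toward the
  # consumer optimum at low pCO2 crosses the boundary
  r <- classify_perturbation(p_sp, g_sp, grid, start = c(26, 300),
                             delta = c(-6, 0))
  expect_identical(r$class, "state_shifting")
  expect_true((r$net_start > 0) != (r$net_end > 0))
  # any sign flip is state_shifting by definition: scan a few random pairs
  withr::with_seed(42, {
    for (k in 1:20) {
      start <- c(runif(1, 12, 30), runif(1, 300, 1400))
      delta <- c(runif(1, -2, 2), runif(1, -100, 100))
      end <- start + delta
      if (any(end < c(10, 280)) || any(end > c(32, 1500))) next
      res <- classify_perturbation(p_sp, g_sp, grid, start, delta)
      flips <- (res$net_start > 0) != (res$net_end > 0)
      expect_identical(res$class == "state_shifting", flips)
    }
  })
})

test_that("state-shifting perturbations reverse consistently", {
  spec <- build_preset("fig4")
  start <- c(26, 300); delta <- c(-6, 0)
  fwd <- classify_perturbation(spec$producer, spec$consumer, spec$grid,
                               start, delta)
  expect_identical(fwd$class, "state_shifting")
  back <- classify_perturbation(spec$producer, spec$consumer, spec$grid,
                                start + delta, -delta)
  expect_identical(back$class, "state_shifting")
  expect_equal(back$net_end, fwd$net_start)
})

test_that("log-balance tolerance separates parallel from reinforcing", {
  # neutral co2 for both species: moving along the pCO2 axis changes
  # nothing, a perfectly parallel perturbation
  p_sp <- species_response("producer", tpc(24, 5, 32, 6))
  g_sp <- species_response("consumer", tpc(20, 6, 26, 4))
  grid <- small_grid()
  r <- classify_perturbation(p_sp, g_sp, grid, start = c(22, 400),
                             delta = c(0, 800))
  expect_identical(r$class, "parallel")
  # warming from the net-positive flank toward the producer optimum at
  # fixed pCO2 strengthens the producer's advantage: reinforcing
  r2 <- classify_perturbation(p_sp, g_sp, grid, start = c(25, 400),
                              delta = c(3, 0))
  expect_identical(r2$class, "reinforcing")
  expect_gt(abs(r2$net_end), abs(r2$net_start))
  # out-of-bounds endpoints error
  expect_error(classify_perturbation(p_sp, g_sp, grid, c(31, 400),
                                     c(5, 0)), "outside the grid")
})

test_that("zero-performance endpoints fall back to sign-based rules", {
  p_sp <- species_response("producer", tpc(24, 5, 32, 6))
  g_sp <- species_response("consumer", tpc(20, 6, 26, 4))
  grid <- small_grid()
  # start beyond the consumer's ct_max: G = 0 there, balance undefined
  r <- classify_perturbation(p_sp, g_sp, grid, start = c(27, 400),
                             delta = c(-2, 0))
  expect_true(r$class %in% c("parallel", "reinforcing", "state_shifting"))
  expect_s3_class(tidy(r), "tbl_df")
})
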