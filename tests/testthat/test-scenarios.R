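test_that("presets carry the documented thermal optima and shifts", {
  expect_equal(build_preset("fig4")$producer$thermal$t_opt, 24)
  expect_equal(build_preset("fig4")$consumer$thermal$t_opt, 20)
  expect_equal(build_preset("fig5")$consumer$thermal$t_opt, 24)
  expect_equal(build_preset("fig5")$producer$thermal$t_opt, 20)
  expect_equal(build_preset("fig6")$producer$thermal$t_opt, 20)
  expect_equal(build_preset("fig6")$consumer$thermal$t_opt, 20)
  expect_equal(build_preset("fig7")$producer$thermal$t_opt, 20)
  expect_equal(build_preset("fig7")$consumer$thermal$t_opt, 20)
  mod <- build_preset("fig8")$consumer$interaction
  expect_equal(mod$d_topt, 2)
  expect_equal(mod$d_ctmax, 4)
  expect_error(build_preset("nosuch"), "available presets")
})

test_that("breadth orderings match the matched-optima scenarios", {
  f6 <- build_preset("fig6")
  expect_gt(thermal_breadth(f6$producer$thermal, 0.5),
            thermal_breadth(f6$consumer$thermal, 0.5))
  f7 <- build_preset("fig7")
  expect_gt(thermal_breadth(f7$consumer$thermal, 0.5),
            thermal_breadth(f7$producer$thermal, 0.5))
})

test_that("scenario runs are deterministic and internally consistent", {
  r1 <- run_scenario(build_preset("fig4"))
  r2 <- run_scenario(build_preset("fig4"))
  expect_identical(r1$net_surface$value, r2$net_surface$value)
  expect_identical(isoclines(r1$phase_map), isoclines(r2$phase_map))
  # all surfaces share the grid; species maxima are exactly 1
  for (s in list(r1$producer_surface, r1$consumer_surface,
                 r1$net_surface, r1$secondary_surface)) {
    expect_equal(t_axis(s), t_axis(r1$net_surface))
  }
  expect_equal(max(r1$producer_surface$value), 1)
  expect_equal(max(r1$consumer_surface$value), 1)
  # net = producer - rho * consumer
  expect_equal(r1$net_surface$value,
               r1$producer_surface$value - r1$consumer_surface$value)
  g <- glance(r1)
  expect_identical(g$name, "fig4")
  td <- tidy(r1)
  expect_setequal(unique(td$panel),
                  c("producer", "consumer", "net", "secondary"))
})

test_that("warm producer / cool consumer: deficit trough at low pCO2 near the consumer optimum", {
  res <- run_scenario(build_preset("fig4"))
  net <- res$net_surface
  i <- which.min(net$value)
  expect_equal(net$pco2_uatm[i], min(c_axis(net)))
  expect_gte(net$temperature_c[i], 18)
  expect_lte(net$temperature_c[i], 22)
  # the trough sits below the producer optimum
  expect_lt(net$temperature_c[i], 24)
})

test_that("warm consumer scenario is stable until a warm-side collapse", {
  net <- run_scenario(build_preset("fig5"))$net_surface
  cmin <- min(c_axis(net))
  col <- net[net$pco2_uatm == cmin, ]
  expect_gt(col$value[col$temperature_c == 16], 0)
  expect_lt(min(col$value[col$temperature_c > 24]), 0)
})

test_that("broad consumer confines the accumulating state to high pCO2", {
  pm <- run_scenario(build_preset("fig7"))$phase_map
  acc <- pm[pm$state == "accumulating", ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$pco2_uatm > stats::median(c_axis(pm))))
})

test_that("broad producer is stable over more conditions than broad consumer", {
  pm6 <- run_scenario(build_preset("fig6"))$phase_map
  pm7 <- run_scenario(build_preset("fig7"))$phase_map
  mid <- c_axis(pm6)[ceiling(length(c_axis(pm6)) / 2)]
  n6 <- sum(pm6$state == "accumulating" & pm6$pco2_uatm == mid)
  n7 <- sum(pm7$state == "accumulating" & pm7$pco2_uatm == mid)
  expect_gt(n6, n7)
})

test_that("interactive pCO2 stress shifts the consumer's thermal limits", {
  res <- run_scenario(build_preset("fig8"))
  g <- res$consumer_surface
  cmin <- min(c_axis(g)); cmax <- max(c_axis(g))
  expect_equal(col_argmax(g, cmin) - col_argmax(g, cmax), 2)
  expect_equal(col_upper_zero(g, cmin) - col_upper_zero(g, cmax), 4)
})

test_that("simulated observations are reproducible and unbiased", {
  crv <- tpc(24, 5, 32, 6)
  a <- simulate_observations(crv, n = 50, noise_sd = 0.05, seed = 7)
  b <- simulate_observations(crv, n = 50, noise_sd = 0.05, seed = 7)
  expect_identical(a$driver, b$driver)
  expect_identical(a$performance, b$performance)
  expect_true(all(a$performance >= 0))
  expect_true(all(a$driver >= 5 & a$driver <= 32))
  # zero noise lands exactly on the curve
  exact <- simulate_observations(crv, n = 40, noise_sd = 0, seed = 3)
  expect_equal(exact$performance, eval_tpc(crv, exact$driver))
  # CLT bound on the mean residual at n = 200, sd = 0.02
  big <- simulate_observations(crv, n = 200, noise_sd = 0.02, seed = 11)
  resid <- big$performance - eval_tpc(crv, big$driver)
  expect_lt(abs(mean(resid)), 0.01)
  expect_error(simulate_observations(crv, n = 0, noise_sd = 0, seed = 1),
               "`n`")
  expect_error(simulate_observations(crv, n = 10, noise_sd = -1, seed = 1),
               "noise_sd")
})

test_that("noiseless thermal observations are recovered near-exactly", {
  truth <- tpc(24, 5, 32, 6)
  obs <- simulate_observations(truth, n = 120, noise_sd = 0, seed = 2)
  fit <- fit_curve(obs, "tpc")
  expect_lt(abs(fit$curve$t_opt - 24), 0.05)
  expect_lt(fit$rmse, 1e-3)
})

test_that("noisy thermal optimum is recovered within half a degree", {
  truth <- tpc(24, 5, 32, 6)
  obs <- simulate_observations(truth, n = 200, noise_sd = 0.02, seed = 1)
  fit <- fit_curve(obs, "tpc")
  expect_lt(abs(fit$curve$t_opt - 24), 0.5)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(tidy(fit)$term,
                   c("t_opt", "ct_min", "ct_max", "sigma_rise", "p_max"))
  expect_true(glance(fit)$converged)
})

test_that("mismatched families fit worse than the generating family", {
  truth <- threshold_response(900, 0.01, 0.3)
  obs <- simulate_observations(truth, n = 150, noise_sd = 0.02, seed = 5)
  matched <- fit_curve(obs, "threshold")
  mismatched <- fit_curve(obs, "saturating")
  expect_lt(matched$rmse, mismatched$rmse)
})

test_that("saturating and hormetic families are also recoverable", {
  sat <- saturating_response(600, 0.4)
  fit_s <- fit_curve(simulate_observations(sat, 150, 0.01, seed = 9),
                     "saturating")
  expect_lt(abs(fit_s$curve$k_half - 600) / 600, 0.2)
  horm <- hormetic_response(alpha = 1.5, lam = 4, kappa = 2)
  fit_h <- fit_curve(simulate_observations(horm, 200, 0.01, seed = 9),
                     "hormetic")
  expect_lt(abs(fit_h$curve$lam - 4) / 4, 0.2)
  expect_error(fit_curve(data.frame(driver = 1:4, performance = 1:4),
                         "tpc"), "at least 25")
})
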