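test_that("growth parameter defaults encode the per-mode endpoint data", {
  ph <- growth_params("phototrophic")
  he <- growth_params("heterotrophic")
  mx <- growth_params("mixotrophic")
  expect_equal(c(ph$k_cap, he$k_cap, mx$k_cap), c(0.5740, 2.0687, 1.9888))
  expect_equal(ph$chl_ratio, 20.5450 / 0.5740)
  expect_equal(he$chl_ratio, 3.3564 / 2.0687)
  expect_equal(mx$chl_ratio, 13.5415 / 1.9888)
  expect_equal(ph$x0, 0.2)
  expect_error(growth_params("phototrophic", k_cap = 0.1, x0 = 0.2),
               "k_cap")
  expect_error(growth_params("phototrophic", rate = -1), "rate")
})

test_that("the logistic trajectory starts at the inoculum and saturates", {
  for (mode in c("phototrophic", "heterotrophic", "mixotrophic")) {
    gp <- growth_params(mode)
    expect_equal(simulate_logistic(gp, 0), gp$x0)
    t_long <- 10 * (1 / gp$rate) * log(gp$k_cap / gp$x0)
    expect_equal(simulate_logistic(gp, t_long), gp$k_cap, tolerance = 0.01)
    tt <- seq(0, 288, by = 6)
    x <- simulate_logistic(gp, tt)
    expect_true(all(diff(x) > 0))          # strictly increasing
    expect_true(all(x <= gp$k_cap + 1e-12))  # bounded by the capacity
  }
  expect_error(simulate_logistic(growth_params("mixotrophic"), c(5, 1)),
               "sorted")
})

test_that("shipped defaults reach the experimental 288-h maxima", {
  expect_equal(simulate_logistic(growth_params("heterotrophic"), 288),
               2.0687, tolerance = 0.02)
  expect_equal(simulate_logistic(growth_params("mixotrophic"), 288),
               1.9888, tolerance = 0.02)
  expect_equal(simulate_logistic(growth_params("phototrophic"), 288),
               0.5740, tolerance = 0.02)
  expect_equal(chlorophyll_trajectory(growth_params("phototrophic"), 288),
               20.5450, tolerance = 0.02)
  expect_equal(chlorophyll_trajectory(growth_params("heterotrophic"), 288),
               3.3564, tolerance = 0.02)
})

test_that("chlorophyll trajectory is proportional to biomass", {
  gp <- growth_params("mixotrophic")
  tt <- seq(0, 288, 24)
  expect_equal(chlorophyll_trajectory(gp, tt),
               gp$chl_ratio * simulate_logistic(gp, tt))
  gp0 <- growth_params("mixotrophic", chl_ratio = 0)
  expect_equal(chlorophyll_trajectory(gp0, tt), rep(0, length(tt)))
})

test_that("residence-time evaluation honours pinned outlet overrides", {
  gp <- growth_params("mixotrophic")
  ov <- concentration_at_residence(gp, 72,
                                   override = list(biomass_g_l = 1.57,
                                                   chl_ug_l = 12970))
  expect_equal(ov$biomass_g_l, 1.57)
  expect_equal(ov$chl_ug_l, 12970)
  expect_equal(ov$source, "override")
  md <- concentration_at_residence(gp, 72)
  expect_equal(md$source, "model")
  expect_equal(md$biomass_g_l, simulate_logistic(gp, 72))
  # an (artificial) zero-residence limit returns the inoculum
  tiny <- concentration_at_residence(gp, 1e-9)
  expect_equal(tiny$biomass_g_l, gp$x0, tolerance = 1e-6)
  expect_equal(tiny$chl_ug_ml, gp$chl_ratio * gp$x0, tolerance = 1e-6)
  expect_error(concentration_at_residence(gp, 0), "positive")
  expect_error(concentration_at_residence(gp, -5), "positive")
})

test_that("fitting recovers exact logistic data to solver precision", {
  tt <- seq(0, 288, by = 24)
  gp <- growth_params("mixotrophic", k_cap = 2.0, rate = 0.05, x0 = 0.2)
  y <- simulate_logistic(gp, tt)
  fit <- fit_logistic(tt, y)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  cf <- coef(fit)
  expect_equal(unname(cf["k_cap"]), 2.0, tolerance = 1e-6)
  expect_equal(unname(cf["rate"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(cf["x0"]), 0.2, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(predict(fit, tt), y, tolerance = 1e-6)
  expect_equal(residuals(fit), y - fitted(fit))
})

test_that("degenerate and invalid series are flagged, not silently fitted", {
  expect_error(fit_logistic(c(0, 24, 48), c(1, 1, 1)), "5")
  flat <- fit_logistic(seq(0, 288, 24), rep(1.3, 13))
  expect_true(flat$degenerate)
  expect_equal(flat$params$k_cap, 1.3, tolerance = 1e-9)
  expect_error(fit_logistic(seq(0, 288, 24), c(rep(0.5, 12), -1)),
               "non-negative")
})
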