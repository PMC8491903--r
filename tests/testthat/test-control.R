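test_that("the stationary law pinpoints the intermediate optimal dose", {
  p <- baseline_params()
  u <- stationary_dose(p)
  expect_false(attr(u, "boundary"))
  expect_equal(as.numeric(u), 104.5, tolerance = 0.5 / 104.5)

  # independent oracle: brute-force minimisation of the closed-form
  # exponential-approximation cost mu(u) / (d(u) + mu(u) - r_S)
  grid <- seq(60, 1000, by = 0.1)
  cf <- (1e-6 + 1e-8 * grid) /
    ((1 - 1 / (1 + (grid / 40)^2.3)) + (1e-6 + 1e-8 * grid) - 0.5)
  expect_lt(abs(as.numeric(u) - grid[which.min(cf)]), 0.5)
})

test_that("without dose-dependent mutation the optimum is the MTD boundary", {
  p0 <- rescue_params(alpha = 0, u_MTD = 700)
  u <- stationary_dose(p0)
  expect_true(attr(u, "boundary"))
  expect_equal(as.numeric(u), 700)
})

test_that("the closed-loop law is admissible and anchored at the constant optimum", {
  p <- baseline_params()
  law <- control_law(p)
  expect_true(all(law$u_opt >= 0 & law$u_opt <= p$u_max))
  # the law at vanishing population equals the low-density constant optimum
  expect_equal(law$u_opt[law$S == 0], as.numeric(stationary_dose(p)))
  # crowding lowers the net growth rate and with it the optimal dose
  expect_true(all(diff(law$u_opt) <= 1e-9))
})

test_that("constant-dose optimisation recovers the trade-off optima", {
  p <- baseline_params()
  sol <- optimize_constant_dose(p, "rescue")
  expect_equal(sol$u_opt, 104.5, tolerance = 3 / 104.5)
  expect_equal(sol$cost, sol$cost_raw)
  expect_equal(sol$n_rescue, 0.8 * sol$cost_raw)

  # the dose-cost curve is non-monotone for alpha > 0: strictly better than
  # both a low and the plateau dose
  gr <- sol$diagnostics$grid
  expect_lt(sol$cost, gr$cost[gr$dose == 30])
  expect_lt(sol$cost, gr$cost[gr$dose == 1000])

  # boundary case: dose-independent mutation makes MTD optimal
  p0 <- rescue_params(alpha = 0)
  s0 <- optimize_constant_dose(p0, "rescue", grid_step = 10)
  expect_equal(s0$u_opt, p0$u_MTD)
  expect_true(s0$diagnostics$boundary)
})

test_that("the discounted objective prefers strictly lower doses", {
  p <- baseline_params()
  sr <- optimize_constant_dose(p, "rescue", grid_step = 2)
  sd <- optimize_constant_dose(p, "discounted", grid_step = 2)
  expect_lt(sd$u_opt, sr$u_opt)
  # and its achieved discounted cost is the smaller of the two
  expect_lt(sd$cost_discounted, sr$cost_discounted)
})
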