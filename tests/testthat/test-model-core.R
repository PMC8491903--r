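test_that("Hill kill rate matches its defining values and derivative", {
  p <- baseline_params()
  expect_equal(death_rate(0, p), 0)
  expect_equal(death_rate(p$h, p), p$d_max / 2)
  # high-precision evaluation of the Hill formula at the optimal dose
  expect_equal(death_rate(104.5, p), 0.90102866, tolerance = 1e-7)
  expect_error(death_rate(-1, p), "non-negative")

  # analytic derivative against central differences
  u <- c(5, 40, 104.5, 600)
  fd <- (death_rate(u + 1e-4, p) - death_rate(u - 1e-4, p)) / 2e-4
  expect_equal(death_rate_deriv(u, p), fd, tolerance = 1e-6)

  # monotone and bounded over random parameter draws
  set.seed(42)
  for (i in 1:25) {
    pp <- rescue_params(d_max = runif(1, 0.2, 3), h = runif(1, 5, 200),
                        k = runif(1, 0.5, 5))
    uu <- sort(runif(50, 0, 1000))
    d <- death_rate(uu, pp)
    expect_true(all(diff(d) >= 0))
    expect_true(all(d <= pp$d_max))
    expect_true(all(death_rate_deriv(uu, pp) >= 0))
  }
})

test_that("mutation rate is linear in dose with the configured slope", {
  p <- baseline_params()
  expect_equal(mutation_rate(0, p), 1e-6)
  expect_equal(mutation_rate(104.5, p), 2.045e-6)
  expect_equal(mutation_rate_deriv(c(0, 500), p), c(1e-8, 1e-8))
  p0 <- rescue_params(alpha = 0)
  expect_equal(mutation_rate(c(0, 123, 1000), p0), rep(1e-6, 3))
  expect_error(mutation_rate(-0.1, p), "non-negative")
})

test_that("establishment probability is the branching-process survival", {
  expect_equal(establishment_prob(0.5, 0.1), 0.8)
  expect_equal(establishment_prob(0.5, 0), 1)
  expect_equal(establishment_prob(0.5, 0.5), 0)
  expect_error(establishment_prob(0.5, 0.6), "subcritical")
})

test_that("the model right-hand side has the stated structure", {
  p <- baseline_params()
  expect_equal(rescue_rhs(0, 0, 50, p), c(dS = 0, dR = 0))
  # at capacity the logistic term vanishes: only mutational outflow remains
  out <- rescue_rhs(p$K, 0, 0, p)
  expect_equal(out[["dS"]], -mutation_rate(0, p) * p$K)
  # at the optimal dose the net sensitive growth is negative from the start
  out <- rescue_rhs(p$S0, 0, 104.5, p)
  expect_lt(out[["dS"]], 0)
  # mutational flux feeds the resistant compartment
  expect_equal(out[["dR"]], mutation_rate(104.5, p) * p$S0)
})

test_that("mean-field drift of the propensities equals the deterministic rate", {
  p <- baseline_params()
  set.seed(7)
  for (i in 1:50) {
    S <- runif(1, 1, p$K)
    R <- runif(1, 0, p$K / 2)
    u <- runif(1, 0, 1000)
    a <- ssa_propensities(S, R, u, p)
    drift <- (a[["beta_S"]] - a[["delta_S"]] - a[["mutation"]]) / S
    expected <- p$r_S * (1 - (S + R) / p$K) - death_rate(u, p) - mutation_rate(u, p)
    expect_equal(drift, expected, tolerance = 1e-12)
    driftR <- (a[["beta_R"]] - a[["delta_R"]]) / max(R, 1)
    if (R > 0) {
      expect_equal(driftR, p$r_R * (1 - (S + R) / p$K), tolerance = 1e-12)
    }
  }
})

test_that("untreated dynamics approach carrying capacity; treatment eliminates", {
  p <- baseline_params()
  traj0 <- simulate_ode(p, schedule_constant(0), dt = 0.05)
  # monotone logistic approach until capacity; afterwards only the slow
  # mutational outflow (~ mu0 K per unit time) drains the compartment
  up <- seq_len(which(traj0$S >= 0.999 * p$K)[1])
  expect_true(all(diff(traj0$S[up]) > 0))
  expect_equal(tail(traj0$S, 1), p$K, tolerance = 1e-3)
  expect_true(all(diff(traj0$S[-up]) > -1.5 * p$mu0 * p$K * 0.05))

  traj <- simulate_ode(p, schedule_constant(104.5), dt = 0.05)
  expect_lt(tail(traj$S, 1), 1)                 # below one cell-equivalent
  expect_true(all(traj$S >= 0) && all(traj$R >= 0))
  expect_equal(traj$time[1], 0)
  expect_equal(tail(traj$time, 1), p$T)

  expect_error(simulate_ode(p, schedule_constant(p$u_MTD + 1)), "inadmissible")
})

test_that("intensity profiles show the drug-induced early peak", {
  p <- baseline_params()
  # equilibrium baseline: constant K * mu0
  pK <- rescue_params(S0 = 1e6)
  prof0 <- intensity_profile(simulate_ode(pK, schedule_constant(0), dt = 0.05))
  expect_equal(prof0$intensity, rep(pK$K * pK$mu0, nrow(prof0)),
               tolerance = 1e-4)

  # any dosed schedule from S0 = 0.1 K starts above the drug-free intensity
  prof <- intensity_profile(simulate_ode(p, schedule_constant(104.5), dt = 0.05))
  expect_gt(prof$intensity[1], p$S0 * p$mu0)
  expect_equal(prof$intensity[1], p$S0 * mutation_rate(104.5, p))

  # an empty population generates nothing
  p0 <- rescue_params(S0 = 0)
  profe <- intensity_profile(simulate_ode(p0, schedule_constant(104.5), dt = 0.1))
  expect_equal(max(abs(profe$intensity)), 0)
})

test_that("trajectory quadrature matches the exponential closed form", {
  # exponential growth kind + constant dose admits a closed-form cost
  p <- rescue_params(growth_kind = "exponential")
  for (u in c(80, 104.5, 400)) {
    traj <- simulate_ode(p, schedule_constant(u), dt = 0.005, rtol = 1e-10)
    got <- rescue_costs(traj, p)
    expect_equal(got$cost_raw, closed_form_cost(u), tolerance = 1e-6)
  }
})

test_that("cost functionals have the stated algebraic structure", {
  p <- baseline_params()
  traj <- simulate_ode(p, schedule_constant(104.5), dt = 0.01)
  costs <- rescue_costs(traj, p)
  expect_equal(costs$pi_f, 0.8)
  expect_equal(costs$n_rescue, costs$pi_f * costs$cost_raw)
  expect_equal(costs$p_rescue, 1 - exp(-costs$n_rescue))
  # the discount weight exp(r_R (T - t)) only inflates the cost
  expect_gt(costs$cost_discounted, costs$cost_raw)

  # n_rescue = 0.1 maps to the closed-form rescue probability
  expect_equal(1 - exp(-0.1), 0.0951625819640404)

  # an extinct trajectory accrues nothing
  pe <- rescue_params(S0 = 0)
  ce <- rescue_costs(simulate_ode(pe, schedule_constant(10), dt = 0.1))
  expect_equal(ce$cost_raw, 0)
  expect_equal(ce$p_rescue, 0)
})

test_that("with a dose-independent mutation rate, cost is non-increasing in dose", {
  p0 <- rescue_params(alpha = 0)
  doses <- c(1, 25, 50, 104.5, 300, 700, 1000)
  costs <- vapply(doses, function(u) {
    unname(evorescue:::constant_dose_costs(u, p0)["raw"])
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("p_rescue is a probability, strictly increasing in n_rescue", {
  n <- c(0, 1e-4, 0.1, 0.5, 2, 10)
  pr <- 1 - exp(-n)
  expect_true(all(pr >= 0 & pr < 1))
  expect_true(all(diff(pr) > 0))
  # and the package computes the same map on real trajectories
  p <- baseline_params()
  c1 <- rescue_costs(simulate_ode(p, schedule_constant(104.5), dt = 0.02))
  c2 <- rescue_costs(simulate_ode(p, schedule_constant(1000), dt = 0.02))
  expect_gt(c2$n_rescue, c1$n_rescue)
  expect_gt(c2$p_rescue, c1$p_rescue)
})
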