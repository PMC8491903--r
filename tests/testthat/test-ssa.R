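test_that("propensities match their defining expressions and clamp at zero", {
  p <- baseline_params()
  expect_equal(unname(ssa_propensities(0, 0, 104.5, p)), rep(0, 5))

  # with theta_S = b_S, the sensitive birth rate is density-independent
  a <- ssa_propensities(1234, 77, 300, p)
  expect_equal(a[["beta_S"]], p$b_S * 1234)
  f <- (1234 + 77) / p$K
  expect_equal(a[["delta_S"]],
               (p$d_S + (p$theta_S - p$d_S) * f + death_rate(300, p)) * 1234)
  expect_equal(a[["beta_R"]], (p$b_R - (p$b_R - p$theta_R) * f) * 77)
  expect_equal(a[["delta_R"]], (p$d_R + (p$theta_R - p$d_R) * f) * 77)
  expect_equal(a[["mutation"]], mutation_rate(300, p) * 1234)

  # above capacity, rates that would go negative are clamped
  pq <- rescue_params(theta_S = 0.5, theta_R = 0.3)
  aq <- ssa_propensities(2 * pq$K, 2 * pq$K, 0, pq)
  expect_true(all(aq >= 0))
})

test_that("identical seeds give identical event sequences", {
  p <- desk_params()
  a <- ssa_run(p, schedule_constant(104.5), seed = 99)
  b <- ssa_run(p, schedule_constant(104.5), seed = 99)
  expect_identical(a$mutation_times, b$mutation_times)
  expect_identical(a$final_S, b$final_S)
  expect_identical(a$final_R, b$final_R)
  c <- ssa_run(p, schedule_constant(104.5), seed = 100)
  expect_false(identical(a$n_events, c$n_events))
})

test_that("degenerate starts return immediately", {
  p0 <- rescue_params(S0 = 0, R0 = 0)
  out <- ssa_run(p0, schedule_constant(50), seed = 1)
  expect_true(out$extinct)
  expect_equal(length(out$mutation_times), 0)
  expect_equal(out$n_events, 0)
})

test_that("the event-count safety cap aborts with a diagnostic", {
  p <- desk_params()
  expect_error(ssa_run(p, schedule_constant(0), seed = 5, max_events = 100),
               "max_events")
})

test_that("a pure birth-death process reproduces exponential mean growth", {
  # no mutation (vanishing mu0), no density dependence: E[N(t)] = N0 e^{rt}
  p <- rescue_params(S0 = 20, R0 = 0, K = Inf, T = 5, mu0 = 1e-300, alpha = 0)
  fs <- vapply(1:5000, function(i) {
    ssa_run(p, schedule_constant(0), seed = 20000 + i,
            track_lineages = FALSE)$final_S
  }, numeric(1))
  theory <- 20 * exp(p$r_S * 5)
  se <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - theory), 3 * se)
})

test_that("cohorts are reproducible and summarised consistently", {
  p <- baseline_params()
  ch <- run_cohort(p, doses = c(60, 104.5), n_sim = 40, seed = 17, scale = 0.01)
  ch2 <- run_cohort(p, doses = c(60, 104.5), n_sim = 40, seed = 17, scale = 0.01)
  expect_identical(ch$replicates, ch2$replicates)
  expect_identical(ch$summary, ch2$summary)

  s <- ch$summary
  expect_true(all(s$cure_fraction >= 0 & s$cure_fraction <= 1))
  expect_true(all(s$cure_lo <= s$cure_fraction & s$cure_fraction <= s$cure_hi))
  # conditional mean excludes the extinct replicates
  r1 <- dplyr::filter(ch$replicates, dose == 104.5, !extinct)
  expect_equal(s$mean_final_N_over_K[s$dose == 104.5],
               mean(r1$final_N) / ch$params$K)
  # establishment table is consistent with the replicate log
  est <- establishment_fraction(ch)
  expect_equal(est$n_mutations,
               tapply(ch$replicates$n_mutations, ch$replicates$dose, sum,
                      default = 0L)[as.character(est$dose)],
               ignore_attr = TRUE)
})
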