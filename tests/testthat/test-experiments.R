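test_that("intensity profiles integrate to the cost and rank as expected", {
  p <- baseline_params()
  tbl <- intensity_experiment(p, doses = c(0, 60, 104.5, 1000), dt = 0.01)

  # untreated baseline asymptotes to K * mu0
  base <- dplyr::filter(tbl, dose == 0)
  expect_equal(tail(base$intensity, 1), p$K * p$mu0, tolerance = 1e-3)

  # higher dose: higher initial peak, faster decay of the rescue window
  # (log-slope of the profile between t = 10 and t = 20)
  peak <- tbl |> dplyr::filter(dose > 0) |> dplyr::group_by(dose) |>
    dplyr::summarise(
      start = intensity[1],
      decay = (log(intensity[dplyr::near(time, 20)]) -
               log(intensity[dplyr::near(time, 10)])) / 10)
  expect_true(all(diff(peak$start) > 0))
  expect_true(all(diff(peak$decay) < 0))

  # area under each dosed profile equals the cost functional
  for (u in c(60, 104.5)) {
    sub <- dplyr::filter(tbl, dose == u)
    auc <- evorescue:::trapz(sub$time, sub$intensity)
    expect_equal(auc, unname(evorescue:::constant_dose_costs(u, p)["raw"]),
                 tolerance = 1e-3)
  }
})

test_that("the relative-cost contour is anchored on the optimal-dose curve", {
  p <- baseline_params()
  res <- contour_experiment(p,
                            alpha_grid = c(1e-9, 1e-8, 1e-7),
                            dose_grid = c(seq(20, 200, by = 10), 500, 1000))
  # relative cost >= 1 with equality only on the optimum
  expect_true(all(res$grid$relative_cost >= 1 - 1e-6))
  # fold change is 1 at zero dose by construction and 11 at the plateau
  # for alpha = 1e-8
  expect_equal(
    res$grid$fold_change[res$grid$alpha == 1e-8 & res$grid$dose == 1000], 11)
  # the optimal dose is non-increasing in mutagenicity
  expect_true(all(diff(res$optimal$u_opt) <= 1e-6))
  # the 1-isoline coincides with the independently optimised curve: the
  # grid dose with minimal relative cost is the one nearest to u_opt
  for (i in seq_len(nrow(res$optimal))) {
    sub <- dplyr::filter(res$grid, alpha == res$optimal$alpha[i])
    expect_equal(sub$dose[which.min(sub$relative_cost)],
                 sub$dose[which.min(abs(sub$dose - res$optimal$u_opt[i]))])
  }
  # a = 1e-8 slice reproduces the intermediate optimum
  expect_equal(res$optimal$u_opt[res$optimal$alpha == 1e-8], 104.5,
               tolerance = 6 / 104.5)
})

test_that("experiments are pure functions of their inputs", {
  p <- baseline_params()
  a <- intensity_experiment(p, doses = c(0, 104.5), dt = 0.1)
  b <- intensity_experiment(p, doses = c(0, 104.5), dt = 0.1)
  expect_identical(a, b)
  s1 <- dose_sweep_experiment(p, doses = c(104.5), n_sim = 30, seed = 3)
  s2 <- dose_sweep_experiment(p, doses = c(104.5), n_sim = 30, seed = 3)
  expect_identical(s1$summary, s2$summary)
})

test_that("result objects serialise to a checksummed plain-text inventory", {
  p <- baseline_params()
  dir <- withr::local_tempdir()
  traj <- simulate_ode(p, schedule_constant(104.5), dt = 0.5)
  inv <- write_results(traj, file.path(dir, "run"))
  expect_true(all(file.exists(inv$file)))
  expect_true(all(nchar(inv$md5) == 32))
  back <- read.csv(inv$file[1])
  expect_equal(names(back), c("t", "S", "R", "u"))
  expect_equal(back$S, traj$S, tolerance = 1e-12)

  sw <- dose_sweep_experiment(p, doses = c(104.5), n_sim = 10, seed = 1)
  inv2 <- write_results(sw, file.path(dir, "sweep"))
  expect_equal(nrow(inv2), 4L)

  man <- file.path(dir, "manifest.json")
  write_manifest("sweep", p, list(seed = 1, n_sim = 10), inv2, man)
  got <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(got$command, "sweep")
  expect_equal(got$params$mu0, p$mu0)
  expect_equal(nrow(got$files), 4L)
})
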