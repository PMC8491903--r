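test_that("default parameters reproduce the baseline configuration", {
  p <- baseline_params()
  expect_equal(p$mu0, 1e-6)
  expect_equal(p$alpha, 1e-8)
  expect_equal(p$r_S, 0.5)
  expect_equal(p$r_R, 0.4)
  expect_equal(p$S0 * p$mu0, 0.1)
  expect_equal(p$u_MTD, 1000)
})

test_that("cross-field invariants are enforced with informative errors", {
  expect_error(rescue_params(r_S = 0.4), "r_S must equal b_S - d_S",
               fixed = TRUE)
  expect_error(rescue_params(theta_S = 0.9), "theta_S")
  expect_error(rescue_params(theta_R = 0.05), "theta_R")
  expect_error(rescue_params(u_MTD = 2000), "u_MTD")
  expect_error(rescue_params(b_R = 0.1, d_R = 0.1, theta_R = 0.1), "b_R")
  expect_error(rescue_params(mu0 = 0), "mu0")
  expect_error(rescue_params(alpha = -1e-9), "alpha")
})

test_that("rescaling preserves per-capita structure and the baseline intensity", {
  p <- baseline_params()
  ps <- scale_params(p, 0.01)
  expect_equal(ps$K, 1e4)
  expect_equal(ps$S0, 1e3)
  expect_equal(ps$mu0, 1e-4)
  expect_equal(ps$alpha, 1e-6)
  expect_equal(ps$S0 * ps$mu0, p$S0 * p$mu0)
  # per-capita mutation intensity at any dose is scale-invariant times 1/c
  expect_equal(ps$S0 * mutation_rate(104.5, ps), p$S0 * mutation_rate(104.5, p))
})

test_that("configuration files round-trip exactly and reject bad input", {
  p <- rescue_params(alpha = 3.7e-9, u_MTD = 350, growth_kind = "gompertz")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  p2 <- read_params(path, quiet = TRUE)
  expect_identical(unclass(p2), unclass(p))

  # packaged default config equals the in-code defaults
  pkg_cfg <- system.file("extdata", "default_params.yaml", package = "evorescue")
  expect_identical(unclass(read_params(pkg_cfg, quiet = TRUE)),
                   unclass(rescue_params()))

  # missing keys fall back with one message each
  partial <- withr::local_tempfile(fileext = ".yaml")
  writeLines("alpha: 2.0e-8", partial)
  msgs <- capture_messages(read_params(partial))
  expect_length(msgs, length(unclass(rescue_params())) - 1L)
  expect_equal(read_params(partial, quiet = TRUE)$alpha, 2e-8)

  # inconsistent r_S is rejected, unknown keys are rejected
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("r_S: 0.4"), bad)
  expect_error(read_params(bad, quiet = TRUE), "r_S")
  writeLines(c("frobnicate: 1"), bad)
  expect_error(read_params(bad, quiet = TRUE), "unknown configuration key")
})
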