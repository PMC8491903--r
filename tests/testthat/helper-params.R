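# Baseline parameter set used across the suite (the packaged defaults), and
# a desk-scale variant for stochastic tests.
baseline_params <- function(...) rescue_params(...)

desk_params <- function(c = 0.01, ...) scale_params(rescue_params(...), c)

# Closed-form cost of a constant dose under pure exponential decay:
# S(t) = S0 exp(-gamma t) with gamma = d(u) + mu(u) - r_S, so
# C = S0 mu (1 - exp(-gamma T)) / gamma. Written out independently of the
# package's pharmacodynamics helpers so it can serve as a quadrature oracle.
closed_form_cost <- function(u, S0 = 1e5, r_S = 0.5, d_max = 1, h = 40,
                             k = 2.3, mu0 = 1e-6, alpha = 1e-8, T = 35) {
  d <- d_max * (1 - 1 / (1 + (u / h)^k))
  mu <- mu0 + alpha * u
  gamma <- d + mu - r_S
  S0 * mu * (1 - exp(-gamma * T)) / gamma
}
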