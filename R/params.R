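#' Model parameters for the rescue-dynamics model
#'
#' Builds the full parameter set of the two-type (sensitive/resistant)
#' birth-death-mutation model: density-dependent growth, Hill
#' pharmacodynamics, the linearly dose-dependent mutation rate, and the
#' stochastic-model turnover parameters. Defaults are the study's baseline
#' configuration: an initial sensitive burden of `S0 = 1e5` cells in a niche
#' of carrying capacity `K = 1e6`, a drug killing at most `d_max = 1` per
#' unit time with half-effect at `h = 40` concentration units, a baseline
#' mutation rate of `1e-6` per cell per unit time rising by `alpha = 1e-8`
#' per concentration unit, and a treatment window of `T = 35` time units.
#'
#' Deterministic net growth rates are tied to the stochastic rates by
#' `r_S = b_S - d_S` and `r_R = b_R - d_R`; both parameterisations are kept
#' so that the ODE model and the Gillespie simulator describe the same
#' mean-field dynamics. The turnover parameters `theta_S`, `theta_R` decide
#' how crowding is split between reduced births and increased deaths in the
#' stochastic model (with `theta = b`, crowding acts purely through deaths).
#'
#' @param growth_kind Density dependence of growth: `"logistic"`
#'   (`r (1 - N/K)`), `"gompertz"` (`r log(K/N)`) or `"exponential"`
#'   (density-independent).
#' @param mu0 Baseline (drug-free) mutation rate, per cell per unit time.
#' @param alpha Slope of the dose-dependent mutation rate,
#'   per concentration unit per unit time. `alpha = 0` recovers the
#'   dose-independent (somatic-mutation-theory) limit.
#' @param b_S,d_S Intrinsic birth and death rates of sensitive cells.
#' @param b_R,d_R Intrinsic birth and death rates of resistant cells;
#'   `b_R > d_R` is required so that an established resistant lineage is
#'   viable.
#' @param d_max Maximal drug-induced kill rate (Hill plateau).
#' @param h Drug concentration yielding half of `d_max`.
#' @param k Hill coefficient (steepness) of the pharmacodynamic curve.
#' @param u_max Concentration at which the pharmacodynamic effect has
#'   plateaued.
#' @param u_MTD Maximum tolerated (instantaneous) concentration; the
#'   admissible dose set is `[0, u_MTD]`. Must satisfy `u_MTD <= u_max`.
#' @param T End of the treatment window, in time units.
#' @param K Carrying capacity (cells).
#' @param S0,R0 Initial sensitive and resistant cell counts.
#' @param theta_S,theta_R Turnover-at-capacity parameters of the stochastic
#'   model, constrained to `d <= theta <= b` componentwise so that all
#'   Gillespie propensities stay non-negative for `N <= K`.
#' @param r_S,r_R Optional explicit net growth rates; if supplied they must
#'   equal `b - d` to within 1e-12 (they are stored redundantly so that
#'   configuration files can mirror the published parameter table).
#'
#' @return An object of class `rescue_params`: a named list of all rates and
#'   constraints, validated for internal consistency.
#' @examples
#' p <- rescue_params()
#' p$S0 * p$mu0   # baseline mutation intensity at treatment start: 0.1
#' @export
rescue_params <- function(growth_kind = c("logistic", "gompertz", "exponential"),
                          mu0 = 1e-6, alpha = 1e-8,
                          b_S = 0.8, d_S = 0.3,
                          b_R = 0.5, d_R = 0.1,
                          d_max = 1.0, h = 40, k = 2.3,
                          u_max = 1000, u_MTD = 1000,
                          T = 35, K = 1e6, S0 = 1e5, R0 = 0,
                          theta_S = 0.8, theta_R = 0.5,
                          r_S = NULL, r_R = NULL) {
  growth_kind <- match.arg(growth_kind)
  p <- list(
    growth_kind = growth_kind,
    mu0 = mu0, alpha = alpha,
    b_S = b_S, d_S = d_S, r_S = if (is.null(r_S)) b_S - d_S else r_S,
    b_R = b_R, d_R = d_R, r_R = if (is.null(r_R)) b_R - d_R else r_R,
    d_max = d_max, h = h, k = k,
    u_max = u_max, u_MTD = u_MTD,
    T = T, K = K, S0 = S0, R0 = R0,
    theta_S = theta_S, theta_R = theta_R
  )
  class(p) <- "rescue_params"
  validate_params(p)
}

#' Validate a `rescue_params` object
#'
#' Enforces the cross-field invariants: consistency of the deterministic and
#' stochastic parameterisations (`r = b - d`), non-negative propensities
#' (`d <= theta <= b`), a viable resistant type (`b_R > d_R`), positivity of
#' rates and of the carrying capacity, and `0 < u_MTD <= u_max`.
#'
#' @param p A `rescue_params` object (or bare list with the same fields).
#' @return `p`, invisibly classed, if valid; otherwise an error naming the
#'   violated rule.
#' @export
validate_params <- function(p) {
  stop_rule <- function(cond, rule) if (!isTRUE(cond)) {
    stop("invalid parameters: ", rule, call. = FALSE)
  }
  num <- c("mu0", "alpha", "b_S", "d_S", "r_S", "b_R", "d_R", "r_R",
           "d_max", "h", "k", "u_max", "u_MTD", "T", "K", "S0", "R0",
           "theta_S", "theta_R")
  for (f in num) {
    stop_rule(is.numeric(p[[f]]) && length(p[[f]]) == 1 && is.finite(p[[f]]) || f == "K",
              paste0(f, " must be a finite number"))
  }
  stop_rule(p$growth_kind %in% c("logistic", "gompertz", "exponential"),
            "growth_kind must be logistic, gompertz or exponential")
  stop_rule(abs(p$r_S - (p$b_S - p$d_S)) <= 1e-12, "r_S must equal b_S - d_S")
  stop_rule(abs(p$r_R - (p$b_R - p$d_R)) <= 1e-12, "r_R must equal b_R - d_R")
  stop_rule(p$b_R > p$d_R, "b_R must exceed d_R (viable resistant type)")
  stop_rule(p$r_S > 0 && p$r_R > 0, "net growth rates r_S, r_R must be positive")
  stop_rule(p$d_S >= 0 && p$d_R >= 0, "death rates must be non-negative")
  stop_rule(p$d_S <= p$theta_S && p$theta_S <= p$b_S,
            "theta_S must lie in [d_S, b_S]")
  stop_rule(p$d_R <= p$theta_R && p$theta_R <= p$b_R,
            "theta_R must lie in [d_R, b_R]")
  stop_rule(p$mu0 > 0, "mu0 must be positive")
  stop_rule(p$alpha >= 0, "alpha must be non-negative")
  stop_rule(p$d_max > 0 && p$h > 0 && p$k > 0, "d_max, h, k must be positive")
  stop_rule(p$u_MTD > 0 && p$u_MTD <= p$u_max, "u_MTD must lie in (0, u_max]")
  stop_rule(p$K > 0, "K must be positive")
  stop_rule(p$S0 >= 0 && p$R0 >= 0, "initial counts must be non-negative")
  stop_rule(p$T > 0, "treatment window T must be positive")
  p
}

#' Rescale the model to a smaller (or larger) population size
#'
#' Applies the scale factor `c` as `K -> cK`, `S0 -> cS0`, `R0 -> cR0`,
#' `mu0 -> mu0/c`, `alpha -> alpha/c`. This keeps all per-capita rates and
#' the products `S0 * mu0` and `S(t) * mu(u)` (hence the cumulative rescue
#' intensity and cure probabilities) fixed to leading order, so virtual
#' cohorts can be simulated at desk scale.
#'
#' @param p A `rescue_params` object.
#' @param c Scale factor, e.g. `0.01` to shrink `K = 1e6` to `1e4`.
#' @return A rescaled `rescue_params` object.
#' @export
scale_params <- function(p, c) {
  stopifnot(inherits(p, "rescue_params"), is.numeric(c), c > 0)
  p$K <- p$K * c
  p$S0 <- p$S0 * c
  p$R0 <- p$R0 * c
  p$mu0 <- p$mu0 / c
  p$alpha <- p$alpha / c
  validate_params(p)
}

#' @export
print.rescue_params <- function(x, ...) {
  cat("<rescue_params> ", x$growth_kind, " growth, K = ", format(x$K),
      ", S0 = ", format(x$S0), ", R0 = ", format(x$R0), "\n", sep = "")
  cat("  growth: r_S = ", x$r_S, " (b ", x$b_S, "/d ", x$d_S,
      "), r_R = ", x$r_R, " (b ", x$b_R, "/d ", x$d_R, ")\n", sep = "")
  cat("  drug:   d_max = ", x$d_max, ", h = ", x$h, ", k = ", x$k,
      ", u_max = ", x$u_max, ", u_MTD = ", x$u_MTD, "\n", sep = "")
  cat("  mutation: mu(u) = ", format(x$mu0), " + ", format(x$alpha),
      " u ; window T = ", x$T, "\n", sep = "")
  invisible(x)
}

# Per-capita density multiplier g(N) with r_i(N) = r_i * g(N), and its
# derivative with respect to N. N is clamped away from zero for the
# gompertz log term; the multiplier itself is used only multiplied by N.
growth_multiplier <- function(N, p) {
  switch(p$growth_kind,
    logistic = 1 - N / p$K,
    gompertz = log(p$K / pmax(N, 1e-12)),
    exponential = rep(1, length(N))
  )
}

growth_multiplier_deriv <- function(N, p) {
  switch(p$growth_kind,
    logistic = rep(-1 / p$K, length(N)),
    gompertz = -1 / pmax(N, 1e-12),
    exponential = rep(0, length(N))
  )
}
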