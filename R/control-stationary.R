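#' Implicit stationary optimal control law
#'
#' Solves the stationarity condition obtained from the Hamilton-Jacobi-
#' Bellman equation of the rescue-minimisation problem,
#' \deqn{\mu(u) + \left[r(S) - d(u) - \mu(u)\right]
#'       \frac{\mu'(u)}{d'(u) + \mu'(u)} = 0,}
#' for the dose `u` at a given sensitive population size `S`. The balance is
#' between the marginal mutation-rate increase and the marginal kill-rate
#' gain weighted by the (negative) net growth rate; the root is found by
#' bracketed bisection (`uniroot`) on `(0, u_max]` to near machine
#' tolerance and clamped to `u_MTD`.
#'
#' At `S = 0` the growth rate is evaluated in the low-density limit
#' `r = r_S`, which is the exponential-decay approximation relevant during
#' effective treatment and yields the optimal constant dose.
#'
#' If the condition has no interior root (notably when `alpha = 0`, where
#' the dose-independent mutation rate removes the trade-off), the optimum is
#' on the boundary and `min(u_MTD, u_max)` is returned with attribute
#' `boundary = TRUE`.
#'
#' @param p A [rescue_params()] object; requires `alpha > 0` for an interior
#'   optimum.
#' @param S Sensitive population size at which to evaluate the law
#'   (default 0, the low-density limit).
#' @param r Optional growth-rate override; default `r_S *
#'   growth_multiplier(S)`.
#' @return The optimal dose (scalar), with attribute `boundary` flagging a
#'   boundary optimum.
#' @examples
#' stationary_dose(rescue_params())  # ~104.5
#' @export
stationary_dose <- function(p, S = 0, r = NULL) {
  stopifnot(inherits(p, "rescue_params"))
  if (is.null(r)) r <- p$r_S * growth_multiplier(S, p)
  boundary <- function() {
    structure(min(p$u_MTD, p$u_max), boundary = TRUE)
  }
  if (p$alpha <= 0) return(boundary())
  g <- function(u) {
    mutation_rate(u, p) +
      (r - death_rate(u, p) - mutation_rate(u, p)) *
        mutation_rate_deriv(u, p) /
        (death_rate_deriv(u, p) + mutation_rate_deriv(u, p))
  }
  lo <- 1e-8 * p$u_max
  if (g(lo) * g(p$u_max) > 0) return(boundary())
  root <- uniroot(g, c(lo, p$u_max), tol = 1e-10 * p$u_max)$root
  structure(min(root, p$u_MTD), boundary = FALSE)
}

#' Closed-loop control law u(S)
#'
#' Evaluates the stationary optimal dose over a grid of sensitive population
#' sizes, giving the feedback law `u(S)` that depends only on the current
#' burden. Between nodes the law is interpolated linearly (which preserves
#' the monotonicity of the node values).
#'
#' @param p A [rescue_params()] object.
#' @param S_grid Population sizes at which to solve; default 50 log-spaced
#'   points from 1 cell to `K` plus `S = 0`.
#' @return A tibble of class `control_law` with columns `S`, `u_opt`,
#'   `boundary`; attribute `"law_fun"` holds the interpolating function.
#' @export
control_law <- function(p, S_grid = NULL) {
  stopifnot(inherits(p, "rescue_params"))
  if (is.null(S_grid)) {
    S_grid <- c(0, 10^seq(0, log10(p$K), length.out = 50))
  }
  res <- purrr::map(S_grid, function(S) {
    u <- stationary_dose(p, S = S)
    tibble::tibble(S = S, u_opt = as.numeric(u),
                   boundary = isTRUE(attr(u, "boundary")))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("control_law", class(out))
  attr(out, "params") <- p
  attr(out, "law_fun") <- approxfun(out$S, out$u_opt, rule = 2)
  out
}
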