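#' Right-hand side of the two-type rescue model
#'
#' Time derivatives of the sensitive (`S`) and resistant (`R`) compartments
#' under drug concentration `u`:
#' \deqn{\dot S = r_S(N) S - d(u) S - \mu(u) S, \qquad
#'       \dot R = r_R(N) R + \mu(u) S,}
#' with `N = S + R`, density-dependent growth `r_i(N)` set by the growth
#' kind, Hill kill `d(u)` acting on sensitive cells only (complete
#' resistance), and the dose-dependent mutation flux `mu(u) S` from the
#' sensitive into the resistant compartment. Back-mutation is zero in this
#' instantiation.
#'
#' @param S,R Cell counts (non-negative).
#' @param u Drug concentration (non-negative).
#' @param p A [rescue_params()] object.
#' @return Numeric vector `c(dS, dR)`.
#' @export
rescue_rhs <- function(S, R, u, p) {
  stopifnot(S >= 0, R >= 0)
  check_dose(u)
  N <- S + R
  g <- growth_multiplier(N, p)
  m <- mutation_rate(u, p)
  dS <- p$r_S * g * S - death_rate(u, p) * S - m * S
  dR <- p$r_R * g * R + m * S
  c(dS = dS, dR = dR)
}

#' Integrate the deterministic rescue model under a dosing schedule
#'
#' Solves the two-type ODE system on `[0, T]` with `deSolve::ode` (lsoda)
#' and returns a dense trajectory suitable for quadrature of the cost
#' functionals. States are clipped at zero: the model preserves
#' non-negativity analytically, so clipping only guards numerical
#' undershoot. Inadmissible schedules (dose above `u_MTD`) are rejected.
#'
#' @param p A [rescue_params()] object.
#' @param schedule A `treatment_schedule`; default no treatment.
#' @param dt Output grid step (time units). The default 0.005 makes the
#'   composite trapezoid on the output grid accurate to ~1e-6 relative for
#'   the decay rates this model produces.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `rescue_trajectory` with columns `time`, `S`,
#'   `R`, `u`, and the parameter set in attribute `"params"`.
#' @examples
#' p <- rescue_params()
#' traj <- simulate_ode(p, schedule_constant(104.5), dt = 0.05)
#' tail(traj, 1)  # sensitive compartment eliminated by T = 35
#' @export
simulate_ode <- function(p, schedule = schedule_constant(0), dt = 0.005,
                         rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(p, "rescue_params"))
  check_schedule(schedule, p)
  times <- seq(0, p$T, by = dt)
  if (tail(times, 1) < p$T) times <- c(times, p$T)
  ufun <- function(t) sched_dose(schedule, t)
  deriv <- function(t, y, parms) {
    S <- max(y[1], 0); R <- max(y[2], 0)
    list(rescue_rhs(S, R, ufun(t), p))
  }
  sol <- deSolve::ode(c(S = p$S0, R = p$R0), times, deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop("ODE integration failed (lsoda istate = ", diag[1],
         "); tighten tolerances or shorten dt", call. = FALSE)
  }
  if (nrow(sol) < length(times)) {
    stop("ODE integration stopped early at t = ", max(sol[, 1]), call. = FALSE)
  }
  out <- tibble::tibble(
    time = sol[, 1],
    S = pmax(sol[, 2], 0),
    R = pmax(sol[, 3], 0),
    u = ufun(sol[, 1])
  )
  class(out) <- c("rescue_trajectory", class(out))
  attr(out, "params") <- p
  out
}

#' Mutation-intensity profile of a trajectory
#'
#' The pointwise rate of generating rescue mutants, `S(t) mu(u(t))`,
#' optionally multiplied by the establishment probability `pi_f` to give the
#' integrand of the cumulative rescue intensity. Under no treatment at
#' carrying capacity the profile is the constant baseline `K * mu0`; any
#' dosed schedule applied to a large population adds an early drug-induced
#' peak when `alpha > 0`, which decays as the sensitive compartment is
#' eliminated.
#'
#' @param traj A `rescue_trajectory` (from [simulate_ode()]).
#' @param p Parameters; defaults to those stored in the trajectory.
#' @param include_establishment Multiply by `pi_f` (default `FALSE`).
#' @return A tibble with columns `time`, `u`, `intensity`.
#' @export
intensity_profile <- function(traj, p = attr(traj, "params"),
                              include_establishment = FALSE) {
  stopifnot(inherits(traj, "rescue_trajectory") || all(c("time", "S", "u") %in% names(traj)))
  fac <- if (include_establishment) establishment_prob(p$b_R, p$d_R) else 1
  tibble::tibble(
    time = traj$time,
    u = traj$u,
    intensity = traj$S * mutation_rate(traj$u, p) * fac
  )
}

#' Cost functionals of a treatment trajectory
#'
#' Computes, by composite trapezoid on the trajectory grid:
#' the raw cost \eqn{C(u) = \int_0^T S \mu(u) dt} (expected number of
#' mutant establishment attempts), the discounted cost
#' \eqn{C_{disc}(u) = \int_0^T S \mu(u) e^{r_R (T - t)} dt} (proportional to
#' the expected resistant burden at the end of treatment, each mutation
#' weighted by the exponential growth its lineage can generate), the
#' cumulative rescue intensity `n_rescue = pi_f * C(u)`, and the rescue
#' probability `p_rescue = 1 - exp(-n_rescue)` (one minus the Poisson zero
#' class).
#'
#' @inheritParams intensity_profile
#' @return A one-row tibble: `cost_raw`, `cost_discounted`, `pi_f`,
#'   `n_rescue`, `p_rescue`.
#' @export
rescue_costs <- function(traj, p = attr(traj, "params")) {
  prof <- intensity_profile(traj, p)
  t_end <- tail(traj$time, 1)
  cost_raw <- trapz(prof$time, prof$intensity)
  cost_disc <- trapz(prof$time, prof$intensity * exp(p$r_R * (t_end - prof$time)))
  pi_f <- establishment_prob(p$b_R, p$d_R)
  n_rescue <- pi_f * cost_raw
  tibble::tibble(
    cost_raw = cost_raw,
    cost_discounted = cost_disc,
    pi_f = pi_f,
    n_rescue = n_rescue,
    p_rescue = 1 - exp(-n_rescue)
  )
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Fast, high-accuracy cost of a constant dose: the quadratures are carried
# as auxiliary ODE states, so the solver tolerance (not an output grid)
# controls accuracy. Sensitive-compartment dynamics only: elimination
# strategies decouple the resistant compartment from the cost.
constant_dose_costs <- function(u, p, rtol = 1e-10) {
  d_u <- death_rate(u, p)
  m_u <- mutation_rate(u, p)
  deriv <- function(t, y, parms) {
    S <- max(y[1], 0)
    dS <- p$r_S * growth_multiplier(S, p) * S - d_u * S - m_u * S
    list(c(dS, S * m_u, S * m_u * exp(p$r_R * (p$T - t))))
  }
  sol <- deSolve::ode(c(p$S0, 0, 0), c(0, p$T), deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = 1e-12 * max(p$S0, 1))
  c(raw = as.numeric(sol[2, 3]), discounted = as.numeric(sol[2, 4]))
}
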