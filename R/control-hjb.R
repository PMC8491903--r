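#' Hamilton-Jacobi-Bellman grid solver for the feedback control map
#'
#' Solves the dynamic-programming equation of the dosing problem,
#' \deqn{V_t + \min_u \left\{ S \mu(u) w(t) +
#'       V_S \left[r(S) - d(u) - \mu(u)\right] S \right\} = 0,}
#' backward from the terminal condition `V(., T) = 0`, and returns the value
#' function and the minimising dose on the grid. Because elimination
#' strategies decouple the resistant compartment (cost and dynamics depend
#' on `S` only), the state is one-dimensional.
#'
#' Discretisation: uniform grid in `log(S)` between `S_min` (default 0.1
#' cells) and `K`, plus an absorbing `S = 0` node with `V = 0` (no cells, no
#' future mutations); first-order upwind differencing of `V_S` (forward
#' where the drift is positive, backward where negative, which keeps the
#' explicit scheme monotone); explicit Euler in reverse time with the step
#' chosen from the CFL bound on the log-scale drift `r(S) - d(u) - mu(u)`.
#' The minimising dose is found by scanning a dose grid at each node, ties
#' broken towards the smallest dose (within 1e-12 in the Hamiltonian).
#'
#' For a sufficiently long treatment window the map is time-independent
#' except near `T` (a boundary effect of the fixed end-time); the solver
#' warns if the map has not become stationary at `t = 0`, which signals that
#' `T` is too short for the time-independent law to be meaningful.
#'
#' @param p A [rescue_params()] object.
#' @param objective `"rescue"` or `"discounted"`.
#' @param n_S Number of log-spaced population nodes.
#' @param S_min Smallest resolved population size (cells).
#' @param dose_step Spacing of the dose scan grid.
#' @param cfl CFL safety factor in `(0, 1)`.
#' @param n_store Number of time slices retained in the output.
#' @return A `control_map` object: list with the node vector `S`, stored
#'   times `t`, matrices `U` (optimal dose) and `V` (value) of dimension
#'   `length(S) x length(t)`, the value at the initial state `V0 =
#'   V(S0, 0)`, and diagnostics (time step, stationarity check).
#' @export
hjb_solve <- function(p, objective = c("rescue", "discounted"),
                      n_S = 301, S_min = 0.1, dose_step = 5,
                      cfl = 0.9, n_store = 36) {
  stopifnot(inherits(p, "rescue_params"))
  objective <- match.arg(objective)
  if (S_min <= 0 || S_min >= p$K) stop("S_min must lie in (0, K)", call. = FALSE)

  x <- seq(log(S_min), log(p$K), length.out = n_S)
  S <- exp(x)
  dx <- x[2] - x[1]

  dose_grid <- seq(0, min(p$u_MTD, p$u_max), by = dose_step)
  if (tail(dose_grid, 1) < p$u_MTD) dose_grid <- c(dose_grid, p$u_MTD)
  mu_g <- mutation_rate(dose_grid, p)
  d_g <- death_rate(dose_grid, p)
  r_S_nodes <- p$r_S * growth_multiplier(S, p)

  # log-scale drift a(S, u) = r(S) - d(u) - mu(u); time-independent
  A <- outer(r_S_nodes, rep(1, length(dose_grid))) -
    matrix(d_g + mu_g, n_S, length(dose_grid), byrow = TRUE)
  Apos <- pmax(A, 0)
  Aneg <- pmin(A, 0)
  B <- outer(S, mu_g)                      # running cost S * mu(u)

  amax <- max(abs(A))
  dt <- cfl * dx / amax
  n_t <- ceiling(p$T / dt)
  dt <- p$T / n_t

  store_idx <- unique(round(seq(1, n_t + 1, length.out = min(n_store, n_t + 1))))
  tgrid <- p$T - (seq_len(n_t + 1) - 1) * dt   # backward clock
  Ustore <- matrix(NA_real_, n_S, length(store_idx))
  Vstore <- matrix(NA_real_, n_S, length(store_idx))
  tstore <- tgrid[store_idx]

  V <- numeric(n_S)                        # V(., T) = 0
  Vbound <- max(B) * p$T * exp(max(0, p$r_R) * p$T) * 10 + 1

  si <- 1L
  if (store_idx[1] == 1L) {
    # at t = T nothing remains to optimise; the running cost alone is
    # minimised by the smallest dose
    Ustore[, 1] <- 0
    Vstore[, 1] <- V
    si <- 2L
  }

  for (n in seq_len(n_t)) {
    t_now <- p$T - n * dt
    w <- if (objective == "rescue") 1 else exp(p$r_R * (p$T - t_now))
    # upwind differences in x; V = 0 beyond the bottom node (absorbing),
    # zero-gradient at the top
    Dp <- c((V[-1] - V[-n_S]) / dx, 0)
    Dm <- c(V[1] / dx, (V[-1] - V[-n_S]) / dx)
    H <- B * w + Apos * Dp + Aneg * Dm
    jmin <- max.col(-H, ties.method = "first")
    rowmin <- H[cbind(seq_len(n_S), jmin)]
    idx <- max.col(H <= rowmin + 1e-12, ties.method = "first")
    V <- V + dt * rowmin
    if (any(!is.finite(V)) || max(abs(V)) > Vbound) {
      stop("HJB time-stepping became unstable; refine the grid ",
           "(increase n_S or lower cfl)", call. = FALSE)
    }
    step_i <- n + 1L
    if (si <= length(store_idx) && store_idx[si] == step_i) {
      Ustore[, si] <- dose_grid[idx]
      Vstore[, si] <- V
      si <- si + 1L
    }
  }

  # stored columns run from t = T down to t = 0; flip to forward time
  ord <- order(tstore)
  res <- structure(list(
    S = S, t = tstore[ord],
    U = Ustore[, ord, drop = FALSE], V = Vstore[, ord, drop = FALSE],
    V0 = approx(x, V, xout = log(p$S0), rule = 2)$y,
    objective = objective, params = p,
    diagnostics = list(dt = dt, n_t = n_t, dose_grid = dose_grid)
  ), class = "control_map")

  # stationarity at t = 0: compare the first two stored slices
  early <- abs(res$U[, 1] - res$U[, 2])
  res$diagnostics$stationary_at_0 <- max(early) <= dose_step
  if (!res$diagnostics$stationary_at_0) {
    warning("control map is not stationary at t = 0; ",
            "the treatment window T may be too short")
  }
  res
}

#' @export
print.control_map <- function(x, ...) {
  cat("<control_map> ", x$objective, " objective, ", length(x$S),
      " population nodes x ", length(x$t), " stored times\n", sep = "")
  cat("  V(S0, 0) = ", format(x$V0), "; dt = ", format(x$diagnostics$dt),
      " (", x$diagnostics$n_t, " steps)\n", sep = "")
  invisible(x)
}

#' Stationary (early/mid-treatment) slice of a control map
#'
#' @param map A `control_map` from [hjb_solve()].
#' @param t_frac Fraction of the window at which to take the slice
#'   (default 0.4, safely away from the end-time boundary layer).
#' @return A tibble `S`, `u_opt`.
#' @export
hjb_stationary_slice <- function(map, t_frac = 0.4) {
  stopifnot(inherits(map, "control_map"))
  j <- which.min(abs(map$t - t_frac * max(map$t)))
  tibble::tibble(S = map$S, u_opt = map$U[, j])
}
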