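#' Optimal constant dose
#'
#' Minimises a cost functional over constant treatment strategies by a
#' coarse dose grid followed by golden-section refinement. Each evaluation
#' integrates the sensitive-compartment dynamics from the configured initial
#' condition to `T`, carrying the cost integral as an auxiliary ODE state.
#'
#' Two objectives are supported: `"rescue"` (the raw cumulative mutation
#' intensity, whose minimiser also minimises the rescue probability) and
#' `"discounted"` (each mutation weighted by `exp(r_R (T - t))`, the
#' exponential growth a resistant lineage founded at `t` can generate by the
#' end of treatment; its minimiser minimises the expected resistant burden
#' at `T`).
#'
#' With `alpha = 0` the cost is monotone decreasing in the dose and the
#' optimum sits on the boundary `u_MTD` (the maximum-tolerated-dose
#' strategy); with `alpha > 0` the drug-induced mutational surplus makes the
#' cost non-monotone and an intermediate dose optimal.
#'
#' @param p A [rescue_params()] object.
#' @param objective `"rescue"` or `"discounted"`.
#' @param dose_bounds Admissible dose interval, a subset of `(0, u_MTD]`.
#' @param grid_step Coarse grid spacing (concentration units).
#' @param tol Absolute tolerance of the golden-section refinement.
#' @return A `control_solution` (kind `"constant"`): the optimal dose, its
#'   raw and discounted costs, `n_rescue`, `p_rescue`, and diagnostics
#'   including the coarse cost curve and a multimodality flag.
#' @examples
#' \donttest{
#' sol <- optimize_constant_dose(rescue_params(), "rescue")
#' glance(sol)
#' }
#' @export
optimize_constant_dose <- function(p, objective = c("rescue", "discounted"),
                                   dose_bounds = c(0, p$u_MTD),
                                   grid_step = 1, tol = 0.01) {
  stopifnot(inherits(p, "rescue_params"))
  objective <- match.arg(objective)
  if (dose_bounds[1] < 0 || dose_bounds[2] > p$u_MTD + 1e-9) {
    stop("dose_bounds must lie within [0, u_MTD]", call. = FALSE)
  }
  pick <- if (objective == "rescue") "raw" else "discounted"
  fcost <- function(u) unname(constant_dose_costs(u, p)[pick])

  grid <- seq(max(dose_bounds[1], grid_step), dose_bounds[2], by = grid_step)
  cost_grid <- vapply(grid, fcost, numeric(1))
  i0 <- which.min(cost_grid)

  # local minima on the coarse grid (interior sign changes of the slope)
  dsign <- sign(diff(cost_grid))
  n_min <- sum(diff(dsign) > 0) + (dsign[1] > 0) +
    (dsign[length(dsign)] < 0)
  multimodal <- n_min > 1

  lo <- grid[max(i0 - 1L, 1L)]
  hi <- grid[min(i0 + 1L, length(grid))]
  if (lo == hi) {
    u_opt <- lo
  } else {
    opt <- optimize(fcost, c(lo, hi), tol = tol)
    u_opt <- opt$minimum
    # golden search can stall at an interior point worse than the grid node
    if (fcost(u_opt) > cost_grid[i0]) u_opt <- grid[i0]
  }
  both <- constant_dose_costs(u_opt, p)
  pi_f <- establishment_prob(p$b_R, p$d_R)
  n_rescue <- pi_f * both[["raw"]]
  boundary <- abs(u_opt - dose_bounds[2]) < grid_step / 2 && i0 == length(grid)

  new_control_solution(
    kind = "constant",
    objective = objective,
    u_opt = u_opt,
    cost = unname(both[[pick]]),
    cost_raw = both[["raw"]],
    cost_discounted = both[["discounted"]],
    n_rescue = n_rescue,
    p_rescue = 1 - exp(-n_rescue),
    params = p,
    diagnostics = list(
      grid = tibble::tibble(dose = grid, cost = cost_grid),
      multimodal = multimodal,
      boundary = boundary
    )
  )
}

new_control_solution <- function(kind, objective, u_opt, cost, cost_raw,
                                 cost_discounted, n_rescue, p_rescue, params,
                                 schedule = NULL, diagnostics = list()) {
  structure(
    list(kind = kind, objective = objective, u_opt = u_opt, cost = cost,
         cost_raw = cost_raw, cost_discounted = cost_discounted,
         n_rescue = n_rescue, p_rescue = p_rescue, schedule = schedule,
         params = params, diagnostics = diagnostics),
    class = "control_solution"
  )
}

#' @export
print.control_solution <- function(x, ...) {
  cat("<control_solution> kind = ", x$kind, ", objective = ", x$objective,
      "\n", sep = "")
  if (!is.null(x$u_opt)) cat("  optimal dose u* = ", format(x$u_opt), "\n", sep = "")
  cat("  achieved cost = ", format(x$cost),
      " (n_rescue = ", format(x$n_rescue),
      ", p_rescue = ", format(x$p_rescue), ")\n", sep = "")
  if (!is.null(x$diagnostics$iterations)) {
    cat("  solver: ", x$diagnostics$iterations, " iterations, residual ",
        format(tail(x$diagnostics$residuals, 1)), "\n", sep = "")
  }
  invisible(x)
}
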