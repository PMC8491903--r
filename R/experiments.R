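#' Mutation-intensity profiles across constant doses
#'
#' Integrates the deterministic model at each constant dose and emits the
#' time-resolved rate of generating rescue mutants, `S(t) mu(u)`. The
#' untreated baseline asymptotes to `K mu0`; dosed profiles trade a higher
#' drug-induced early peak against a faster-closing rescue window. The area
#' under each profile is the raw cost `C(u)`.
#'
#' @param p A [rescue_params()] object.
#' @param doses Constant doses; the default set spans no treatment,
#'   below-optimal, near-optimal and plateau regimes.
#' @param dt Output grid step.
#' @return A tibble `dose, time, intensity`.
#' @export
intensity_experiment <- function(p, doses = c(0, 30, 60, 104.5, 300, 1000),
                                 dt = 0.01) {
  stopifnot(inherits(p, "rescue_params"))
  purrr::map_dfr(doses, function(u) {
    traj <- simulate_ode(p, schedule_constant(u), dt = dt)
    prof <- intensity_profile(traj, p)
    tibble::tibble(dose = u, time = prof$time, intensity = prof$intensity)
  })
}

#' Relative-cost contour over mutagenicity and dose
#'
#' For each mutation-rate slope `alpha`, evaluates the cost of every
#' constant dose on a grid and locates the optimal constant dose, yielding
#' the relative cumulative mutation intensity `C(u; alpha)/C(u*; alpha)`
#' (>= 1, with equality along the optimal-dose curve) and the fold change
#' `mu(u; alpha)/mu0` of the mutation rate. Doses at which the optimum sits
#' on the admissibility boundary are flagged.
#'
#' @param p A [rescue_params()] object (its `alpha` is overridden by the
#'   grid).
#' @param alpha_grid Mutation-slope values; default 25 log-spaced points
#'   spanning `1e-9` to `1e-7`.
#' @param dose_grid Constant doses; default 200 points on `[1, u_max]`.
#' @param levels Contour levels of the relative cost.
#' @return A `contour_result`: list with `grid` (tibble `alpha, dose, cost,
#'   relative_cost, fold_change`), `optimal` (tibble `alpha, u_opt,
#'   cost_opt, boundary`), and `levels`.
#' @export
contour_experiment <- function(p,
                               alpha_grid = 10^seq(-9, -7, length.out = 25),
                               dose_grid = seq(1, p$u_max, length.out = 200),
                               levels = c(1, 1.25, 1.5, 2, 3, 4, 5)) {
  stopifnot(inherits(p, "rescue_params"))
  per_alpha <- purrr::map(alpha_grid, function(a) {
    pa <- p
    pa$alpha <- a
    pa <- validate_params(pa)
    cost <- vapply(dose_grid, function(u) {
      unname(constant_dose_costs(u, pa)["raw"])
    }, numeric(1))
    i0 <- which.min(cost)
    lo <- dose_grid[max(i0 - 1L, 1L)]
    hi <- dose_grid[min(i0 + 1L, length(dose_grid))]
    fc <- function(u) unname(constant_dose_costs(u, pa)["raw"])
    if (lo < hi) {
      opt <- optimize(fc, c(lo, hi), tol = 0.01)
      u_opt <- opt$minimum
      c_opt <- opt$objective
      if (c_opt > cost[i0]) { u_opt <- dose_grid[i0]; c_opt <- cost[i0] }
    } else {
      u_opt <- dose_grid[i0]; c_opt <- cost[i0]
    }
    boundary <- i0 == length(dose_grid)
    list(
      grid = tibble::tibble(
        alpha = a, dose = dose_grid, cost = cost,
        relative_cost = cost / c_opt,
        fold_change = mutation_rate(dose_grid, pa) / pa$mu0
      ),
      optimal = tibble::tibble(alpha = a, u_opt = u_opt, cost_opt = c_opt,
                               boundary = boundary)
    )
  })
  structure(list(
    grid = dplyr::bind_rows(purrr::map(per_alpha, "grid")),
    optimal = dplyr::bind_rows(purrr::map(per_alpha, "optimal")),
    levels = levels, params = p
  ), class = "contour_result")
}

#' @export
print.contour_result <- function(x, ...) {
  cat("<contour_result> ", length(unique(x$grid$alpha)), " alpha x ",
      length(unique(x$grid$dose)), " dose grid\n", sep = "")
  print(x$optimal, ...)
  invisible(x)
}

#' Stochastic dose sweep with deterministic overlay
#'
#' Runs virtual-treatment cohorts over a dose grid and joins the
#' deterministic prediction of the cure probability, `exp(-n_rescue(u))`
#' (the Poisson zero class of the cumulative rescue intensity), to the
#' simulated cure fractions. The default runs at desk scale `c = 0.01`
#' (carrying capacity `1e4`), which preserves per-capita rates and the
#' products `S mu` that determine rescue probabilities; `scale = 1`
#' restores the full-size configuration (long-running).
#'
#' @param p A [rescue_params()] object.
#' @param doses Constant doses to sweep.
#' @param n_sim Replicates per dose.
#' @param seed Base seed.
#' @param scale Down-scaling factor (default 0.01).
#' @param ... Passed to [run_cohort()].
#' @return A `dose_sweep` object: the underlying `cohort_result` plus a
#'   `summary` with the predicted cure probability per dose and the
#'   establishment-fraction table.
#' @export
dose_sweep_experiment <- function(p, doses = c(20, 30, 45, 60, 80, 104.5,
                                               150, 250, 400),
                                  n_sim = 500, seed = 1, scale = 0.01, ...) {
  stopifnot(inherits(p, "rescue_params"))
  cohort <- run_cohort(p, doses, n_sim = n_sim, seed = seed, scale = scale, ...)
  ps <- cohort$params
  predicted <- vapply(doses, function(u) {
    pi_f <- establishment_prob(ps$b_R, ps$d_R)
    exp(-pi_f * unname(constant_dose_costs(u, ps)["raw"]))
  }, numeric(1))
  summ <- dplyr::left_join(
    cohort$summary,
    tibble::tibble(dose = doses, predicted_cure = predicted),
    by = "dose"
  )
  structure(list(cohort = cohort, summary = summ,
                 establishment = establishment_fraction(cohort),
                 params = ps, seed = seed),
            class = "dose_sweep")
}

#' @export
print.dose_sweep <- function(x, ...) {
  cat("<dose_sweep> simulated vs predicted cure by dose\n")
  print(dplyr::select(x$summary, "dose", "n_sim", "cure_fraction",
                      "cure_lo", "cure_hi", "predicted_cure",
                      "mean_final_N_over_K"), ...)
  invisible(x)
}
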