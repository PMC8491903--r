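#' Tidy a control solution
#'
#' Returns the solution's schedule or cost curve as a tibble: for an
#' open-loop (forward-backward sweep) solution, the time grid with the
#' optimal dose, states and multipliers; for a constant-dose solution, the
#' coarse dose-cost curve explored by the optimiser.
#'
#' @param x A `control_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy control_solution
#' @export
tidy.control_solution <- function(x, ...) {
  if (!is.null(x$schedule)) return(tibble::as_tibble(x$schedule))
  x$diagnostics$grid
}

#' One-row summary of a control solution
#'
#' @param x A `control_solution`.
#' @param ... Unused.
#' @return A one-row tibble: kind, objective, optimal dose (for constant
#'   solutions), achieved costs, rescue intensity and probability, and
#'   solver diagnostics.
#' @method glance control_solution
#' @export
glance.control_solution <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    objective = x$objective,
    u_opt = if (is.null(x$u_opt)) NA_real_ else x$u_opt,
    cost = x$cost,
    cost_raw = x$cost_raw,
    cost_discounted = x$cost_discounted,
    n_rescue = x$n_rescue,
    p_rescue = x$p_rescue,
    iterations = x$diagnostics$iterations %||% NA_integer_,
    converged = x$diagnostics$converged %||% NA,
    multimodal = x$diagnostics$multimodal %||% NA
  )
}

#' Tidy a feedback control map
#'
#' @param x A `control_map` from [hjb_solve()].
#' @param ... Unused.
#' @return A long tibble `S, t, u_opt, value`.
#' @method tidy control_map
#' @export
tidy.control_map <- function(x, ...) {
  tibble::tibble(
    S = rep(x$S, times = length(x$t)),
    t = rep(x$t, each = length(x$S)),
    u_opt = as.vector(x$U),
    value = as.vector(x$V)
  )
}

#' Per-dose summary of a virtual-treatment cohort
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return The per-dose summary tibble.
#' @method tidy cohort_result
#' @export
tidy.cohort_result <- function(x, ...) {
  x$summary
}

#' One-row summary of a cohort run
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return A one-row tibble with cohort size and the range of cure
#'   fractions.
#' @method glance cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    n_doses = nrow(x$summary),
    n_replicates = nrow(x$replicates),
    cure_min = min(x$summary$cure_fraction),
    cure_max = max(x$summary$cure_fraction),
    K = x$params$K,
    seed = x$seed
  )
}

#' Tidy a relative-cost contour
#'
#' @param x A `contour_result`.
#' @param ... Unused.
#' @return The long grid tibble `alpha, dose, cost, relative_cost,
#'   fold_change`.
#' @method tidy contour_result
#' @export
tidy.contour_result <- function(x, ...) {
  x$grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
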