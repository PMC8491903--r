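#' Gillespie event propensities
#'
#' The five event rates of the stochastic birth-death-mutation model at a
#' given state and dose: sensitive birth and death, resistant birth and
#' death, and the sensitive-to-resistant mutation. Crowding is split
#' between births and deaths by the turnover parameters `theta`:
#' \deqn{\beta_S = (b_S - (b_S-\theta_S)N/K)S, \quad
#'       \delta_S = (d_S + (\theta_S-d_S)N/K + d(u))S,}
#' and analogously for resistant cells (which the drug does not kill), with
#' the mutation propensity `mu(u) S` decoupled from birth events. Each rate
#' is clamped at zero (states with `N > K` occur stochastically). Their
#' mean-field drift reproduces the deterministic model exactly:
#' `(beta_S - delta_S - mu S)/S = r_S (1 - N/K) - d(u) - mu(u)` for the
#' logistic parameterisation.
#'
#' @param S,R Integer cell counts.
#' @param u Drug concentration.
#' @param p A [rescue_params()] object.
#' @return Named numeric vector `beta_S, delta_S, beta_R, delta_R, mutation`.
#' @export
ssa_propensities <- function(S, R, u, p) {
  stopifnot(S >= 0, R >= 0)
  check_dose(u)
  f <- (S + R) / p$K
  c(beta_S = max((p$b_S - (p$b_S - p$theta_S) * f) * S, 0),
    delta_S = max((p$d_S + (p$theta_S - p$d_S) * f + death_rate(u, p)) * S, 0),
    beta_R = max((p$b_R - (p$b_R - p$theta_R) * f) * R, 0),
    delta_R = max((p$d_R + (p$theta_R - p$d_R) * f) * R, 0),
    mutation = max(mutation_rate(u, p) * S, 0))
}

#' Exact stochastic simulation of one virtual treatment
#'
#' Runs the Gillespie algorithm for the two-type model from `(S0, R0)` until
#' `t = T` or absorption at `(0, 0)` (a cure), under an admissible dosing
#' schedule. Constant and piecewise-constant schedules are simulated
#' exactly; a tabulated schedule is frozen on segments no longer than
#' `dt_max`. Every mutation event founds its own resistant lineage whose
#' fate is tracked, so establishment can be read off per event.
#'
#' @param p A [rescue_params()] object.
#' @param schedule A `treatment_schedule` (default: no treatment).
#' @param seed Integer seed; required, so every replicate is reproducible.
#' @param scale Optional down-scaling factor passed to [scale_params()].
#' @param t_end Simulation end time (default `p$T`).
#' @param dt_max Rate-freezing step for tabulated schedules.
#' @param max_events Safety cap on the event count; exceeding it aborts the
#'   replicate with an error (guards untreated runs at carrying capacity).
#' @param track_lineages Track per-lineage fates (default `TRUE`).
#' @return An object of class `ssa_outcome`: list with `final_S`,
#'   `final_R`, `t_final`, `extinct`, `mutation_times`, `lineage_alive`,
#'   `first_established` (time of the first mutation whose lineage is alive
#'   at the end, `NA` if none), `n_events`, `seed`.
#' @examples
#' out <- ssa_run(rescue_params(), schedule_constant(104.5), seed = 1,
#'                scale = 0.01)
#' out$extinct
#' @export
ssa_run <- function(p, schedule = schedule_constant(0), seed,
                    scale = NULL, t_end = NULL, dt_max = 0.01,
                    max_events = 5e7, track_lineages = TRUE) {
  stopifnot(inherits(p, "rescue_params"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (!is.null(scale)) p <- scale_params(p, scale)
  check_schedule(schedule, p)
  if (is.null(t_end)) t_end <- p$T
  segs <- as_segments(schedule, t_end, dt_max)
  set.seed(seed)
  res <- ssa_core(round(p$S0), round(p$R0), t_end,
                  segs$start, death_rate(segs$dose, p),
                  mutation_rate(segs$dose, p),
                  p$b_S, p$d_S, p$theta_S, p$b_R, p$d_R, p$theta_R,
                  p$K, max_events, track_lineages)
  if (res$status == 1) {
    stop("replicate aborted: event count exceeded max_events = ",
         format(max_events), " at t = ", format(res$t_final), call. = FALSE)
  }
  alive <- as.logical(res$lineage_alive)
  first_est <- if (track_lineages && any(alive)) {
    min(res$mutation_times[alive])
  } else NA_real_
  structure(list(
    final_S = res$final_S, final_R = res$final_R, t_final = res$t_final,
    extinct = res$extinct, mutation_times = res$mutation_times,
    lineage_alive = alive, first_established = first_est,
    n_events = res$n_events, seed = seed
  ), class = "ssa_outcome")
}

#' @export
print.ssa_outcome <- function(x, ...) {
  cat("<ssa_outcome> ", if (x$extinct) "extinct (cure)" else "surviving",
      " at t = ", format(x$t_final), "\n", sep = "")
  cat("  final S = ", x$final_S, ", R = ", x$final_R, "; ",
      length(x$mutation_times), " mutation event(s), ",
      sum(x$lineage_alive), " established\n", sep = "")
  invisible(x)
}

#' Cohorts of virtual treatments over a dose grid
#'
#' Simulates `n_sim` independent virtual treatments at each constant dose
#' and summarises the outcomes: the cure fraction (proportion of replicates
#' with `N(T) = 0`) with an exact binomial confidence interval, the mean
#' normalised final size `N(T)/K` of the rescued (non-extinct) replicates,
#' and the establishment fraction among mutation events. Replicate `j` at
#' dose index `i` uses seed `seed + (i - 1) * n_sim + (j - 1)`, so cohorts
#' are reproducible and extensible without seed collisions.
#'
#' @param p A [rescue_params()] object.
#' @param doses Constant doses to sweep.
#' @param n_sim Replicates per dose.
#' @param seed Base seed.
#' @param scale Optional down-scaling factor ([scale_params()]); `0.01` is
#'   the desk-scale default used throughout the package's experiments.
#' @param conf_level Confidence level of the binomial interval.
#' @param ... Passed to [ssa_run()] (e.g. `max_events`).
#' @return A `cohort_result`: list with `replicates` (one row per virtual
#'   treatment), `summary` (one row per dose), the scaled parameter set and
#'   the seed. Replicates aborted at the event cap are counted in
#'   `n_aborted` and excluded from the summaries.
#' @export
run_cohort <- function(p, doses, n_sim = 500, seed = 1, scale = NULL,
                       conf_level = 0.95, ...) {
  stopifnot(inherits(p, "rescue_params"))
  if (n_sim < 1) stop("n_sim must be at least 1", call. = FALSE)
  if (!is.null(scale)) p <- scale_params(p, scale)
  reps <- purrr::map_dfr(seq_along(doses), function(i) {
    purrr::map_dfr(seq_len(n_sim), function(j) {
      s <- seed + (i - 1L) * n_sim + (j - 1L)
      out <- tryCatch(
        ssa_run(p, schedule_constant(doses[i]), seed = s, ...),
        error = function(e) e
      )
      if (inherits(out, "error")) {
        return(tibble::tibble(dose = doses[i], replicate = j, seed = s,
                              final_S = NA_real_, final_R = NA_real_,
                              final_N = NA_real_, extinct = NA,
                              n_mutations = NA_integer_,
                              n_established = NA_integer_,
                              first_established = NA_real_, aborted = TRUE))
      }
      tibble::tibble(
        dose = doses[i], replicate = j, seed = s,
        final_S = out$final_S, final_R = out$final_R,
        final_N = out$final_S + out$final_R,
        extinct = out$extinct,
        n_mutations = length(out$mutation_times),
        n_established = sum(out$lineage_alive),
        first_established = out$first_established,
        aborted = FALSE
      )
    })
  })
  summ <- reps |>
    dplyr::filter(!.data$aborted) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      n_sim = dplyr::n(),
      n_cured = sum(.data$extinct),
      cure_fraction = n_cured / n_sim,
      cure_lo = binom.test(n_cured, n_sim,
                           conf.level = conf_level)$conf.int[1],
      cure_hi = binom.test(n_cured, n_sim,
                           conf.level = conf_level)$conf.int[2],
      n_rescued = sum(!.data$extinct),
      mean_final_N_over_K = ifelse(n_rescued > 0,
                                   mean(.data$final_N[!.data$extinct]) / p$K,
                                   NA_real_),
      n_mutation_events = sum(.data$n_mutations),
      n_established = sum(.data$n_established),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_aborted = vapply(.data$dose, function(d) {
      sum(reps$aborted[reps$dose == d])
    }, integer(1)))
  structure(list(replicates = reps, summary = summ, params = p, seed = seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", length(unique(x$summary$dose)), " dose(s) x ",
      max(x$summary$n_sim), " replicates (K = ", format(x$params$K), ")\n",
      sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Establishment fraction per dose
#'
#' The fraction of mutation events whose resistant lineage is alive at the
#' end of treatment, per dose, with an exact binomial confidence interval.
#' Under complete resistance this fraction should sit near the
#' branching-process establishment probability `pi_f = 1 - d_R/b_R`
#' independently of the dose. Doses with no mutation events are reported
#' with `NA` fractions.
#'
#' @param cohort A `cohort_result` from [run_cohort()].
#' @param conf_level Confidence level.
#' @return A tibble `dose, n_mutations, n_established, fraction, lo, hi`.
#' @export
establishment_fraction <- function(cohort, conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort_result"))
  cohort$replicates |>
    dplyr::filter(!.data$aborted) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(n_mutations = sum(.data$n_mutations),
                     n_established = sum(.data$n_established),
                     .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      fraction = ifelse(.data$n_mutations > 0,
                        .data$n_established / .data$n_mutations, NA_real_),
      lo = ifelse(.data$n_mutations > 0,
                  binom.test(.data$n_established, .data$n_mutations,
                             conf.level = conf_level)$conf.int[1], NA_real_),
      hi = ifelse(.data$n_mutations > 0,
                  binom.test(.data$n_established, .data$n_mutations,
                             conf.level = conf_level)$conf.int[2], NA_real_)
    ) |>
    dplyr::ungroup()
}
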