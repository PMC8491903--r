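#' Treatment schedules
#'
#' A treatment schedule is a bounded dosing function `u(t)` on the treatment
#' window. Three representations are supported: a constant dose, a
#' piecewise-constant schedule (dose changes at breakpoints), and a
#' tabulated `(t, u)` curve with a stated interpolation rule. Admissibility
#' (`0 <= u(t) <= u_MTD`) is checked against a parameter set whenever a
#' schedule is used.
#'
#' @param u Constant dose (for `schedule_constant`).
#' @param times For `schedule_piecewise`, segment start times (first must be
#'   0; doses are held constant between consecutive starts). For
#'   `schedule_table`, the tabulated time grid.
#' @param doses Dose per segment (`schedule_piecewise`) or per tabulated
#'   time (`schedule_table`).
#' @param rule Interpolation rule for tabulated schedules: `"linear"` or
#'   `"constant"` (left-continuous step).
#' @return A `treatment_schedule` object.
#' @examples
#' schedule_constant(104.5)
#' schedule_piecewise(c(0, 10, 20), c(200, 100, 50))
#' @name schedules
NULL

#' @rdname schedules
#' @export
schedule_constant <- function(u) {
  check_dose(u)
  stopifnot(length(u) == 1)
  structure(list(kind = "constant", u = u), class = "treatment_schedule")
}

#' @rdname schedules
#' @export
schedule_piecewise <- function(times, doses) {
  check_dose(doses)
  if (length(times) != length(doses) || length(times) < 1) {
    stop("times and doses must have equal positive length", call. = FALSE)
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("segment start times must be strictly increasing from 0", call. = FALSE)
  }
  structure(list(kind = "piecewise", times = times, doses = doses),
            class = "treatment_schedule")
}

#' @rdname schedules
#' @export
schedule_table <- function(times, doses, rule = c("linear", "constant")) {
  rule <- match.arg(rule)
  check_dose(doses)
  if (length(times) != length(doses) || length(times) < 2) {
    stop("need at least two (t, u) pairs", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("tabulated times must be strictly increasing", call. = FALSE)
  }
  structure(list(kind = "table", times = times, doses = doses, rule = rule),
            class = "treatment_schedule")
}

#' Evaluate a schedule at given times
#'
#' @param sched A `treatment_schedule`.
#' @param t Time(s) at which to evaluate the dose.
#' @return Dose(s) at `t`. Outside the tabulated/segment range the nearest
#'   value is held.
#' @export
sched_dose <- function(sched, t) {
  stopifnot(inherits(sched, "treatment_schedule"))
  switch(sched$kind,
    constant = rep(sched$u, length(t)),
    piecewise = {
      idx <- findInterval(t, sched$times, rightmost.closed = FALSE)
      sched$doses[pmax(idx, 1L)]
    },
    table = approx(sched$times, sched$doses, xout = t, rule = 2,
                   method = if (sched$rule == "linear") "linear" else "constant")$y
  )
}

#' @export
print.treatment_schedule <- function(x, ...) {
  desc <- switch(x$kind,
    constant = paste0("constant dose u = ", x$u),
    piecewise = paste0(length(x$doses), " piecewise-constant segments"),
    table = paste0("tabulated, ", length(x$times), " points (", x$rule, ")"))
  cat("<treatment_schedule> ", desc, "\n", sep = "")
  invisible(x)
}

# Maximum dose a schedule can take (for admissibility checks).
sched_max_dose <- function(sched) {
  switch(sched$kind,
    constant = sched$u,
    piecewise = max(sched$doses),
    table = max(sched$doses))
}

check_schedule <- function(sched, p) {
  stopifnot(inherits(sched, "treatment_schedule"))
  if (sched_max_dose(sched) > p$u_MTD + 1e-9) {
    stop("schedule is inadmissible: dose exceeds u_MTD = ", p$u_MTD,
         call. = FALSE)
  }
  invisible(sched)
}

# Reduce any schedule to piecewise-constant segments on [0, t_end] for the
# exact stochastic simulator. Constant and piecewise schedules map one to
# one (the SSA is then exact); a tabulated schedule is frozen on a grid of
# step at most dt_max, evaluated at segment midpoints.
as_segments <- function(sched, t_end, dt_max = 0.01) {
  switch(sched$kind,
    constant = list(start = 0, dose = sched$u),
    piecewise = {
      keep <- sched$times < t_end
      list(start = sched$times[keep], dose = sched$doses[keep])
    },
    table = {
      n <- max(2L, ceiling(t_end / dt_max))
      edges <- seq(0, t_end, length.out = n + 1L)
      mid <- (edges[-1] + edges[-(n + 1L)]) / 2
      list(start = edges[-(n + 1L)], dose = sched_dose(sched, mid))
    })
}
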