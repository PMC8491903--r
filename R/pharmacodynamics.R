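#' Hill pharmacodynamics: drug-induced kill rate
#'
#' The per-capita death rate induced by drug concentration `u` follows a
#' saturating Hill curve \deqn{d(u) = d_{max}\left(1 - \frac{1}{1 +
#' (u/h)^k}\right),} so `d(0) = 0`, `d(h) = d_max / 2`, and `d` increases
#' monotonically towards the plateau `d_max`. The bounded leverage of
#' molecular binding is what makes intermediate doses competitive: past the
#' plateau, extra drug adds mutagenicity but no extra kill.
#'
#' @param u Drug concentration(s), non-negative.
#' @param p A [rescue_params()] object supplying `d_max`, `h`, `k`.
#' @return Kill rate(s) per unit time, same length as `u`.
#' @seealso [death_rate_deriv()] for the analytic slope `d'(u)`.
#' @examples
#' p <- rescue_params()
#' death_rate(c(0, 40), p)   # 0 and d_max/2
#' @export
death_rate <- function(u, p) {
  check_dose(u)
  x <- (u / p$h)^p$k
  p$d_max * x / (1 + x)
}

#' Analytic derivative of the Hill kill rate
#'
#' @inheritParams death_rate
#' @return `d'(u)`, per unit time per concentration unit; finite and
#'   non-negative for `u > 0` (and for `u = 0` when `k >= 1`).
#' @export
death_rate_deriv <- function(u, p) {
  check_dose(u)
  out <- numeric(length(u))
  pos <- u > 0
  x <- (u[pos] / p$h)^p$k
  out[pos] <- p$d_max * p$k * x / (u[pos] * (1 + x)^2)
  if (any(!pos)) out[!pos] <- if (p$k > 1) 0 else if (p$k == 1) p$d_max / p$h else Inf
  out
}

#' Dose-dependent phenotypic mutation rate
#'
#' The rate at which sensitive cells transition to the resistant phenotype,
#' `mu(u) = mu0 + alpha * u`: a drug-free baseline plus a linear
#' drug-induced surplus. `alpha = 0` recovers the classical dose-independent
#' assumption under which the maximum tolerated dose is trivially optimal.
#'
#' @inheritParams death_rate
#' @return Mutation rate(s) per cell per unit time.
#' @export
mutation_rate <- function(u, p) {
  check_dose(u)
  p$mu0 + p$alpha * u
}

#' Slope of the dose-dependent mutation rate
#'
#' @inheritParams death_rate
#' @return `mu'(u) = alpha`, recycled to the length of `u`.
#' @export
mutation_rate_deriv <- function(u, p) {
  check_dose(u)
  rep(p$alpha, length(u))
}

#' Establishment probability of a resistant lineage
#'
#' A lineage founded by a single resistant cell with intrinsic birth rate
#' `b_R` and death rate `d_R` escapes stochastic extinction with probability
#' \deqn{\pi_f = 1 - d_R / b_R,} the classical survival probability of a
#' supercritical branching process. Treated as a dose-independent constant
#' of the resistant cell (complete resistance).
#'
#' @param b_R Intrinsic birth rate of resistant cells (positive).
#' @param d_R Intrinsic death rate of resistant cells, `0 <= d_R <= b_R`.
#' @return Establishment probability in `[0, 1]`.
#' @examples
#' establishment_prob(0.5, 0.1)  # 0.8
#' @export
establishment_prob <- function(b_R, d_R) {
  if (!is.numeric(b_R) || !is.numeric(d_R) || b_R <= 0 || d_R < 0) {
    stop("b_R must be positive and d_R non-negative", call. = FALSE)
  }
  if (d_R > b_R) {
    stop("d_R > b_R: resistant type is subcritical, rescue impossible under ",
         "this model", call. = FALSE)
  }
  1 - d_R / b_R
}

check_dose <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0)) {
    stop("drug concentration u must be finite and non-negative", call. = FALSE)
  }
  invisible(u)
}
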