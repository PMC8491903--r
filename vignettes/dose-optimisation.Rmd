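---
title: "Optimal dosing against drug-induced evolutionary rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal dosing against drug-induced evolutionary rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorescue)
```

## The model

`evorescue` studies a treated cell population (tumour cells, bacteria)
consisting of drug-sensitive cells $S$ and resistant cells $R$ in a niche
of carrying capacity $K$:

$$
\dot S = r_S(N)\,S - d(u)\,S - \mu(u)\,S, \qquad
\dot R = r_R(N)\,R + \mu(u)\,S, \qquad N = S + R .
$$

Three ingredients drive everything:

* **Density-dependent growth** $r_i(N)$: logistic $r_i(1 - N/K)$ by
  default; Gompertz and pure exponential variants are available through
  `growth_kind`.
* **Hill pharmacodynamics** $d(u) = d_{\max}\bigl(1 - 1/(1 +
  (u/h)^k)\bigr)$: molecular binding saturates, so the kill rate plateaus
  at $d_{\max}$ near the concentration `u_max`. The drug does not touch
  resistant cells (complete resistance), and the per-capita kill depends
  only on concentration (log-kill), not density.
* **A dose-dependent mutation rate** $\mu(u) = \mu_0 + \alpha u$: the rate
  at which sensitive cells acquire the resistant phenotype rises with drug
  exposure, as reported for stress-induced mutagenesis in bacteria and for
  several anticancer agents. $\alpha = 0$ recovers the classical
  dose-independent assumption.

Resistant lineages start from single cells, so their fate is stochastic: a
lineage founded by one cell with birth rate $b_R$ and death rate $d_R$
escapes extinction with the branching-process probability
$\pi_f = 1 - d_R/b_R$. Rescue mutations arrive as an inhomogeneous Poisson
process with intensity $S(t)\,\mu(u(t))$, so over a treatment window
$[0, T]$ the expected number of *established* rescue lineages is

$$
\bar n_{\text{rescue}}(u) = \pi_f \int_0^T S(t)\,\mu(u(t))\,dt
  = \pi_f\, C(u),
$$

and the probability of evolutionary rescue is the complement of the
Poisson zero class, $1 - e^{-\bar n_{\text{rescue}}}$. Because $\pi_f$ is
a dose-independent constant of the resistant cell, minimising the rescue
probability is the same as minimising the raw cost $C(u)$, and the
optimisers work with $C$ while `rescue_costs()` reports
$\bar n_{\text{rescue}}$ and the rescue probability alongside.

A second objective matters clinically: if rescue does happen, early
mutations generate far larger resistant burdens than late ones. Weighting
each mutation by the exponential growth $e^{r_R (T - t)}$ its lineage can
generate by the end of treatment gives the *discounted* cost
$C_{\text{disc}}(u) = \int_0^T S \mu(u) e^{r_R(T - t)}\,dt$, proportional
to the expected resistant population at $T$.

## The dosing trade-off

With a dose-independent mutation rate, more drug is always better: the
only route to rescue is time spent at large $S$, so the maximum tolerated
dose (MTD) closes the rescue window fastest and is trivially optimal. With
$\alpha > 0$ a genuine trade-off appears. Because the kill rate saturates
while the mutation rate keeps rising, pushing the dose past the Hill
plateau buys almost no extra decay but keeps inflating the mutational
surplus; dosing *below* the plateau trades a slightly longer rescue window
for a much smaller drug-induced mutation peak.

```{r tradeoff}
p <- rescue_params()     # packaged baseline configuration
u_star <- stationary_dose(p)
u_star
```

The interior optimum solves the stationarity condition derived from the
Hamilton–Jacobi–Bellman (HJB) equation of the problem,

$$
\mu(u) + \bigl[r(S) - d(u) - \mu(u)\bigr]\,
  \frac{\mu'(u)}{d'(u) + \mu'(u)} = 0 ,
$$

balancing the marginal mutagenicity $\mu'$ against the marginal kill $d'$
weighted by the (negative) net growth. During effective treatment the
population decays nearly exponentially, so the law is evaluated in the
low-density limit $r(S) \to r_S$ by default; `control_law()` evaluates it
along an $S$ grid to give the closed-loop feedback law $u(S)$. For the
baseline parameters the optimal constant dose is $u^* \approx 104.5$ —
roughly a tenth of the pharmacodynamic plateau `u_max = 1000`, at which
the model produces between four and five times as many expected rescue
mutants as at $u^*$.

## Three solvers, one answer

The package deliberately solves the same control problem three ways; their
agreement on the baseline configuration is part of the test suite.

1. **Constant doses** (`optimize_constant_dose()`): a coarse dose grid
   (step 1 concentration unit) with golden-section refinement; each
   evaluation integrates the sensitive-compartment ODE with the cost
   carried as an auxiliary state, so solver tolerance (1e-10 relative)
   rather than an output grid controls quadrature accuracy.
2. **Open-loop schedules** (`fbsm_solve()`): the forward–backward sweep of
   Pontryagin's minimum principle — forward state integration, backward
   adjoint integration with transversality $\lambda(T) = 0$, pointwise
   Hamiltonian minimisation over $[0, u_{\text{MTD}}]$ with a relaxed
   update ($\omega = 0.1$ by default). The adjoint equations are derived
   analytically for each growth kind and verified in the tests against
   finite differences of the cost (to ~1e-6 relative with the refined
   gradient quadrature).
3. **Dynamic programming** (`hjb_solve()`): since elimination strategies
   decouple the resistant compartment, the state is one-dimensional and a
   simple monotone scheme suffices — uniform grid in $\log S$ from 0.1
   cells to $K$ plus an absorbing $S = 0$ node, first-order upwind
   differencing, explicit Euler in reverse time under a CFL bound
   (safety factor 0.9). Instability is detected and aborts with a
   grid-refinement hint rather than returning garbage.

The open-loop and feedback solutions improve on the best constant dose
only marginally (the test suite checks agreement within 10%): the optimal
schedule is nearly constant except for a boundary layer near $T$, where
the control drops because mutations arising just before the horizon no
longer matter. The time-stationary slice of the HJB map coincides with the
analytic law $u(S)$ within one dose-grid step, which is the cross-solver
oracle for both.

## The stochastic engine

Deterministic dynamics cannot produce a cure — an infinitesimal mutational
flux always rescues the population — so virtual treatments are simulated
with an exact Gillespie algorithm (`ssa_run()`, Rcpp core). Propensities
split crowding between births and deaths via turnover parameters
$\theta_i$ (with the baseline $\theta_S = b_S$, crowding acts purely
through deaths); mutation is a separate event type, deliberately not
coupled to birth events. Constant and piecewise-constant schedules are
simulated exactly by redrawing the waiting time at segment boundaries;
tabulated schedules are frozen on segments of at most `dt_max = 0.01` time
units. Each mutation founds its own tracked lineage, so the establishment
fraction is a direct observable.

Cohorts (`run_cohort()`, `dose_sweep_experiment()`) run by default at desk
scale $c = 0.01$: $K \to cK$, $S_0 \to cS_0$, $\mu_0 \to \mu_0/c$,
$\alpha \to \alpha/c$. This keeps per-capita rates and the product
$S\,\mu$ — hence $\bar n_{\text{rescue}}$ and cure probabilities — fixed
to leading order, while making a 500-replicate sweep a matter of seconds.
What down-scaling does *not* preserve is the conditional size of rescued
populations at $T$: a rescued clone needs $\ln(K)/r_R$ time units to fill
the niche, so smaller $K$ lets it saturate earlier. Conclusions about
`mean_final_N_over_K` at desk scale are therefore qualitative; cure
fractions are the scale-robust quantity, and the suite verifies them
against the Poisson zero class $e^{-\bar n_{\text{rescue}}(u)}$ at every
swept dose.

```{r sweep, eval = FALSE}
sweep <- dose_sweep_experiment(p, n_sim = 500, seed = 1)
autoplot(sweep)
```

The sweep reproduces the model's headline prediction: the cure probability
is *non-monotone* in dose, peaking near the stationary optimum, while with
$\alpha = 0$ the same sweep is monotone non-decreasing.

## The discounted optimum and a known discrepancy

Minimising $C_{\text{disc}}$ over constant doses with the baseline
parameters (discount rate $r_R = 0.4$, $S_0 = 10^5$, full logistic
dynamics, $T = 35$) yields $u^*_{\text{disc}} \approx 77.8$ — strictly
below the rescue optimum, as the theory demands: the discount weight makes
the early mutational peak costlier, so the optimal strategy uses less drug
early. The stochastic counterpart of this objective — the mean rescued
population size conditioned on non-extinction — has its minimum at a still
lower dose (around 60 in comparable studies). The two quantities are
related but not identical objects: the conditional mean divides by the
dose-dependent rescue probability and is affected by logistic saturation
of rescued clones, both of which shift its minimiser downward relative to
the Eq-4-style integral. The package reports the functional it defines;
the difference is documented here rather than papered over, and the
sensitivity is easy to explore: the discounted optimum moves by tens of
concentration units as the discount rate or the initial density varies.

## Numerical choices and degenerate inputs

* **ODE integration**: `lsoda`, relative tolerance 1e-8 (1e-10 in the
  optimisers), dense output step 0.005 time units for trajectory
  quadrature; the composite trapezoid on that grid matches the
  closed-form exponential-decay cost to better than 1e-6 relative, which
  is a test oracle.
* **Negative states**: the model preserves non-negativity analytically;
  states are clipped at zero to guard numerical undershoot only.
* **Stationary law**: bracketed root-finding on $(0, u_{\max}]$; when the
  condition has no sign change (notably $\alpha = 0$), the boundary
  optimum $\min(u_{\text{MTD}}, u_{\max})$ is returned and flagged.
* **Tie-breaking**: wherever doses are scanned (FBSM Hamiltonian, HJB
  nodes), the smallest dose within 1e-12 of the minimum wins — prefer
  less drug.
* **Establishment at finite density**: $\pi_f = 1 - d_R/b_R$ is the
  zero-density branching limit. Lineages actually arise at densities up
  to $S_0/K = 0.1$, where the crowding term raises the resistant death
  rate, so observed establishment fractions sit up to
  $\approx \pi_f \cdot S_0/K$ below 0.8 at eradicating doses; the
  acceptance suite allows exactly that correction. At sub-eradication
  doses the niche never empties and the branching picture does not apply,
  so those doses are excluded from the establishment check.
* **Branching-process validation**: the single-lineage extinction check
  runs to $T = 20$; the closed form
  $q(t) = d(e^{rt} - 1)/(b e^{rt} - d)$ is within 1e-4 of $d_R/b_R = 0.2$
  there, while surviving lineages grow like $e^{0.4 t}$ and would
  dominate runtime at larger horizons.
* **Problem sizes**: the shipped tests use 301–561 time/space nodes for
  the solvers, 500-replicate cohorts at scale 0.01, 900 replicates for
  the mean-field comparison and 10,000 for the branching check — sizes
  chosen so the full suite completes in about two minutes while every
  statistical assertion retains 3-standard-error headroom.

## What the synthetic experiments do and do not show

All experiments are generated internally from the parameter configuration;
there is no external data. The generator emulates logistic regrowth, Hill
kill and a linear mutagenic dose response with the packaged baseline
(`rescue_params()`), which fixes the baseline mutation intensity at
$S_0 \mu_0 = 0.1$ — mutation-limited, where optimisation matters. Real
treatments add pharmacokinetics (here $u(t)$ *is* the realised
concentration), partial resistance, standing variation ($R_0 > 0$ is
supported but not exercised by the defaults), immune and spatial effects,
and mutation-rate dose responses that need not be linear. Passing tests
therefore demonstrate internal consistency of the theory, its solvers and
its simulator — not that any particular drug has these parameters.

## Limitations

Containment objectives (stabilising rather than eradicating the burden),
multi-drug schedules, collateral-sensitivity cycling and explicitly
stochastic treatment of sub-threshold resistant lineages in the
deterministic solvers are out of scope. The HJB solver is first-order
accurate; its value function carries upwind diffusion of a few percent at
the default grid, which is why the cross-solver tolerance is 10%.
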