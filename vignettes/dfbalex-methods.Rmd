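---
title: "Methods: lexicographic DFBA with an LP-feasibility penalty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicographic DFBA with an LP-feasibility penalty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfbalex)
```

## The model

A culture of `n_s` organisms in a stirred tank is described by biomass
densities `y_i` (gDW/L), extracellular concentrations `s` (mmol/L) and, when
the pH balance is enabled, total dissolved carbon and nitrogen plus six
algebraic speciation variables. Each organism carries a stoichiometric model
`S` (metabolites × reactions) and the quasi-steady-state assumption of flux
balance analysis: intracellular dynamics relax fast relative to the
extracellular environment, so at every instant the flux vector `v` satisfies
`S v = 0` within bounds `v_LB(x) <= v <= v_UB(x)` that depend on the
extracellular state (uptake kinetics, light, clamps).

The mass balances are the usual CSTR forms,

```
dy_i/dt = mu_i y_i - F_out y_i / V
ds/dt   = (F_in s0 - F_out s) / V + MT_s + sum_i (v_sp,i - v_sc,i) y_i
```

with `MT_s = kLa (s_gas/K_H - s)` for sparged species and zero otherwise,
and `v_sp`/`v_sc` the production and consumption parts of the signed
exchange flux. The sign convention is positive = secretion into the medium
(the SBML exchange convention); consumption bounds therefore act on the
negative flux direction. Biomass is absent from the feed, so its dilution
term uses `F_out` only.

## Unique fluxes by lexicographic optimization

The FBA optimum pins the optimal *value* of the objective, not the flux
*vector*: at a growth optimum, overflow routes, futile cycles and parallel
pathways typically leave exchange fluxes free on the optimal face. A
right-hand side built from an arbitrary vertex of that face is not a
function of the state, and adaptive integrators repeatedly re-solve the LP
at nearby states receiving discontinuous answers.

`dfbalex` therefore solves a *priority list* of LPs at every evaluation:
level 0 minimizes the total slack of the mass-balance rows (below), level 1
maximizes biomass, and each further level optimizes one exchange flux
consumed by the ODEs, subject to all earlier optima held fixed. Optimal
values of LPs are unique and vary continuously with the bounds, so the flux
entries pinned by the list are unique and continuous in `x` — the property
the integrator needs. The ordering of the lower-priority objectives is part
of the model description: different orderings are different models of the
organism's secondary behaviour, and biologically implausible orderings
(e.g. maximizing oxygen consumption for a phototroph) produce implausible
trajectories. `uniqueness_diagnostic()` reports the attainable range of any
flux after the listed levels are fixed; a nondegenerate range means the list
is too short for that flux. A compound "maximize production and minimize
consumption" objective is a single `max` on the signed exchange flux.

Earlier optima are fixed as two-sided bands
`z* - delta <= c' v <= z* + delta` with
`delta = max(1e-9, 1e-9 |z*|)`: exact equality rows on floating-point optima
cause spurious infeasibility in later levels. The band makes each reported
optimum reproducible across LP backends to well below 1e-6, which the test
suite asserts by solving every fixture with both the built-in simplex and
`boot::simplex`.

## The feasibility level and the penalty state

Augmenting the equality rows with nonnegative slack pairs,

```
min sum(s+) + sum(s-)   s.t.  S v + s+ - s- = 0,  v_LB <= v <= v_UB
```

gives a problem that is feasible whenever `v_LB <= v_UB` (take any `v` in
the box and absorb `S v` into the slacks) and whose optimum is zero iff the
original LP is feasible. Slacks are attached directly to the
bounded-variable form rather than to a textbook standard form; the two are
equivalent in optimal value and the bounded form keeps box constraints
native to the solver. Placing this objective at top priority makes the
dynamic system *extended*: it is defined even where the growth LP is
infeasible, so the integrator never aborts mid-step. The only unrecoverable
error is an empty box (`lb > ub`), which can arise solely from a malformed
kinetic law and is reported as a hard error naming the reaction.

The per-species feasibility optima are summed and integrated as an extra
state, the penalty. Along feasible trajectories it is identically zero; once
the system becomes infeasible it grows monotonically (the integrand is
nonnegative). Carrying it as a state, rather than post-processing, keeps it
exact under adaptive stepping. `detect_infeasibility()` scans the
instantaneous penalty rate for the first exceedance of `epsilon` (default
1e-6, left open by the method; the default is small relative to any
mass-balance residual of interest at the integration tolerances used) and
refines the crossing by linear interpolation between output points, so the
reported onset is accurate to about one output step.

## LP solving

No linear-programming package is assumed: the package ships a dense
bounded-variable two-phase simplex (variable shifting/splitting to standard
form, artificial-variable phase 1, Bland's rule throughout for cycling
safety). Dense tableau pivoting is entirely adequate for the problem sizes
the package targets in testing (tens of reactions); genome-scale models
work through the same interface but benefit from sparse solvers, which the
backend key leaves room for. `boot::simplex` is wired in as a second,
independent backend used by the cross-checking tests; linearly dependent
equality rows are eliminated (after a rank consistency check) before
calling it, as it mishandles them. All-zero constraint rows are dropped
during standardization, with a nonzero right-hand side on such a row
reported as trivially infeasible.

## Kinetic laws and forcings

* **Uptake**: `v <= vmax s/(Ks + s)`, divided by `(1 + i/Ki)` per
  inhibitor. Units: `vmax` mmol/gDW/h, `Ks`, `Ki` mmol/L. Negative
  concentrations (transient integrator excursions) are clamped to zero
  inside the law, so bounds are always in `[0, vmax]` and monotone in `s`.
  A `custom` form accepts an arbitrary function for laws outside this
  family.
* **Gas transfer**: `kLa (s_gas/K_H - s)`; the dissolved concentration is
  capped at the Henry constant by zeroing a positive driving force at the
  cap, which keeps the right-hand side continuous rather than imposing a
  hard state constraint.
* **Light**: the surface flux is a clipped squared sinusoid with peak 28
  mmol photons/gDW/h at noon and a daylight window 5:00-19:00 (both
  configurable; the window must be symmetric about noon for the squared-sine
  form). Self-shading uses Beer-Lambert depth averaging
  `I_a = I_0 (1 - e^(-L Ke))/(L Ke)` with
  `Ke = Ke_intercept + Ke_slope * biomass`; for `L Ke < 1e-10` the two-term
  series is used so the factor is continuous with limit `I_0`. The
  attenuation coefficients are config-supplied (they are instrument- and
  culture-specific); the defaults (14 /m intercept, 50 /m per gDW/L) are
  representative of dense microalgal ponds a few centimetres deep. The
  depth-averaged value is applied as the photon uptake bound itself,
  replacing the model default on the designated light-capture reaction;
  which reaction(s) that is, is model-specific and must be named in the
  species spec. Biomass stratification over depth is neglected.

## The pH block as an index-1 DAE

With the carbonate and ammonia equilibria active, total carbon `C_T` and
total nitrogen `N_T` become differential states and the six species CO2,
HCO3-, CO3^2-, NH3, NH4+, H+ become algebraic, closed by carbon and
nitrogen balances, the three equilibrium relations and a charge balance
with OH- eliminated via `Kw/H+`. Default constants are the standard 25 °C
values (pK1 6.35, pK2 10.33, pKa(NH4+) 9.25, pKw 14), all overridable; the
solution's net strong-ion charge is taken as zero, and H+ exchange by the
organisms is neglected in the charge balance. `solve_speciation()` finds
the unique positive H+ root of the charge balance in log space (structural
positivity over the whole pH range) to initialize the DAE consistently; the
Jacobian of the residuals with respect to the algebraic block is checked
for nonsingularity (`index1_check()`, using a row-equilibrated reciprocal
condition number so the disparate magnitudes of the equilibrium constants
do not masquerade as singularity), and the system is integrated by the
Radau IIA method with a singular mass matrix. Biological CO2 exchange and
gas transfer drive `dC_T/dt`; the dissolved CO2 seen by uptake kinetics is
the algebraic variable.

## Integration choices

DFBA systems are stiff (fluxes switch on substrate-depletion timescales far
shorter than growth). The ODE path uses the variable-order BDF method from
`deSolve` (lsode core) with defaults `rtol = 1e-6`, `atol = 1e-8`; the DAE
path uses `radau`. The day/night forcing has kinks at dawn and dusk; the
integrator is restarted at every such transition (and any user-declared
forcing discontinuity) so no kink sits inside a step, avoiding order
reduction. Nonnegativity of biomass and metabolites is enforced by zeroing
inward derivatives at the origin plus the kinetic clamping above; pH runs
disable the projection, since the algebraic block must be free to balance
and the kinetics are specified so negative concentrations cannot occur.
Species LPs are decoupled given the state, so results are independent of
the order species are listed; this is asserted in tests rather than assumed.

## What the synthetic fixtures do and do not show

The test fixtures are built in code: a 6-reaction growth toy with yield 0.1
gDW/mmol, an overflow route that is degenerate at the growth optimum (the
canonical nonuniqueness the lexicographic scheme removes), and an optional
ATP-maintenance demand that renders the LP infeasible below a computable
substrate threshold `s* = 2m Ks/(vmax - 2m)` — giving an analytic target
for the infeasibility-detection machinery. A dual-substrate variant with
glucose-inhibited xylose uptake and a clamped O2 state reproduces the
structure of diauxic batch fermentations. Random bounded LPs with planted
feasible points (integer null vectors) or planted infeasibility
certificates (a strictly positive row over a positive box) exercise the
feasibility construction against an independent direct solve, with integer
coefficients so brute-force checks are exact.

Passing these tests demonstrates the mathematics — uniqueness, continuity,
the feasibility/penalty contract, linear cost scaling in the number of
models — on networks small enough to verify by hand. It does not
demonstrate genome-scale numerical behaviour: real reconstructions bring
ill-conditioned stoichiometry, thousands-fold larger LPs and degenerate
bases that stress a dense tableau solver far more than these fixtures.
Problem sizes used by the suite: LPs up to 5×8 (500 random instances),
communities up to 10 replicated models, horizons up to 24 h, all chosen so
a full run completes in a few minutes on one core.

## Known limitations

* Dense simplex: adequate for toy and mid-sized models; genome-scale work
  wants a sparse LP backend behind the same interface.
* No gene-protein-reaction rules, flux variability analysis, or parsimonious
  FBA; integer and quadratic programs are out of scope.
* The basis-reuse acceleration for solving the whole priority list from one
  factorization is not implemented; each level is solved from scratch.
* The pH block models only the carbonate/ammonia/water system with unit
  activity coefficients at 25 °C; phosphate buffers, ionic strength and
  temperature dependence are not included.
* The penalty state is reported and used for infeasibility detection; its
  use as an objective in DFBA optimization is outside this package's scope.
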