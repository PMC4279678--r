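# dfbalex

Dynamic flux balance analysis (DFBA) with lexicographic optimization and an
LP-feasibility penalty, in R.

## The problem

DFBA simulates a culture by embedding a flux balance analysis (FBA) linear
program in the right-hand side of the extracellular mass balances: at every
state `x(t)`, each organism `k` solves

```
max  c' v        s.t.  S v = 0,   v_LB(x) <= v <= v_UB(x)
```

and the exchange fluxes read off the optimum drive the ODEs for biomass and
metabolite concentrations. Two failure modes plague naive implementations:

1. **Nonunique fluxes.** The optimal *value* of an LP is unique, but the
   optimal flux *vector* usually is not. If the right-hand side consumes a
   flux that is free on the optimal face, the dynamic system is ill-defined
   and adaptive integrators see discontinuous right-hand sides.
2. **Infeasibility.** As substrates deplete, the LP can become infeasible
   (e.g. a maintenance demand that can no longer be met), crashing the
   integrator or silently fabricating a "death phase".

`dfbalex` implements the direct-approach remedy for both. The mass-balance
rows are augmented with nonnegative slack pairs,

```
min  sum(s+) + sum(s-)    s.t.  S v + s+ - s- = 0,   v_LB <= v <= v_UB,
                                s+, s- >= 0
```

a phase-one feasibility problem that is solvable whenever the bound box is
nonempty and whose optimum is zero **iff** the original LP is feasible. This
objective sits at the top of a *lexicographic priority list* — feasibility
first, then biomass maximization, then each exchange flux the ODEs consume,
each level solved subject to all earlier optima held fixed. Optimal values
are unique and continuous in the bounds, so the reported exchange fluxes are
unique and the extended dynamic system is defined for all simulation time.
The integral of the feasibility optimum is carried as an extra *penalty*
state: identically zero along feasible trajectories, and its first departure
from zero (beyond a tolerance `epsilon`) locates the infeasibility time.

The package also provides: COBRA-JSON and SBML Level 3 (fbc) model readers
and writers, Michaelis–Menten uptake kinetics with inhibition, gas–liquid
mass transfer with Henry's-law caps, a day/night surface light model with
Beer–Lambert depth averaging for phototrophs, CSTR feed/discharge terms, and
a carbonate/ammonia pH speciation block integrated as an index-1 DAE
(mass-matrix Radau method). Stiff integration uses `deSolve` (variable-order
BDF); LPs are solved by the package's bounded-variable two-phase simplex,
with `boot::simplex` available as an independent cross-check backend.

## Worked example

A 6-reaction toy network (glucose uptake bounded at 10 mmol/gDW/h, biomass
yield 0.1 gDW/mmol glucose, an overflow route for surplus energy):

```r
library(dfbalex)

toy <- make_growth_toy(uptake_bound = 10)
pl  <- priority_list(lex_level("biomass", "max"), lex_level("eth", "min"))
flp <- build_feasibility(model_lp(toy$model))
sol <- lexicographic_solve(flp, compile_priorities(pl, toy$model, toy$exmap))
print(sol)
#> <lexicographic_solution> status = solved, feasibility = 0
#>   objective values: 1, 0
setNames(sol$flux, toy$model$reaction_ids)
#>  EX_glc    R_glyc R_biomass    R_atpm    EX_co2    EX_eth
#>     -10        10         1         5         2         0
```

Feasibility cost 0 (the LP is feasible), growth rate 1/h (= 0.1 × 10), and
the overflow flux `EX_eth` pinned to 0 by the second priority level. With
only biomass in the list, `uniqueness_diagnostic()` reports `EX_eth` free on
`[0, 5]` — exactly the degeneracy that lexicographic ordering removes.

A batch culture with Michaelis–Menten glucose uptake and a maintenance
demand of 1 mmol/gDW/h runs out of substrate and the LP turns infeasible;
the simulation survives and the penalty state locates the onset:

```r
toy <- make_growth_toy(uptake_bound = 10, maintenance = 1)
sp  <- species_spec("ecoli", toy$model, toy$exmap, pl,
                    uptake = list(uptake_law("glc", vmax = 10, Ks = 0.5)))
cfg <- community_config(list(sp), metabolites = c("glc", "co2", "eth"),
                        reactor = reactor_spec(V = 1))
res <- simulate_community(cfg,
                          c(biomass_ecoli = 0.1, glc = 2, co2 = 0, eth = 0),
                          sim_options(t_span = c(0, 6), n_out = 121))
print(res)
#> <simulation_result> 121 points on [0, 6] h, 1 species
#>   final penalty 4.093; infeasibility time: 1.65 h
```

The onset agrees with the analytic threshold: uptake capacity
`vmax*s/(Ks+s)` falls below twice the maintenance demand at
`s* = 2m*Ks/(vmax - 2m) = 0.125 mmol/L`, which the glucose trajectory
crosses at ~1.69 h — within one output step of the detected 1.65 h.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dfbalex.R", package = "dfbalex"))') \
    run --config run.json --out results/
```

with subcommands `run`, `check-model` and `demo`.

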