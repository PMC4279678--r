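# Shared scenario builders. Everything is generated in code; no data files.

# default toy priority list: biomass first, then pin the overflow flux
toy_priorities <- function() {
  priority_list(lex_level("biomass", "max"), lex_level("eth", "min"))
}

# single-species batch culture of the growth toy
toy_batch_config <- function(uptake_bound = 10, maintenance = 0,
                             uptake = list(), reactor = reactor_spec(V = 1),
                             clamp = character(0)) {
  toy <- make_growth_toy(uptake_bound = uptake_bound,
                         maintenance = maintenance)
  sp <- species_spec("ecoli", toy$model, toy$exmap, toy_priorities(),
                     uptake = uptake)
  community_config(list(sp), metabolites = c("glc", "co2", "eth"),
                   reactor = reactor, clamp = clamp)
}

# Example-1-style dual-substrate batch protocol: Michaelis-Menten uptake of
# glucose and (glucose-inhibited) xylose, dissolved O2 clamped, ATP
# maintenance demand making the LP infeasible once both substrates fall
# below their uptake thresholds.
dual_substrate_protocol <- function(maintenance = 1,
                                    glc0 = 2, xyl0 = 1,
                                    o2_clamp = 0.24) {
  toy <- make_dual_substrate_toy(maintenance = maintenance)
  pl <- priority_list(lex_level("biomass", "max"),
                      lex_level("eth", "min"),
                      lex_level("glc", "max"),   # minimize consumption
                      lex_level("xyl", "max"))
  laws <- list(
    uptake_law("glc", vmax = 10, Ks = 0.5),
    uptake_law("xyl", vmax = 8, Ks = 0.5, inhibitors = c(glc = 0.05))
  )
  sp <- species_spec("ecoli", toy$model, toy$exmap, pl, uptake = laws)
  cfg <- community_config(
    list(sp), metabolites = c("glc", "xyl", "co2", "eth", "o2"),
    reactor = reactor_spec(V = 1), clamp = "o2"
  )
  list(config = cfg,
       x0 = c(biomass_ecoli = 0.1, glc = glc0, xyl = xyl0,
              co2 = 0, eth = 0, o2 = o2_clamp),
       maintenance = maintenance,
       laws = laws)
}

# time at which a decreasing trajectory column crosses a threshold
crossing_time <- function(times, values, threshold) {
  below <- which(values < threshold)
  stopifnot(length(below) > 0, below[1] > 1)
  i <- below[1]
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

# brute-force feasibility check of a bounded LP on an integer grid plus
# LP-free certificate: used as an oracle on tiny instances only
grid_feasible <- function(lp, step = 0.5) {
  grids <- lapply(seq_along(lp$lb), function(j) {
    seq(lp$lb[j], lp$ub[j], by = step)
  })
  pts <- as.matrix(do.call(expand.grid, grids))
  any(apply(pts, 1L, function(v) all(abs(lp$S %*% v) < 1e-9)))
}
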