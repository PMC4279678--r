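test_that("constant-bound growth integrates to the closed-form exponential", {
  cfg <- toy_batch_config(uptake_bound = 5)   # mu* = 0.5/h
  opt <- sim_options(t_span = c(0, 2), n_out = 21)
  res <- simulate_community(cfg, c(biomass_ecoli = 0.05, glc = 100,
                                   co2 = 0, eth = 0), opt)
  analytic <- 0.05 * exp(0.5 * res$times)
  rel <- abs(res$states[, "biomass_ecoli"] - analytic) / analytic
  expect_lt(max(rel), 10 * opt$rtol)
  expect_true(all(res$penalty < opt$epsilon))
  expect_true(is.na(res$infeasibility_time))
})

test_that("bounds forced to zero reduce the system to linear washout", {
  toy <- make_growth_toy(uptake_bound = 0)
  m <- toy$model
  m$lb_default[] <- 0
  m$ub_default[] <- 0
  sp <- species_spec("ecoli", m, toy$exmap, toy_priorities())
  cfg <- community_config(list(sp), metabolites = c("glc", "co2", "eth"),
                          reactor = reactor_spec(V = 2, F_in = 1, F_out = 1,
                                                 feed = c(glc = 10)))
  res <- simulate_community(cfg, c(biomass_ecoli = 0.5, glc = 1, co2 = 0,
                                   eth = 0),
                            sim_options(c(0, 6), n_out = 13))
  s_an <- 10 + (1 - 10) * exp(-res$times / 2)
  y_an <- 0.5 * exp(-res$times / 2)
  expect_lt(max(abs(res$states[, "glc"] - s_an)), 1e-4)
  expect_lt(max(abs(res$states[, "biomass_ecoli"] - y_an)), 1e-5)
})

test_that("mid-horizon infeasibility is survived, monotone and bracketed", {
  cfg <- toy_batch_config(maintenance = 1,
                          uptake = list(uptake_law("glc", vmax = 10,
                                                   Ks = 0.5)))
  opt <- sim_options(c(0, 6), n_out = 121)
  res <- simulate_community(cfg, c(biomass_ecoli = 0.1, glc = 2, co2 = 0,
                                   eth = 0), opt)
  expect_equal(max(res$times), 6)                   # horizon completed
  expect_true(all(diff(res$penalty) >= -1e-10))     # monotone penalty
  expect_false(is.na(res$infeasibility_time))
  # the LP turns infeasible when uptake capacity drops below twice the
  # maintenance demand: vmax*s/(Ks+s) = 2m  =>  s* = 2m*Ks/(vmax-2m)
  s_star <- 2 * 1 * 0.5 / (10 - 2 * 1)
  t_star <- crossing_time(res$times, res$states[, "glc"], s_star)
  step <- diff(res$times[1:2])
  expect_lt(abs(res$infeasibility_time - t_star), 2 * step)
  expect_gt(res$penalty[length(res$penalty)], 0)
})

test_that("a system infeasible from the start reports onset at t0", {
  cfg <- toy_batch_config(uptake_bound = 1, maintenance = 2)
  res <- simulate_community(cfg, c(biomass_ecoli = 0.1, glc = 10, co2 = 0,
                                   eth = 0),
                            sim_options(c(0, 1), n_out = 11))
  expect_equal(res$infeasibility_time, 0)
  expect_true(all(diff(res$penalty) >= -1e-10))
  expect_equal(max(res$times), 1)
})

test_that("infeasibility detection interpolates a constructed penalty ramp", {
  fake <- structure(
    list(times = seq(0, 8, by = 0.5),
         feasibility_rate = pmax(0, seq(0, 8, by = 0.5) - 4) * 0.3,
         options = list(epsilon = 1e-6)),
    class = "simulation_result")
  t_hit <- detect_infeasibility(fake, 1e-6)
  expect_lt(abs(t_hit - 4.0), 0.5)     # within one step width
  fake$feasibility_rate[] <- 0
  expect_true(is.na(detect_infeasibility(fake, 1e-6)))
})

test_that("halving the tolerances barely moves the final state", {
  cfg <- toy_batch_config(uptake_bound = 5,
                          uptake = list(uptake_law("glc", vmax = 5,
                                                   Ks = 0.5)))
  x0 <- c(biomass_ecoli = 0.05, glc = 8, co2 = 0, eth = 0)
  coarse <- simulate_community(cfg, x0,
                               sim_options(c(0, 4), rtol = 1e-6,
                                           atol = 1e-8, n_out = 9))
  fine <- simulate_community(cfg, x0,
                             sim_options(c(0, 4), rtol = 5e-7,
                                         atol = 5e-9, n_out = 9))
  dev <- max(abs(coarse$states[9, ] - fine$states[9, ]))
  expect_lt(dev, 10 * 1e-6 * max(abs(coarse$states[9, ])))
})

test_that("species order does not affect community trajectories", {
  toyA <- make_growth_toy(uptake_bound = 4)
  toyB <- make_growth_toy(uptake_bound = 8)
  spA <- species_spec("A", toyA$model, toyA$exmap, toy_priorities(),
                      uptake = list(uptake_law("glc", vmax = 4, Ks = 0.5)))
  spB <- species_spec("B", toyB$model, toyB$exmap, toy_priorities(),
                      uptake = list(uptake_law("glc", vmax = 8, Ks = 0.5)))
  mets <- c("glc", "co2", "eth")
  x0 <- c(biomass_A = 0.1, biomass_B = 0.2, glc = 5, co2 = 0, eth = 0)
  resAB <- simulate_community(
    community_config(list(spA, spB), mets, reactor_spec(V = 1)),
    x0, sim_options(c(0, 2), n_out = 11))
  resBA <- simulate_community(
    community_config(list(spB, spA), mets, reactor_spec(V = 1)),
    x0, sim_options(c(0, 2), n_out = 11))
  for (nm in c("biomass_A", "biomass_B", "glc", "co2", "eth")) {
    expect_equal(resBA$states[, nm], resAB$states[, nm], tolerance = 1e-8)
  }
})

test_that("light transitions trigger integrator restarts", {
  toy <- make_growth_toy(uptake_bound = 5)
  sp <- species_spec("alg", toy$model, toy$exmap, toy_priorities(),
                     photon = list(reaction = "EX_eth",
                                   light = light_model()))
  cfg <- community_config(list(sp), c("glc", "co2", "eth"),
                          reactor_spec(V = 1))
  res <- simulate_community(cfg, c(biomass_alg = 0.05, glc = 50, co2 = 0,
                                   eth = 0),
                            sim_options(c(0, 24), n_out = 25))
  expect_gte(res$diagnostics$segments, 3)   # dawn and dusk split the day
  expect_true(all(c(5, 19) %in% res$times))
})

test_that("pH DAE runs keep the algebraic residuals and totals consistent", {
  cfg <- community_config(
    list(), metabolites = "co2",
    reactor = reactor_spec(V = 1),
    gas = list(co2 = gas_transfer_spec(kLa = 2, K_H = 30, s_gas = 12)),
    ph = ph_spec())
  opt <- sim_options(c(0, 5), n_out = 11, nonnegative = FALSE)
  res <- simulate_community(cfg, c(C_T = 1.22, N_T = 0.1643), opt)
  k <- equilibrium_constants()
  for (i in seq_along(res$times)) {
    st <- res$states[i, ]
    resid <- equilibrium_residuals(
      c(C_T = unname(st["C_T"]), N_T = unname(st["N_T"]),
        st[c("co2", "hco3", "co3", "nh3", "nh4", "h")]), k)
    expect_lt(max(abs(resid)), 100 * opt$atol)
  }
  # no nitrogen source or sink: N_T constant
  expect_lt(max(abs(res$states[, "N_T"] - 0.1643)), 1e-9)
  # gas transfer drives dissolved CO2 monotonically toward saturation
  sat <- 12 / 30
  gap <- abs(res$states[, "co2"] - sat)
  expect_true(all(diff(gap) < 0))
})

test_that("results write to tidy CSV plus a manifest that reflects the run", {
  cfg <- toy_batch_config(uptake_bound = 5)
  res <- simulate_community(cfg, c(biomass_ecoli = 0.05, glc = 50, co2 = 0,
                                   eth = 0),
                            sim_options(c(0, 1), n_out = 6,
                                        backend = "simplex"))
  dir <- withr::local_tempdir()
  files <- write_results(res, dir)
  df <- utils::read.csv(file.path(dir, "trajectories.csv"),
                        check.names = FALSE)
  expect_equal(df$time, res$times)
  expect_equal(df$glc, unname(res$states[, "glc"]), tolerance = 1e-12)
  # flux columns present for every priority-listed exchange species
  expect_true(all(c("ecoli.glc", "ecoli.co2", "ecoli.eth") %in% names(df)))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$epsilon, 1e-6)
  expect_equal(man$backend, "simplex")
  expect_equal(man$species, "ecoli")
})
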