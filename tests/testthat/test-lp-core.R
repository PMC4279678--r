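test_that("feasibility construction attains zero exactly on feasible LPs", {
  # v1 = v2 over [0,1]^2: v = 0 satisfies S v = 0
  lp <- bounded_lp(matrix(c(1, -1), 1), c(0, 0), c(1, 1))
  res <- solve_lp(build_feasibility(lp))
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 0, tolerance = 1e-9)
  # v = 0 unattainable on [1,2]: min |v| = 1, one slack absorbs it
  lp2 <- bounded_lp(matrix(1, 1, 1), 1, 2)
  res2 <- solve_lp(build_feasibility(lp2))
  expect_equal(res2$objective, 1, tolerance = 1e-9)
  expect_equal(res2$x[1], 1, tolerance = 1e-9)
  # symmetric negative box
  lp3 <- bounded_lp(matrix(1, 1, 1), -2, -1)
  expect_equal(solve_lp(build_feasibility(lp3))$objective, 1,
               tolerance = 1e-9)
})

test_that("the plain LP solver reports optimal, unbounded and infeasible", {
  expect_equal(
    solve_lp(bounded_lp(matrix(0, 0, 1), 0, 1, c = 1, sense = "max"))$objective,
    1, tolerance = 1e-9)
  expect_equal(
    solve_lp(bounded_lp(matrix(0, 0, 1), 0, Inf, c = 1, sense = "max"))$status,
    "unbounded")
  expect_equal(
    solve_lp(bounded_lp(matrix(1, 1, 1), 1, 2, c = 1, sense = "max"))$status,
    "infeasible")
  # solver failure statuses never raise
  expect_no_error(solve_lp(bounded_lp(matrix(0, 0, 1), 0, Inf, c = 1,
                                      sense = "max")))
})

test_that("lexicographic optimization reproduces the hand-enumerated vertices", {
  # v1 = v2 + v3, all in [0,1]; vertex enumeration gives:
  #   max v1 then min v2 -> values (1, 0), flux (1, 0, 1)
  #   max v1 then max v2 -> flux (1, 1, 0)
  flp <- build_feasibility(bounded_lp(matrix(c(1, -1, -1), 1),
                                      c(0, 0, 0), c(1, 1, 1)))
  s1 <- lexicographic_solve(flp, priority_list(lex_level(c(1, 0, 0), "max"),
                                               lex_level(c(0, 1, 0), "min")))
  expect_equal(s1$feasibility_value, 0, tolerance = 1e-8)
  expect_equal(s1$objective_values, c(1, 0), tolerance = 1e-8)
  expect_equal(s1$flux, c(1, 0, 1), tolerance = 1e-8)
  s2 <- lexicographic_solve(flp, priority_list(lex_level(c(1, 0, 0), "max"),
                                               lex_level(c(0, 1, 0), "max")))
  expect_equal(s2$flux, c(1, 1, 0), tolerance = 1e-8)
})

test_that("the slack budget constrains later levels: max v on [1,2] stops at 1", {
  # min slacks gives 1 (attained at v = 1); fixing that optimum forces
  # s+ + s- = 1 with v + s+ - s- = 0, hence v <= 1 although the box allows 2
  flp <- build_feasibility(bounded_lp(matrix(1, 1, 1), 1, 2))
  s <- lexicographic_solve(flp, priority_list(lex_level(1, "max")))
  expect_equal(s$feasibility_value, 1, tolerance = 1e-8)
  expect_equal(s$objective_values, 1, tolerance = 1e-8)
  expect_equal(s$flux, 1, tolerance = 1e-8)
})

test_that("uniqueness diagnostic separates pinned from free fluxes", {
  flp <- build_feasibility(bounded_lp(matrix(c(1, -1, -1), 1),
                                      c(0, 0, 0), c(1, 1, 1)))
  p2 <- priority_list(lex_level(c(1, 0, 0), "max"),
                      lex_level(c(0, 1, 0), "min"))
  s2 <- lexicographic_solve(flp, p2)
  expect_equal(unname(uniqueness_diagnostic(flp, p2, s2, 1)), c(1, 1),
               tolerance = 1e-7)
  p1 <- priority_list(lex_level(c(1, 0, 0), "max"))
  s1 <- lexicographic_solve(flp, p1)
  rng <- uniqueness_diagnostic(flp, p1, s1, 3)
  expect_equal(unname(rng), c(0, 1), tolerance = 1e-7)
  # a variable pinned by lb = ub reports a degenerate interval
  flp3 <- build_feasibility(bounded_lp(matrix(c(1, -1), 1), c(0.5, 0),
                                       c(0.5, 1)))
  p3 <- priority_list(lex_level(c(0, 1), "max"))
  s3 <- lexicographic_solve(flp3, p3)
  expect_equal(unname(uniqueness_diagnostic(flp3, p3, s3, 1)), c(0.5, 0.5),
               tolerance = 1e-7)
})

test_that("unbounded lower-priority levels are flagged and later levels skipped", {
  # v1 free upward, level 2 unbounded; level statuses record it
  flp <- build_feasibility(bounded_lp(matrix(0, 0, 2), c(0, 0), c(1, Inf)))
  s <- lexicographic_solve(flp, priority_list(lex_level(c(1, 0), "max"),
                                              lex_level(c(0, 1), "max"),
                                              lex_level(c(1, 1), "min")))
  expect_equal(s$level_status, c("optimal", "unbounded", "skipped"))
  expect_equal(s$objective_values[1], 1, tolerance = 1e-8)
  expect_true(is.na(s$objective_values[2]))
  expect_equal(s$flux[1], 1, tolerance = 1e-8)
})

test_that("feasibility optimum is zero iff the original LP is feasible (oracle sweep)", {
  # seeded sweep against the independent backend solving the un-slacked LP
  n_ok <- 0L
  for (i in 1:60) {
    feas <- i %% 2 == 0
    n_q <- 1 + (i %% 4)
    n_r <- n_q + 1 + (i %% 3)
    lp <- random_bounded_lp(n_q, n_r, feasible = feas, seed = 5000 + i)
    fval <- solve_lp(build_feasibility(lp))$objective
    expect_gte(fval, -1e-10)
    direct <- solve_lp(lp, backend = "boot")$status
    if (feas) {
      expect_lt(fval, 1e-7)
      expect_true(direct %in% c("optimal", "unbounded"))
    } else {
      expect_gt(fval, 1e-7)
      expect_equal(direct, "infeasible")
    }
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 60L)
})

test_that("objective values are invariant under reaction permutation and backend swap", {
  toy <- make_growth_toy()
  pl <- compile_priorities(toy_priorities(), toy$model, toy$exmap)
  flp <- build_feasibility(model_lp(toy$model))
  base <- lexicographic_solve(flp, pl)

  perm <- c(3, 6, 1, 4, 2, 5)
  Sp <- toy$model$S[, perm]
  lp_p <- bounded_lp(Sp, toy$model$lb_default[perm],
                     toy$model$ub_default[perm])
  costs <- lapply(pl$levels, function(lv) lv$cost[perm])
  pl_p <- priority_list(lex_level(costs[[1]], "max"),
                        lex_level(costs[[2]], "min"))
  permuted <- lexicographic_solve(build_feasibility(lp_p), pl_p)
  expect_equal(permuted$objective_values, base$objective_values,
               tolerance = 1e-7)
  # un-permute fluxes named in the priority list
  unperm <- numeric(6)
  unperm[perm] <- permuted$flux
  expect_equal(unperm[c(3, 6)], base$flux[c(3, 6)], tolerance = 1e-6)

  alt <- lexicographic_solve(flp, pl, backend = "boot")
  expect_equal(alt$objective_values, base$objective_values,
               tolerance = 1e-6)
  expect_equal(alt$flux[c(3, 6)], base$flux[c(3, 6)], tolerance = 1e-6)
})

test_that("appending a priority level never disturbs earlier optima", {
  toy <- make_growth_toy()
  flp <- build_feasibility(model_lp(toy$model))
  short <- compile_priorities(priority_list(lex_level("biomass", "max")),
                              toy$model, toy$exmap)
  long <- compile_priorities(toy_priorities(), toy$model, toy$exmap)
  s_short <- lexicographic_solve(flp, short)
  s_long <- lexicographic_solve(flp, long)
  expect_equal(s_long$objective_values[1], s_short$objective_values[1],
               tolerance = 1e-8)
})

test_that("optimal objective values respond O(eta) to bound perturbations", {
  toy <- make_growth_toy()
  pl <- compile_priorities(toy_priorities(), toy$model, toy$exmap)
  base <- lexicographic_solve(build_feasibility(model_lp(toy$model)), pl)
  eta <- 1e-4
  for (j in which(is.finite(toy$model$lb_default))) {
    lb <- toy$model$lb_default
    lb[j] <- lb[j] + eta
    pert <- lexicographic_solve(
      build_feasibility(bounded_lp(toy$model$S, lb, toy$model$ub_default)),
      pl)
    expect_lt(max(abs(pert$objective_values - base$objective_values)),
              10 * eta)
    expect_lt(abs(pert$feasibility_value - base$feasibility_value),
              10 * eta)
  }
})
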