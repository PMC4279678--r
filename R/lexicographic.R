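#' Build a priority list of lexicographic objectives
#'
#' Orders the objectives optimized sequentially at every right-hand-side
#' evaluation. The slack-minimization feasibility objective is always,
#' implicitly, at top priority; it is not listed. By convention the first
#' listed level maximizes biomass and subsequent levels pin down each
#' exchange flux consumed by the dynamic mass balances, so that the
#' reported fluxes are unique and vary continuously with the state.
#'
#' Each level is a list with fields:
#' \describe{
#'   \item{`cost`}{numeric cost vector on reaction space, or `NULL` when
#'     `name` is given;}
#'   \item{`name`}{name of an exchange species (resolved against an
#'     exchange map at compile time) or `"biomass"`;}
#'   \item{`sense`}{`"max"` or `"min"`, applied to the signed flux. A
#'     "maximize production and minimize consumption" compound objective is
#'     exactly `sense = "max"` on the signed exchange flux.}
#' }
#'
#' @param ... level specifications, e.g. `lex_level("biomass", "max")`.
#' @return An object of class `priority_list`.
#' @seealso [lex_level()], [compile_priorities()]
#' @export
priority_list <- function(...) {
  levels <- list(...)
  if (!length(levels)) stop("priority list must contain at least one level")
  for (lv in levels) {
    if (!inherits(lv, "lex_level")) {
      stop("each level must be built with lex_level()")
    }
  }
  structure(list(levels = levels), class = "priority_list")
}

#' Define one lexicographic objective level
#'
#' @param what a numeric cost vector on reaction space, `"biomass"`, or the
#'   name of an exchange species known to the model's exchange map.
#' @param sense `"max"` or `"min"`.
#' @return A `lex_level` object.
#' @export
lex_level <- function(what, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.numeric(what)) {
    structure(list(cost = as.numeric(what), name = NULL, sense = sense),
              class = "lex_level")
  } else if (is.character(what) && length(what) == 1L) {
    structure(list(cost = NULL, name = what, sense = sense),
              class = "lex_level")
  } else {
    stop("lex_level: 'what' must be a cost vector or a single name")
  }
}

#' @export
print.priority_list <- function(x, ...) {
  cat(sprintf("<priority_list> %d levels (after implicit feasibility)\n",
              length(x$levels)))
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    lab <- if (!is.null(lv$name)) lv$name else "custom cost"
    cat(sprintf("  %d: %s %s\n", i, lv$sense, lab))
  }
  invisible(x)
}

#' Resolve named priority levels to cost vectors
#'
#' Levels naming `"biomass"` compile to a unit cost on the model's biomass
#' reaction; levels naming an exchange species compile to a unit cost on
#' the mapped exchange reaction, signed so that `"max"` maximizes the
#' *signed* flux under the positive-equals-secretion convention (hence a
#' single signed cost expresses "maximize production and minimize
#' consumption").
#'
#' @param plist a [priority_list()].
#' @param model a `metabolic_model`.
#' @param exmap an [exchange_map()] for the model.
#' @return A `priority_list` whose every level carries a numeric cost.
#' @export
compile_priorities <- function(plist, model, exmap) {
  stopifnot(inherits(plist, "priority_list"))
  n_r <- length(model$reaction_ids)
  levels <- lapply(plist$levels, function(lv) {
    if (!is.null(lv$cost)) {
      if (length(lv$cost) != n_r) {
        stop("cost vector length does not match reaction count")
      }
      return(lv)
    }
    cost <- rep(0, n_r)
    if (identical(lv$name, "biomass")) {
      cost[model$biomass_reaction] <- 1
    } else {
      row <- exmap$entries[exmap$entries$species == lv$name, ]
      if (nrow(row) == 0L) {
        stop("priority level names unmapped species: ", lv$name)
      }
      cost[row$reaction] <- row$sign
    }
    lv$cost <- cost
    lv
  })
  structure(list(levels = levels), class = "priority_list")
}

lex_delta <- function(z) max(1e-9, 1e-9 * abs(z))

#' Lexicographic optimization with feasibility at top priority
#'
#' Solves the priority-ordered sequence of LPs over the slack-augmented
#' system: level 0 minimizes the total slack (the feasibility objective);
#' each subsequent level optimizes its own cost subject to every earlier
#' optimum being held fixed within a small two-sided tolerance. Optimal
#' *values* of LPs are unique and continuous in the bounds even when
#' optimal *points* are not, so the returned objective values — and any
#' flux pinned by a priority level — are independent of the solver's vertex
#' selection.
#'
#' @param flp a [build_feasibility()] problem.
#' @param priorities a [priority_list()] with numeric costs (length
#'   `n_r`; see [compile_priorities()]).
#' @param lb,ub optional state-dependent bound vectors overriding the base
#'   LP bounds (length `n_r`).
#' @param backend LP backend key, see [solve_lp()].
#' @return A `lexicographic_solution`: `objective_values` (one per listed
#'   level, in the level's own sense), `flux` (length `n_r`),
#'   `feasibility_value` (level-0 optimum, `>= 0`), `status` (`"solved"`
#'   or `"infeasible_bounds"`), and `level_status`.
#' @export
lexicographic_solve <- function(flp, priorities, lb = NULL, ub = NULL,
                                backend = "simplex") {
  stopifnot(inherits(flp, "feasibility_lp"),
            inherits(priorities, "priority_list"))
  can <- flp_canonical(flp, lb = lb, ub = ub)
  if (any(can$lb > can$ub)) {
    return(structure(
      list(objective_values = rep(NA_real_, length(priorities$levels)),
           flux = rep(NA_real_, flp$n_r),
           feasibility_value = NA_real_,
           status = "infeasible_bounds",
           level_status = character(0)),
      class = "lexicographic_solution"
    ))
  }
  n_all <- length(can$feas_cost)
  n_r <- flp$n_r

  Ale <- matrix(0, 0L, n_all)
  ble <- numeric(0)

  fix_level <- function(cost_min, z) {
    # two-sided band  z - delta <= cost_min' x <= z + delta
    d <- lex_delta(z)
    Ale <<- rbind(Ale, cost_min, -cost_min)
    ble <<- c(ble, z + d, -(z - d))
  }

  # level 0: feasibility
  res <- solve_canonical(can$feas_cost, can$Aeq, can$beq, Ale, ble,
                         can$lb, can$ub, backend = backend)
  if (res$status != "optimal") {
    stop("feasibility LP did not solve (status ", res$status,
         "); this indicates a malformed problem, not LP infeasibility")
  }
  feas_val <- max(0, res$objective)
  fix_level(can$feas_cost, res$objective)
  x <- res$x

  n_lv <- length(priorities$levels)
  obj_vals <- rep(NA_real_, n_lv)
  lv_status <- character(n_lv)

  for (i in seq_len(n_lv)) {
    lv <- priorities$levels[[i]]
    if (is.null(lv$cost)) {
      stop("priority level ", i, " has no cost vector; ",
           "use compile_priorities() first")
    }
    cost <- c(lv$cost, rep(0, n_all - n_r))
    cost_min <- if (lv$sense == "max") -cost else cost
    res <- solve_canonical(cost_min, can$Aeq, can$beq, Ale, ble,
                           can$lb, can$ub, backend = backend)
    if (res$status == "unbounded") {
      lv_status[i] <- "unbounded"
      lv_status[seq_len(n_lv) > i] <- "skipped"
      break
    }
    if (res$status != "optimal") {
      lv_status[i] <- res$status
      lv_status[seq_len(n_lv) > i] <- "skipped"
      break
    }
    lv_status[i] <- "optimal"
    obj_vals[i] <- if (lv$sense == "max") -res$objective else res$objective
    fix_level(cost_min, res$objective)
    x <- res$x
  }

  structure(
    list(objective_values = obj_vals,
         flux = x[seq_len(n_r)],
         feasibility_value = feas_val,
         status = "solved",
         level_status = lv_status),
    class = "lexicographic_solution"
  )
}

#' @export
print.lexicographic_solution <- function(x, ...) {
  cat(sprintf("<lexicographic_solution> status = %s, feasibility = %.3g\n",
              x$status, x$feasibility_value))
  cat("  objective values:",
      paste(signif(x$objective_values, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Flux-range diagnostic after lexicographic fixing
#'
#' Computes the attainable minimum and maximum of one flux subject to every
#' priority-level optimum of a solved lexicographic problem being held
#' fixed. Equal endpoints (within tolerance) certify that the priority
#' list is long enough to pin that flux uniquely; a nondegenerate interval
#' flags a flux that would make the dynamic system ill-defined if consumed
#' by the right-hand side.
#'
#' @param flp,priorities,backend as in [lexicographic_solve()].
#' @param solution a solved `lexicographic_solution`.
#' @param flux_index integer reaction index to probe.
#' @param lb,ub optional bound overrides matching the original solve.
#' @return Numeric vector `c(min, max)` of attainable values.
#' @export
uniqueness_diagnostic <- function(flp, priorities, solution, flux_index,
                                  lb = NULL, ub = NULL,
                                  backend = "simplex") {
  stopifnot(inherits(solution, "lexicographic_solution"),
            solution$status == "solved")
  can <- flp_canonical(flp, lb = lb, ub = ub)
  n_all <- length(can$feas_cost)
  n_r <- flp$n_r
  Ale <- matrix(0, 0L, n_all)
  ble <- numeric(0)
  add_fix <- function(cost_min, z) {
    d <- lex_delta(z)
    Ale <<- rbind(Ale, cost_min, -cost_min)
    ble <<- c(ble, z + d, -(z - d))
  }
  add_fix(can$feas_cost, solution$feasibility_value)
  for (i in seq_along(priorities$levels)) {
    lv <- priorities$levels[[i]]
    if (is.na(solution$objective_values[i])) break
    cost <- c(lv$cost, rep(0, n_all - n_r))
    z <- solution$objective_values[i]
    if (lv$sense == "max") add_fix(-cost, -z) else add_fix(cost, z)
  }
  probe <- rep(0, n_all)
  probe[flux_index] <- 1
  lo <- solve_canonical(probe, can$Aeq, can$beq, Ale, ble,
                        can$lb, can$ub, backend = backend)
  hi <- solve_canonical(-probe, can$Aeq, can$beq, Ale, ble,
                        can$lb, can$ub, backend = backend)
  c(min = if (lo$status == "optimal") lo$objective else -Inf,
    max = if (hi$status == "optimal") -hi$objective else Inf)
}
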