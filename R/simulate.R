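#' Simulation options
#'
#' @param t_span numeric `c(t0, tf)`, hours.
#' @param rtol,atol integrator tolerances (defaults 1e-6, 1e-8).
#' @param epsilon feasibility tolerance on the instantaneous penalty rate:
#'   a trajectory is flagged infeasible from the first time the summed
#'   per-species feasibility objective exceeds `epsilon` (default 1e-6,
#'   penalty-rate units mmol/L/h-equivalent).
#' @param nonnegative logical: project negative excursions of biomass and
#'   metabolite states by zeroing inward derivatives at the origin
#'   (kinetic laws additionally clamp negative concentrations). Disable
#'   for pH DAE runs.
#' @param restart_times forcing-discontinuity times (hours) at which the
#'   integrator is restarted; day/night light transitions of any
#'   configured light model are added automatically.
#' @param backend LP backend key (see [solve_lp()]).
#' @param n_out number of output grid points (default 101).
#' @param seed integer, recorded in the manifest (fixture generation
#'   only; the simulation itself is deterministic).
#' @return A `sim_options` object.
#' @export
sim_options <- function(t_span, rtol = 1e-6, atol = 1e-8, epsilon = 1e-6,
                        nonnegative = TRUE, restart_times = numeric(0),
                        backend = "simplex", n_out = 101L, seed = NULL) {
  stopifnot(length(t_span) == 2L, t_span[1L] < t_span[2L],
            rtol > 0, atol > 0, epsilon > 0, n_out >= 2L)
  structure(
    list(t_span = as.numeric(t_span), rtol = rtol, atol = atol,
         epsilon = epsilon, nonnegative = nonnegative,
         restart_times = sort(unique(as.numeric(restart_times))),
         backend = backend, n_out = as.integer(n_out), seed = seed),
    class = "sim_options"
  )
}

# day/night transition times of all configured light models within a span
light_transitions <- function(config, t_span) {
  out <- numeric(0)
  for (sp in config$species) {
    if (is.null(sp$photon)) next
    lm <- sp$photon$light
    days <- seq(floor(t_span[1L] / 24) - 1, ceiling(t_span[2L] / 24) + 1)
    out <- c(out, days * 24 + lm$dawn, days * 24 + lm$dusk)
  }
  out <- sort(unique(out))
  out[out > t_span[1L] & out < t_span[2L]]
}

# Build the full initial state (penalty zeroed, speciation made
# consistent) from a named partial state.
build_initial_state <- function(config, x0) {
  lay <- config$layout
  y0 <- stats::setNames(numeric(length(lay$state_names)), lay$state_names)
  known <- intersect(names(x0), lay$state_names)
  unknown <- setdiff(names(x0), lay$state_names)
  if (length(unknown)) {
    stop("initial state names not in the layout: ",
         paste(unknown, collapse = ", "),
         " (expected among: ", paste(lay$state_names, collapse = ", "), ")")
  }
  y0[known] <- unlist(x0)[known]
  missing_diff <- setdiff(setdiff(lay$diff_names, "penalty"), known)
  if (length(missing_diff)) {
    stop("initial state is missing: ", paste(missing_diff, collapse = ", "))
  }
  if (!is.null(config$ph)) {
    sp <- solve_speciation(y0[["C_T"]], y0[["N_T"]], config$ph$constants)
    y0[lay$i_alg] <- unclass(sp)[.spec_algebraic]
    chk <- index1_check(sp, config$ph$constants)
    if (!chk$index1) {
      stop("pH DAE is not index-1 at the consistent initial speciation ",
           "(rcond = ", signif(chk$rcond, 3), ")")
    }
  }
  y0
}

#' Simulate a DFBA community
#'
#' Integrates the extended system assembled by [assemble_rhs()] with a
#' stiff variable-order BDF method (`deSolve`, lsode core), or — when a pH
#' block is configured — the index-1 DAE via the implicit Runge-Kutta
#' method `radau` with a singular mass matrix and a consistent initial
#' speciation from [solve_speciation()]. Because the feasibility-first
#' lexicographic hierarchy is solvable at every state with a nonempty
#' bound box, integration never aborts on LP infeasibility; instead the
#' integrated penalty state departs from zero and
#' [detect_infeasibility()] brackets the onset time. The integrator is
#' restarted at day/night light transitions and any user-supplied
#' `restart_times` so the nonsmooth forcing kinks never sit inside a
#' step.
#'
#' @param config a [community_config()].
#' @param x0 named numeric vector of initial differential states
#'   (biomass per species as `biomass_<name>`, metabolites by name,
#'   `C_T`/`N_T` for pH runs; `penalty` defaults to 0).
#' @param options a [sim_options()].
#' @return A `simulation_result`: `times`, `states` (matrix, one row per
#'   time), per-species `fluxes` (matrices of signed exchange rates) and
#'   `growth`, the `penalty` trajectory and its instantaneous rate
#'   `feasibility_rate`, `infeasibility_time` (`NA` if feasible
#'   throughout), `diagnostics` (LP solve counts), and the `options`
#'   used.
#' @export
simulate_community <- function(config, x0, options) {
  stopifnot(inherits(config, "community_config"),
            inherits(options, "sim_options"))
  lay <- config$layout
  y0 <- build_initial_state(config, x0)
  t0 <- options$t_span[1L]
  tf <- options$t_span[2L]
  breaks <- sort(unique(c(
    t0, tf,
    options$restart_times[options$restart_times > t0 &
                            options$restart_times < tf],
    light_transitions(config, options$t_span)
  )))
  grid <- sort(unique(c(seq(t0, tf, length.out = options$n_out), breaks)))

  nn_idx <- c(lay$i_biomass, lay$i_met)   # states kept nonnegative
  deriv <- function(t, y, parms) {
    r <- assemble_rhs(t, y, config, backend = options$backend)
    dx <- r$dx
    if (options$nonnegative) {
      hit <- nn_idx[y[nn_idx] <= 0 & dx[nn_idx] < 0]
      dx[hit] <- 0
    }
    list(dx)
  }

  count0 <- lp_solve_count()
  rows <- NULL
  y_cur <- y0
  for (seg in seq_len(length(breaks) - 1L)) {
    tt <- grid[grid >= breaks[seg] & grid <= breaks[seg + 1L]]
    if (length(tt) < 2L) tt <- c(breaks[seg], breaks[seg + 1L])
    sol <- if (is.null(config$ph)) {
      deSolve::ode(y = y_cur, times = tt, func = deriv, parms = NULL,
                   method = "bdf", rtol = options$rtol, atol = options$atol)
    } else {
      nd <- lay$n_diff
      mass <- diag(c(rep(1, nd), rep(0, length(lay$alg_names))))
      deSolve::radau(y = y_cur, times = tt, func = deriv, parms = NULL,
                     mass = mass, rtol = options$rtol, atol = options$atol)
    }
    sol <- unclass(sol)
    y_cur <- sol[nrow(sol), -1L]
    rows <- if (is.null(rows)) sol else rbind(rows, sol[-1L, , drop = FALSE])
  }
  times <- rows[, 1L]
  states <- rows[, -1L, drop = FALSE]
  colnames(states) <- lay$state_names

  # per-output-point fluxes, growth and instantaneous feasibility values
  n_t <- length(times)
  n_sp <- length(config$species)
  growth <- matrix(NA_real_, n_t, n_sp,
                   dimnames = list(NULL, lay$species))
  feas_rate <- numeric(n_t)
  fluxes <- lapply(config$species, function(sp) {
    matrix(NA_real_, n_t, nrow(sp$exmap$entries),
           dimnames = list(NULL, sp$exmap$entries$species))
  })
  names(fluxes) <- lay$species
  for (i in seq_len(n_t)) {
    r <- assemble_rhs(times[i], states[i, ], config,
                      backend = options$backend)
    growth[i, ] <- r$growth
    feas_rate[i] <- sum(r$feasibility_values)
    for (k in seq_len(n_sp)) fluxes[[k]][i, ] <- r$fluxes[[k]]
  }

  result <- structure(
    list(times = times, states = states, fluxes = fluxes, growth = growth,
         penalty = states[, "penalty"], feasibility_rate = feas_rate,
         infeasibility_time = NA_real_,
         diagnostics = list(lp_solves = lp_solve_count() - count0,
                            n_out = n_t,
                            segments = length(breaks) - 1L),
         options = options,
         species = lay$species,
         ph = !is.null(config$ph)),
    class = "simulation_result"
  )
  result$infeasibility_time <- detect_infeasibility(result, options$epsilon)
  result
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d points on [%.3g, %.3g] h, %d species\n",
              length(x$times), min(x$times), max(x$times),
              length(x$species)))
  cat(sprintf("  final penalty %.4g; infeasibility time: %s\n",
              x$penalty[length(x$penalty)],
              if (is.na(x$infeasibility_time)) "none" else
                sprintf("%.4g h", x$infeasibility_time)))
  invisible(x)
}

#' Locate the onset of infeasibility from a penalty trajectory
#'
#' Scans the instantaneous feasibility objective (the penalty-rate time
#' series) for the earliest grid point exceeding `epsilon` and refines the
#' crossing by linear interpolation between the bracketing points. Only
#' trajectories whose penalty rate stays within `epsilon` everywhere are
#' feasible.
#'
#' @param result a `simulation_result`.
#' @param epsilon feasibility tolerance (defaults to the run's option).
#' @return The infeasibility onset time (hours), or `NA` if the
#'   trajectory stays feasible.
#' @export
detect_infeasibility <- function(result, epsilon = NULL) {
  if (is.null(epsilon)) epsilon <- result$options$epsilon
  g <- result$feasibility_rate
  tt <- result$times
  idx <- which(g > epsilon)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(tt[1L])
  # linear interpolation of the epsilon crossing in [t_{i-1}, t_i]
  t0 <- tt[i - 1L]
  t1 <- tt[i]
  g0 <- g[i - 1L]
  g1 <- g[i]
  t0 + (epsilon - g0) / (g1 - g0) * (t1 - t0)
}

#' Write simulation results to disk
#'
#' Writes a tidy CSV of the trajectories (one row per time point; columns
#' are states, per-species exchange fluxes as `<species>.<exchange>`,
#' growth rates, penalty rate) plus, for pH runs, the pH column, and a
#' JSON run manifest recording the options and solver backend.
#'
#' @param result a `simulation_result`.
#' @param path output directory (created if needed).
#' @param format `"csv"` (the only format currently).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, path, format = "csv") {
  format <- match.arg(format, "csv")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(time = result$times, result$states,
                   check.names = FALSE)
  for (k in seq_along(result$fluxes)) {
    fm <- result$fluxes[[k]]
    colnames(fm) <- paste(result$species[k], colnames(fm), sep = ".")
    df <- cbind(df, fm)
  }
  gm <- result$growth
  colnames(gm) <- paste0("mu_", result$species)
  df <- cbind(df, gm, feasibility_rate = result$feasibility_rate)
  if (result$ph) df$pH <- ph_value(result$states[, "h"])
  traj <- file.path(path, "trajectories.csv")
  utils::write.csv(df, traj, row.names = FALSE)
  manifest <- list(
    package = "dfbalex",
    version = as.character(utils::packageVersion("dfbalex")),
    backend = result$options$backend,
    epsilon = result$options$epsilon,
    rtol = result$options$rtol, atol = result$options$atol,
    t_span = result$options$t_span,
    n_out = result$options$n_out,
    seed = result$options$seed,
    species = result$species,
    ph = result$ph,
    infeasibility_time = result$infeasibility_time,
    lp_solves = result$diagnostics$lp_solves
  )
  man <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(traj, man))
}

#' LP solves needed for one right-hand-side evaluation
#'
#' Instrumented counter used by the linear-scaling diagnostics: evaluates
#' [assemble_rhs()] once at `(t, x0)` and reports how many LP solves it
#' issued (one feasibility solve plus one per priority level, per
#' species).
#'
#' @param config a [community_config()].
#' @param x0 named initial state (as for [simulate_community()]).
#' @param t evaluation time (default: 0).
#' @param backend LP backend key.
#' @return Integer LP solve count.
#' @export
rhs_lp_solves <- function(config, x0, t = 0, backend = "simplex") {
  y0 <- build_initial_state(config, x0)
  before <- lp_solve_count()
  assemble_rhs(t, y0, config, backend = backend)
  lp_solve_count() - before
}
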