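#' Construct a bounded-variable linear program
#'
#' The flux balance LP of constraint-based modelling: optimize `c' v` over
#' the flux cone `S v = 0` intersected with box bounds `lb <= v <= ub`
#' (mmol/gDW/h; the biomass column is 1/h). Bounds may be infinite.
#'
#' @param S numeric matrix, metabolites x reactions (stoichiometry).
#' @param lb,ub numeric vectors of flux bounds, length `ncol(S)`.
#' @param c numeric cost vector, length `ncol(S)`. Defaults to zeros.
#' @param sense `"max"` or `"min"`.
#' @return An object of class `bounded_lp`.
#' @export
bounded_lp <- function(S, lb, ub, c = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- as.matrix(S)
  if (is.null(c)) c <- rep(0, ncol(S))
  stopifnot(length(lb) == ncol(S), length(ub) == ncol(S),
            length(c) == ncol(S))
  if (any(lb > ub)) {
    bad <- which(lb > ub)
    stop("lb > ub for variable(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
         c = as.numeric(c), sense = sense),
    class = "bounded_lp"
  )
}

#' @export
print.bounded_lp <- function(x, ...) {
  cat(sprintf("<bounded_lp> %d metabolites x %d reactions, sense = %s\n",
              nrow(x$S), ncol(x$S), x$sense))
  invisible(x)
}

#' Build the phase-one LP feasibility problem
#'
#' Augments the mass-balance rows of a bounded LP with nonnegative slack
#' pairs `s+`, `s-` so that the equalities read `S v + s+ - s- = 0`, and
#' sets the feasibility cost `sum(s+) + sum(s-)` as the objective. The
#' resulting problem is feasible whenever the box `lb <= ub` is nonempty,
#' and its optimal value is zero if and only if the original LP is feasible.
#' The optimal value measures the distance from feasibility and, integrated
#' along a DFBA trajectory, yields the penalty function.
#'
#' @param lp a [bounded_lp()].
#' @return An object of class `feasibility_lp` carrying the base LP and the
#'   slack block dimensions.
#' @export
build_feasibility <- function(lp) {
  stopifnot(inherits(lp, "bounded_lp"))
  structure(
    list(base = lp, n_r = ncol(lp$S), n_q = nrow(lp$S)),
    class = "feasibility_lp"
  )
}

#' @export
print.feasibility_lp <- function(x, ...) {
  cat(sprintf("<feasibility_lp> base %d x %d, %d slack pairs\n",
              x$n_q, x$n_r, x$n_q))
  invisible(x)
}

# Canonical pieces of the slack-augmented system. Variables are ordered
# [v (n_r), s+ (n_q), s- (n_q)].
flp_canonical <- function(flp, lb = NULL, ub = NULL) {
  n_r <- flp$n_r
  n_q <- flp$n_q
  S <- flp$base$S
  Aeq <- cbind(S, diag(1, n_q), -diag(1, n_q))
  list(
    Aeq = Aeq,
    beq = rep(0, n_q),
    lb = c(if (is.null(lb)) flp$base$lb else lb, rep(0, 2L * n_q)),
    ub = c(if (is.null(ub)) flp$base$ub else ub, rep(Inf, 2L * n_q)),
    feas_cost = c(rep(0, n_r), rep(1, 2L * n_q))
  )
}

#' Solve a linear program
#'
#' Solver abstraction over the package's LP backends. For a
#' [bounded_lp()] the problem `opt c'v s.t. S v = 0, lb <= v <= ub` is
#' solved; for a [build_feasibility()] object the slack-minimization
#' phase-one problem is solved. Solver failure is reported as a status,
#' never as an error, so that an integration loop embedding the solve can
#' always continue.
#'
#' @param lp a `bounded_lp` or `feasibility_lp`.
#' @param backend `"simplex"` (the package's bounded-variable two-phase
#'   simplex) or `"boot"` (`boot::simplex` on the identical standardized
#'   problem). Backends are interchangeable: downstream results agree
#'   within solver tolerance.
#' @return A list with elements `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"infeasible_bounds"`,
#'   `"numerical_failure"`), `objective`, and the primal point `x`
#'   (fluxes; for a feasibility problem the slack blocks are appended).
#' @export
solve_lp <- function(lp, backend = "simplex") {
  if (inherits(lp, "bounded_lp")) {
    obj <- if (lp$sense == "max") -lp$c else lp$c
    res <- solve_canonical(obj, lp$S, rep(0, nrow(lp$S)),
                           lb = lp$lb, ub = lp$ub, backend = backend)
    if (res$status == "optimal" && lp$sense == "max") {
      res$objective <- -res$objective
    }
    if (res$status == "infeasible_bounds") res$status <- "infeasible"
    return(res)
  }
  if (inherits(lp, "feasibility_lp")) {
    can <- flp_canonical(lp)
    res <- solve_canonical(can$feas_cost, can$Aeq, can$beq,
                           lb = can$lb, ub = can$ub, backend = backend)
    return(res)
  }
  stop("solve_lp expects a bounded_lp or feasibility_lp")
}
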