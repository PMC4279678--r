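#' Acid-base equilibrium constants (25 degrees C defaults)
#'
#' Constants of the carbonate system, ammonium and water autoionization,
#' supplied as pK values on the conventional mol/L scale and stored
#' internally on the package's mmol/L concentration scale. Defaults are
#' the standard 25 degrees C literature values; all are overridable.
#'
#' @param pK1 first carbonic-acid constant (CO2/HCO3-), default 6.35.
#' @param pK2 second carbonic-acid constant (HCO3-/CO3^2-), default 10.33.
#' @param pKa_NH4 ammonium acid constant (NH4+/NH3), default 9.25.
#' @param pKw water autoionization, default 14.
#' @return An `equilibrium_constants` object with fields `K1`, `K2`,
#'   `Ka`, `Kw` in mmol/L units (`Kw` in (mmol/L)^2).
#' @export
equilibrium_constants <- function(pK1 = 6.35, pK2 = 10.33,
                                  pKa_NH4 = 9.25, pKw = 14) {
  stopifnot(pK1 > 0, pK2 > 0, pKa_NH4 > 0, pKw > 0)
  structure(
    list(K1 = 10^(-pK1) * 1e3, K2 = 10^(-pK2) * 1e3,
         Ka = 10^(-pKa_NH4) * 1e3, Kw = 10^(-pKw) * 1e6,
         pK = c(pK1 = pK1, pK2 = pK2, pKa_NH4 = pKa_NH4, pKw = pKw)),
    class = "equilibrium_constants"
  )
}

# canonical ordering of the algebraic block
.spec_algebraic <- c("co2", "hco3", "co3", "nh3", "nh4", "h")

#' Speciation state of the carbonate/ammonia system
#'
#' @param C_T,N_T total dissolved carbon and nitrogen, mmol/L
#'   (differential variables of the DAE).
#' @param co2,hco3,co3,nh3,nh4,h ionic/molecular species concentrations,
#'   mmol/L (algebraic variables).
#' @return A named numeric vector of class `speciation_state`.
#' @export
speciation_state <- function(C_T, N_T, co2, hco3, co3, nh3, nh4, h) {
  structure(
    c(C_T = C_T, N_T = N_T, co2 = co2, hco3 = hco3, co3 = co3,
      nh3 = nh3, nh4 = nh4, h = h),
    class = "speciation_state"
  )
}

#' Residuals of the pH equilibrium system
#'
#' The six algebraic relations that close the carbonate/ammonia DAE:
#' carbon closure (`C_T = CO2 + HCO3- + CO3^2-`), nitrogen closure
#' (`N_T = NH3 + NH4+`), the two carbonate equilibria
#' (`H+ . HCO3- = K1 . CO2`, `H+ . CO3^2- = K2 . HCO3-`), the ammonium
#' equilibrium (`H+ . NH3 = Ka . NH4+`), and charge balance with OH-
#' eliminated through `Kw / H+`
#' (`NH4+ + H+ = HCO3- + 2 CO3^2- + Kw / H+`). All zero iff the state is
#' a consistent speciation. H+ exchange by the organisms is neglected in
#' the charge balance and the solution's net ionic valency is taken as
#' zero.
#'
#' @param state a [speciation_state()] (or named vector with its fields).
#' @param constants an [equilibrium_constants()].
#' @return Numeric residual vector of length 6, named
#'   `c("carbon", "nitrogen", "K1", "K2", "Ka", "charge")`.
#' @export
equilibrium_residuals <- function(state, constants) {
  s <- as.list(unclass(state)[c("C_T", "N_T", .spec_algebraic)])
  if (s$h == 0) stop("H+ concentration is zero: OH- = Kw/H+ is undefined")
  c(carbon = s$C_T - s$co2 - s$hco3 - s$co3,
    nitrogen = s$N_T - s$nh3 - s$nh4,
    K1 = s$h * s$hco3 - constants$K1 * s$co2,
    K2 = s$h * s$co3 - constants$K2 * s$hco3,
    Ka = s$h * s$nh3 - constants$Ka * s$nh4,
    charge = s$nh4 + s$h - s$hco3 - 2 * s$co3 - constants$Kw / s$h)
}

# speciation fractions at a given H+ (all in mmol/L)
speciate_at_h <- function(C_T, N_T, h, k) {
  den_c <- h^2 + k$K1 * h + k$K1 * k$K2
  den_n <- h + k$Ka
  list(co2 = C_T * h^2 / den_c,
       hco3 = C_T * k$K1 * h / den_c,
       co3 = C_T * k$K1 * k$K2 / den_c,
       nh4 = N_T * h / den_n,
       nh3 = N_T * k$Ka / den_n)
}

#' Solve the speciation system for given totals
#'
#' Finds the unique positive root of the charge balance as a function of
#' H+ (solved in log space so positivity is structural across the full pH
#' range), then distributes `C_T` and `N_T` over their protonation states.
#' Used to construct consistent initial conditions for the pH DAE.
#'
#' @param C_T,N_T total carbon and nitrogen, mmol/L (`>= 0`).
#' @param constants an [equilibrium_constants()].
#' @param tol relative root tolerance on H+ (default 1e-12).
#' @return A consistent [speciation_state()].
#' @export
solve_speciation <- function(C_T, N_T,
                             constants = equilibrium_constants(),
                             tol = 1e-12) {
  stopifnot(C_T >= 0, N_T >= 0)
  k <- constants
  charge_mismatch <- function(logh) {
    h <- exp(logh)
    sp <- speciate_at_h(C_T, N_T, h, k)
    sp$nh4 + h - sp$hco3 - 2 * sp$co3 - k$Kw / h
  }
  # h in mmol/L: pH 14 ~ 1e-11, pH 0 ~ 1e3
  lo <- log(1e-12)
  hi <- log(1e3)
  if (charge_mismatch(lo) > 0 || charge_mismatch(hi) < 0) {
    stop("speciation root not bracketed in pH (0, 15): ",
         "charge mismatch at bracket ends = ",
         signif(charge_mismatch(lo), 3), ", ",
         signif(charge_mismatch(hi), 3))
  }
  root <- stats::uniroot(charge_mismatch, c(lo, hi), tol = tol)
  h <- exp(root$root)
  # one Newton polish on the charge balance in h
  sp <- speciate_at_h(C_T, N_T, h, k)
  speciation_state(C_T = C_T, N_T = N_T,
                   co2 = sp$co2, hco3 = sp$hco3, co3 = sp$co3,
                   nh3 = sp$nh3, nh4 = sp$nh4, h = h)
}

#' pH of a speciation state
#'
#' @param state a [speciation_state()] (or an H+ concentration in mmol/L).
#' @return pH on the conventional mol/L scale.
#' @export
ph_value <- function(state) {
  x <- unclass(state)
  h <- if ("h" %in% names(x)) x[["h"]] else x
  -log10(h / 1e3)
}

#' Index-1 check for the pH DAE
#'
#' Differentiates [equilibrium_residuals()] with respect to the six
#' algebraic variables (finite differences) and tests the Jacobian for
#' numerical nonsingularity via its reciprocal condition number. A
#' nonsingular algebraic Jacobian makes the coupled system an index-1 DAE,
#' integrable by a mass-matrix stiff method.
#'
#' @param state a strictly positive [speciation_state()].
#' @param constants an [equilibrium_constants()].
#' @param rcond_tol reciprocal-condition threshold (default 1e-12),
#'   applied to the row-equilibrated Jacobian so the check reflects
#'   structural singularity rather than the disparate magnitudes of the
#'   equilibrium constants.
#' @return A list: `index1` (logical), `rcond` (raw reciprocal condition
#'   estimate, which collapses as H+ tends to zero), `rcond_scaled` (the
#'   equilibrated estimate used for the decision) and the `jacobian`.
#' @export
index1_check <- function(state, constants = equilibrium_constants(),
                         rcond_tol = 1e-12) {
  x <- unclass(state)
  J <- matrix(0, 6L, 6L,
              dimnames = list(names(equilibrium_residuals(state, constants)),
                              .spec_algebraic))
  f0 <- equilibrium_residuals(state, constants)
  for (j in seq_along(.spec_algebraic)) {
    nm <- .spec_algebraic[j]
    hstep <- max(1e-8, 1e-8 * abs(x[[nm]]))
    xp <- x
    xp[[nm]] <- xp[[nm]] + hstep
    J[, j] <- (equilibrium_residuals(xp, constants) - f0) / hstep
  }
  # raw reciprocal condition: diverges to 0 as H+ -> 0 (the OH- row)
  rc_raw <- tryCatch(rcond(J), error = function(e) 0)
  # row-equilibrated copy: insensitive to the disparate magnitudes of the
  # closure rows (O(1)) and the equilibrium rows (O(K)), so it flags only
  # structural singularity
  rs <- apply(abs(J), 1L, max)
  rs[rs == 0] <- 1
  rc_scaled <- tryCatch(rcond(J / rs), error = function(e) 0)
  ok <- is.finite(rc_scaled) && rc_scaled > rcond_tol &&
    is.finite(rc_raw) && rc_raw > 1e-30
  list(index1 = ok, rcond = rc_raw, rcond_scaled = rc_scaled, jacobian = J)
}
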