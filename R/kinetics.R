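#' Michaelis-Menten uptake law
#'
#' Upper bound on the uptake rate of one substrate by one organism,
#' `vmax * s / (Ks + s)`, optionally divided by `(1 + i/Ki)` for each
#' competitive inhibitor. A `custom` form accepts an arbitrary function of
#' the concentration map for kinetic laws not expressible in this family.
#'
#' @param species extracellular substrate name.
#' @param vmax maximal uptake rate, mmol/gDW/h (`>= 0`).
#' @param Ks half-saturation constant, mmol/L (`> 0`).
#' @param inhibitors named numeric vector of inhibition constants `Ki`
#'   (mmol/L), names being the inhibiting species.
#' @param form one of `"michaelis_menten"`,
#'   `"michaelis_menten_inhibited"`, `"custom"`.
#' @param fn for `form = "custom"`: `function(concentrations)` returning a
#'   nonnegative bound.
#' @return An `uptake_law` object.
#' @export
uptake_law <- function(species, vmax = NULL, Ks = NULL,
                       inhibitors = numeric(0),
                       form = c("michaelis_menten",
                                "michaelis_menten_inhibited", "custom"),
                       fn = NULL) {
  form <- match.arg(form)
  if (form == "custom") {
    stopifnot(is.function(fn))
  } else {
    stopifnot(is.numeric(vmax), vmax >= 0, is.numeric(Ks), Ks > 0)
    if (length(inhibitors)) {
      stopifnot(!is.null(names(inhibitors)), all(inhibitors > 0))
      form <- "michaelis_menten_inhibited"
    }
  }
  structure(
    list(species = species, vmax = vmax, Ks = Ks,
         inhibitors = inhibitors, form = form, fn = fn),
    class = "uptake_law"
  )
}

#' Evaluate an uptake bound at given concentrations
#'
#' Negative concentrations (transient integrator artifacts) are clamped to
#' zero before evaluation, so the bound is always in `[0, vmax]` and
#' monotone nondecreasing in the substrate concentration.
#'
#' @param law an [uptake_law()].
#' @param concentrations named numeric vector/list, mmol/L.
#' @return Nonnegative uptake bound, mmol/gDW/h.
#' @export
mm_bound <- function(law, concentrations) {
  conc <- function(name) {
    if (!name %in% names(concentrations)) {
      stop("concentration for species '", name, "' is missing")
    }
    max(0, as.numeric(concentrations[[name]]))
  }
  if (law$form == "custom") {
    return(max(0, law$fn(concentrations)))
  }
  s <- conc(law$species)
  v <- law$vmax * s / (law$Ks + s)
  for (nm in names(law$inhibitors)) {
    v <- v / (1 + conc(nm) / law$inhibitors[[nm]])
  }
  v
}

#' Gas-liquid mass transfer specification
#'
#' Parameters of the film model `kLa * (s_gas / K_H - s)` for a sparged or
#' surface-aerated species: the volumetric transfer coefficient `kLa`
#' (1/h), Henry's constant `K_H` (the saturation concentration scale,
#' mmol/L per unit gas-phase measure), and the gas-phase concentration.
#' Non-gas species use [null_transfer()], which contributes zero.
#'
#' @param kLa volumetric mass-transfer coefficient, 1/h (`>= 0`).
#' @param K_H Henry constant (`> 0`).
#' @param s_gas gas-phase concentration (same measure as `K_H`'s
#'   denominator).
#' @return A `gas_transfer_spec` object.
#' @export
gas_transfer_spec <- function(kLa, K_H, s_gas) {
  stopifnot(kLa >= 0, K_H > 0)
  structure(list(kLa = kLa, K_H = K_H, s_gas = s_gas, gas = TRUE),
            class = "gas_transfer_spec")
}

#' @rdname gas_transfer_spec
#' @export
null_transfer <- function() {
  structure(list(kLa = 0, K_H = 1, s_gas = 0, gas = FALSE),
            class = "gas_transfer_spec")
}

#' Mass-transfer rate into the liquid phase
#'
#' @param spec a [gas_transfer_spec()] (or [null_transfer()]).
#' @param s dissolved concentration, mmol/L.
#' @return `kLa * (s_gas / K_H - s)` for gas species, 0 otherwise
#'   (mmol/L/h).
#' @export
mass_transfer_rate <- function(spec, s) {
  if (!spec$gas) return(0)
  spec$kLa * (spec$s_gas / spec$K_H - s)
}

#' Henry's-law cap on dissolved concentration
#'
#' Returns the Henry constant, used by the simulation driver as the
#' maximum dissolved concentration of a sparged species: the driving force
#' of the mass-transfer law is capped so the dissolved phase cannot exceed
#' it. Applies only to species flagged as gases; [null_transfer()] species
#' are uncapped (`Inf`).
#'
#' @param spec a [gas_transfer_spec()].
#' @return The cap, mmol/L (`Inf` for non-gas species).
#' @export
henry_cap <- function(spec) {
  if (!spec$gas) return(Inf)
  spec$K_H
}

#' Day/night surface light model with Beer-Lambert depth averaging
#'
#' The surface photon flux follows a clipped squared-sinusoid with a
#' daylight window from `dawn` to `24 - dawn` o'clock and peak
#' `surface_peak` at noon. Self-shading in a pond of depth `pond_depth` is
#' modelled by averaging the Beer-Lambert profile over depth with
#' attenuation coefficient `K_e = Ke_intercept + Ke_slope * biomass`.
#'
#' @param surface_peak peak photon uptake capacity, mmol photons/gDW/h
#'   (default 28).
#' @param dawn,dusk clock hours of the daylight window; the squared-sine
#'   form requires `dusk = 24 - dawn` (default 5:00 and 19:00).
#' @param pond_depth pond depth `L`, m.
#' @param Ke_intercept,Ke_slope attenuation coefficient model, 1/m and
#'   1/m per gDW/L.
#' @return A `light_model` object.
#' @export
light_model <- function(surface_peak = 28, dawn = 5, dusk = 19,
                        pond_depth = 0.05,
                        Ke_intercept = 14, Ke_slope = 50) {
  stopifnot(surface_peak >= 0, dawn > 0, dawn < 12,
            pond_depth > 0, Ke_intercept > 0, Ke_slope >= 0)
  if (abs(dusk - (24 - dawn)) > 1e-9) {
    stop("the squared-sine light model requires dusk = 24 - dawn")
  }
  structure(
    list(surface_peak = surface_peak, dawn = dawn, dusk = dusk,
         pond_depth = pond_depth,
         Ke_intercept = Ke_intercept, Ke_slope = Ke_slope),
    class = "light_model"
  )
}

#' Surface light intensity
#'
#' `I0(t) = peak * (max(sin^2(2 pi t / 48), m) - m) / (1 - m)` with
#' `m = sin^2(2 pi dawn / 48)`; `t` in clock hours, reduced modulo 24.
#' Zero outside the daylight window, `peak` at noon.
#'
#' @param model a [light_model()].
#' @param t time, hours.
#' @return Photon flux, mmol photons/gDW/h (vectorized over `t`).
#' @export
surface_light <- function(model, t) {
  t <- t %% 24
  m <- sin(2 * pi * model$dawn / 48)^2
  s2 <- sin(2 * pi * t / 48)^2
  model$surface_peak * (pmax(s2, m) - m) / (1 - m)
}

#' Depth-averaged light available to cells
#'
#' Beer-Lambert averaging over the pond depth:
#' `Ia = I0 * (1 - exp(-L Ke)) / (L Ke)`, with
#' `Ke = Ke_intercept + Ke_slope * total_biomass`. For `L Ke` below 1e-10
#' the two-term series `1 - L Ke / 2` is used so the factor is continuous
#' with limit `I0` as the culture clears.
#'
#' @param model a [light_model()].
#' @param t time, hours.
#' @param total_biomass total culture biomass density, gDW/L (`>= 0`).
#' @return Average photon flux, mmol photons/gDW/h.
#' @export
attenuated_light <- function(model, t, total_biomass) {
  total_biomass <- max(0, total_biomass)
  I0 <- surface_light(model, t)
  Ke <- model$Ke_intercept + model$Ke_slope * total_biomass
  x <- model$pond_depth * Ke
  factor <- if (x < 1e-10) 1 - x / 2 else (1 - exp(-x)) / x
  I0 * factor
}
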