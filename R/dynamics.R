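#' Reactor specification for a CSTR
#'
#' Geometry and flow terms of the continuous stirred-tank reactor mass
#' balances: `ds/dt` gains `(F_in * s0 - F_out * s) / V` and biomass loses
#' `F_out * y / V` (the feed carries no biomass). A batch reactor is
#' `F_in = F_out = 0`.
#'
#' @param V culture volume, L (`> 0`).
#' @param F_in,F_out inlet and outlet flows, L/h (`>= 0`).
#' @param feed named numeric vector of feed concentrations `s0`, mmol/L
#'   (species absent from the feed default to 0; totals `C_T`/`N_T` may be
#'   included for pH runs).
#' @return A `reactor_spec` object.
#' @export
reactor_spec <- function(V, F_in = 0, F_out = 0, feed = numeric(0)) {
  stopifnot(V > 0, F_in >= 0, F_out >= 0)
  structure(list(V = V, F_in = F_in, F_out = F_out, feed = feed),
            class = "reactor_spec")
}

#' Specification of one species in a community
#'
#' Bundles everything the right-hand side needs per organism: the
#' metabolic model, the exchange map tying model reactions to
#' extracellular species, the lexicographic priority list (feasibility is
#' implicitly on top), the state-dependent uptake laws, and optionally a
#' photon-uptake binding for phototrophs.
#'
#' @param name species label.
#' @param model a `metabolic_model`.
#' @param exmap an [exchange_map()] for the model.
#' @param priorities a [priority_list()]; named levels are compiled
#'   against `model` and `exmap` here.
#' @param uptake list of [uptake_law()] objects; each law bounds the
#'   consumption direction of the exchange reaction mapped to its species.
#' @param photon optional list `list(reaction =, light =)` binding a
#'   light-capture exchange reaction to a [light_model()]: its uptake
#'   bound is the depth-averaged photon flux.
#' @return A `species_spec` object (with the feasibility problem and
#'   compiled priorities precomputed).
#' @export
species_spec <- function(name, model, exmap, priorities,
                         uptake = list(), photon = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(exmap, "exchange_map"),
            inherits(priorities, "priority_list"))
  compiled <- compile_priorities(priorities, model, exmap)
  for (law in uptake) {
    stopifnot(inherits(law, "uptake_law"))
    if (law$form != "custom" &&
        !law$species %in% exmap$entries$species) {
      stop("species '", name, "': uptake law for '", law$species,
           "' has no exchange mapping")
    }
  }
  if (!is.null(photon)) {
    ridx <- if (is.character(photon$reaction))
      match(photon$reaction, model$reaction_ids) else photon$reaction
    if (is.na(ridx)) stop("unknown photon reaction: ", photon$reaction)
    photon$reaction <- ridx
    stopifnot(inherits(photon$light, "light_model"))
  }
  structure(
    list(name = name, model = model, exmap = exmap,
         priorities = compiled,
         flp = build_feasibility(model_lp(model)),
         uptake = uptake, photon = photon),
    class = "species_spec"
  )
}

#' pH balance block specification
#'
#' Enables the carbonate/ammonia speciation DAE. The named carbon species
#' is removed from the ordinary metabolite block: its exchange and
#' gas-transfer terms drive total carbon `C_T` instead, and the dissolved
#' CO2 seen by uptake kinetics is the algebraic speciation variable.
#'
#' @param constants an [equilibrium_constants()].
#' @param carbon_species extracellular name of CO2 (default `"co2"`).
#' @return A `ph_spec` object.
#' @export
ph_spec <- function(constants = equilibrium_constants(),
                    carbon_species = "co2") {
  structure(list(constants = constants, carbon_species = carbon_species),
            class = "ph_spec")
}

#' Assemble a community simulation configuration
#'
#' Validates the cross-references between species specs, the extracellular
#' metabolite list, gas-transfer laws, clamps and the optional pH block,
#' and precomputes the state-vector layout. Errors here, not during
#' integration.
#'
#' @param species list of [species_spec()] objects.
#' @param metabolites character vector of extracellular species names
#'   carried as state (when a pH block is present, its carbon species is
#'   listed here too and is re-routed to the algebraic block).
#' @param reactor a [reactor_spec()].
#' @param gas named list of [gas_transfer_spec()] for sparged species;
#'   unnamed species get [null_transfer()].
#' @param clamp character vector of species held constant (derivative
#'   forced to zero), e.g. oxygen supplied in excess.
#' @param ph optional [ph_spec()].
#' @return A `community_config` with a `layout` describing the state
#'   vector: biomass block, metabolite block, (`C_T`, `N_T` when pH is
#'   on), the integrated penalty, and the algebraic speciation block.
#' @export
community_config <- function(species, metabolites, reactor,
                             gas = list(), clamp = character(0),
                             ph = NULL) {
  stopifnot(length(species) >= 0, inherits(reactor, "reactor_spec"))
  for (sp in species) stopifnot(inherits(sp, "species_spec"))
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("duplicate species names")
  known <- metabolites
  if (!is.null(ph)) {
    stopifnot(inherits(ph, "ph_spec"))
    if (!ph$carbon_species %in% metabolites) {
      stop("pH block: carbon species '", ph$carbon_species,
           "' not in the metabolite list")
    }
  }
  for (sp in species) {
    mapped <- sp$exmap$entries$species
    missing <- setdiff(mapped, known)
    if (length(missing)) {
      stop("species '", sp$name, "' maps extracellular species absent ",
           "from the state: ", paste(missing, collapse = ", "))
    }
    for (law in sp$uptake) {
      if (law$form != "custom" && !law$species %in% known) {
        stop("uptake law species '", law$species, "' absent from the state")
      }
    }
  }
  bad_clamp <- setdiff(clamp, metabolites)
  if (length(bad_clamp)) {
    stop("clamped species absent from the state: ",
         paste(bad_clamp, collapse = ", "))
  }
  bad_gas <- setdiff(names(gas), metabolites)
  if (length(bad_gas)) {
    stop("gas-transfer species absent from the state: ",
         paste(bad_gas, collapse = ", "))
  }

  met_state <- metabolites
  if (!is.null(ph)) met_state <- setdiff(met_state, ph$carbon_species)
  diff_names <- c(paste0("biomass_", sp_names, recycle0 = TRUE), met_state,
                  if (!is.null(ph)) c("C_T", "N_T"), "penalty")
  alg_names <- if (!is.null(ph)) .spec_algebraic else character(0)
  layout <- list(
    species = sp_names,
    metabolites = met_state,
    diff_names = diff_names,
    alg_names = alg_names,
    state_names = c(diff_names, alg_names),
    n_diff = length(diff_names),
    i_biomass = seq_along(sp_names),
    i_met = length(sp_names) + seq_along(met_state),
    i_penalty = length(sp_names) + length(met_state) +
      (if (!is.null(ph)) 2L else 0L) + 1L
  )
  if (!is.null(ph)) {
    layout$i_CT <- length(sp_names) + length(met_state) + 1L
    layout$i_NT <- layout$i_CT + 1L
    layout$i_alg <- layout$n_diff + seq_len(6L)
  }
  structure(
    list(species = species, metabolites = metabolites, reactor = reactor,
         gas = gas, clamp = clamp, ph = ph, layout = layout),
    class = "community_config"
  )
}

#' @export
print.community_config <- function(x, ...) {
  cat(sprintf("<community_config> %d species, %d extracellular species%s\n",
              length(x$species), length(x$metabolites),
              if (!is.null(x$ph)) ", pH balance on" else ""))
  invisible(x)
}

# named concentration vector visible to kinetics at a state
state_concentrations <- function(config, y) {
  lay <- config$layout
  conc <- y[lay$i_met]
  names(conc) <- lay$metabolites
  if (!is.null(config$ph)) {
    conc[config$ph$carbon_species] <- y[lay$i_alg[1L]]  # dissolved CO2
  }
  conc
}

#' State-dependent flux bounds for one species
#'
#' Starts from the model's default bounds and applies, for each uptake
#' law, a consumption bound on the mapped exchange reaction (respecting
#' the sign convention: with positive-equals-secretion the bound acts on
#' the negative flux direction), and the photon bound from the
#' depth-averaged light for phototrophs. Production directions are left
#' at model defaults.
#'
#' @param sp a [species_spec()].
#' @param concentrations named concentrations, mmol/L.
#' @param t time, hours (for the light model).
#' @param total_biomass total community biomass, gDW/L (self-shading).
#' @return list `lb`, `ub` of length `n_r`, always with `lb <= ub`.
#' @export
bounds_update <- function(sp, concentrations, t = 0, total_biomass = 0) {
  lb <- sp$model$lb_default
  ub <- sp$model$ub_default
  for (law in sp$uptake) {
    rate <- mm_bound(law, concentrations)
    row <- sp$exmap$entries[sp$exmap$entries$species == law$species, ]
    j <- row$reaction
    if (row$sign > 0) {
      lb[j] <- max(lb[j], -rate)
      if (lb[j] > ub[j]) ub[j] <- lb[j]
    } else {
      ub[j] <- min(ub[j], rate)
      if (ub[j] < lb[j]) lb[j] <- ub[j]
    }
  }
  if (!is.null(sp$photon)) {
    # the depth-averaged light is the photon uptake capacity itself
    j <- sp$photon$reaction
    ia <- attenuated_light(sp$photon$light, t, total_biomass)
    lb[j] <- -ia
    if (lb[j] > ub[j]) lb[j] <- ub[j]
  }
  list(lb = lb, ub = ub)
}

#' Split signed exchange fluxes into production and consumption rates
#'
#' @param solution a solved `lexicographic_solution`.
#' @param exmap the [exchange_map()] used for the solve.
#' @return A data frame with columns `species`, `production`,
#'   `consumption` (both `>= 0`, mmol/gDW/h, with
#'   `production * consumption = 0` per species).
#' @export
flux_sign_map <- function(solution, exmap) {
  stopifnot(inherits(solution, "lexicographic_solution"),
            solution$status == "solved")
  e <- exmap$entries
  signed <- solution$flux[e$reaction] * e$sign
  data.frame(species = e$species,
             production = pmax(signed, 0),
             consumption = pmax(-signed, 0),
             stringsAsFactors = FALSE)
}

# capped mass-transfer rate for one species
transfer_rate <- function(config, name, s) {
  spec <- config$gas[[name]]
  if (is.null(spec)) return(0)
  mt <- mass_transfer_rate(spec, s)
  if (s >= henry_cap(spec)) mt <- min(mt, 0)
  mt
}

#' Right-hand side of the extended DFBA system
#'
#' For each species: update the state-dependent bounds, solve the
#' feasibility-first lexicographic hierarchy, and read off the growth rate
#' and exchange fluxes. Then assemble the CSTR mass balances, the
#' penalty derivative (the sum of the per-species feasibility optima,
#' which is zero exactly while every LP is feasible), and, when the pH
#' block is on, the algebraic speciation residuals. LP infeasibility never
#' raises here: the slack-augmented hierarchy is solvable whenever the
#' bound box is nonempty, so the extended system is defined for all
#' simulation time.
#'
#' @param t time, hours.
#' @param y state vector in the configuration's layout.
#' @param config a [community_config()].
#' @param backend LP backend key.
#' @return A list: `dx` (derivatives for differential entries, residuals
#'   for algebraic entries), `fluxes` (per-species named signed exchange
#'   rates, positive = secretion), `growth` (per-species 1/h),
#'   `feasibility_values` (per-species, `>= 0`).
#' @export
assemble_rhs <- function(t, y, config, backend = "simplex") {
  lay <- config$layout
  reac <- config$reactor
  biomass <- pmax(y[lay$i_biomass], 0)
  conc <- state_concentrations(config, y)
  total_bio <- sum(biomass)

  n_sp <- length(config$species)
  growth <- numeric(n_sp)
  feas <- numeric(n_sp)
  fluxes <- vector("list", n_sp)
  names(fluxes) <- lay$species
  # net specific rate per extracellular species (production - consumption)
  net <- stats::setNames(numeric(length(config$metabolites)),
                         config$metabolites)
  for (k in seq_len(n_sp)) {
    sp <- config$species[[k]]
    bnd <- bounds_update(sp, conc, t = t, total_biomass = total_bio)
    if (any(bnd$lb > bnd$ub)) {
      j <- which(bnd$lb > bnd$ub)[1L]
      stop("species '", sp$name, "': lb > ub for reaction '",
           sp$model$reaction_ids[j], "' (malformed kinetic law)")
    }
    sol <- lexicographic_solve(sp$flp, sp$priorities,
                               lb = bnd$lb, ub = bnd$ub, backend = backend)
    growth[k] <- sol$flux[sp$model$biomass_reaction]
    feas[k] <- sol$feasibility_value
    e <- sp$exmap$entries
    signed <- sol$flux[e$reaction] * e$sign
    names(signed) <- e$species
    fluxes[[k]] <- signed
    net[e$species] <- net[e$species] + signed * biomass[k]
  }

  dx <- numeric(length(lay$state_names))
  names(dx) <- lay$state_names
  # biomass: growth minus outflow dilution
  dx[lay$i_biomass] <- growth * y[lay$i_biomass] -
    reac$F_out * y[lay$i_biomass] / reac$V
  # ordinary metabolites
  feed_of <- function(nm) {
    if (nm %in% names(reac$feed)) reac$feed[[nm]] else 0
  }
  for (i in seq_along(lay$metabolites)) {
    nm <- lay$metabolites[i]
    s <- y[lay$i_met[i]]
    d <- (reac$F_in * feed_of(nm) - reac$F_out * s) / reac$V +
      transfer_rate(config, nm, s) + net[[nm]]
    if (nm %in% config$clamp) d <- 0
    dx[lay$i_met[i]] <- d
  }
  # penalty: integral of the total distance from feasibility
  dx[lay$i_penalty] <- sum(feas)
  if (!is.null(config$ph)) {
    cs <- config$ph$carbon_species
    co2 <- y[lay$i_alg[1L]]
    dCT <- (reac$F_in * feed_of("C_T") - reac$F_out * y[lay$i_CT]) / reac$V +
      transfer_rate(config, cs, co2) + net[[cs]]
    dNT <- (reac$F_in * feed_of("N_T") - reac$F_out * y[lay$i_NT]) / reac$V
    if (cs %in% config$clamp) dCT <- 0
    dx[lay$i_CT] <- dCT
    dx[lay$i_NT] <- dNT
    st <- c(C_T = unname(y[lay$i_CT]), N_T = unname(y[lay$i_NT]),
            stats::setNames(unname(y[lay$i_alg]), .spec_algebraic))
    dx[lay$i_alg] <- equilibrium_residuals(st, config$ph$constants)
  }
  list(dx = dx, fluxes = fluxes, growth = growth,
       feasibility_values = feas)
}
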