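# Synthetic networks and random LPs: every module is testable without
# downloading genome-scale reconstructions.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Fixed toy growth network
#'
#' A 4-metabolite, 6-reaction network standing in for a genome-scale
#' model: glucose uptake (`EX_glc`, bounded), glycolysis lumped into one
#' step producing precursor and energy carrier (`R_glyc`), a biomass
#' reaction consuming 10 precursor + 5 energy and releasing 2 CO2
#' (`R_biomass`), ATP maintenance (`R_atpm`, lower-bounded by
#' `maintenance`), CO2 secretion (`EX_co2`) and overflow secretion of the
#' energy carrier (`EX_eth`). Growth is limited by uptake with yield 0.1:
#' the lexicographic biomass optimum is `mu* = 0.1 * uptake_bound`
#' whenever `uptake_bound >= 2 * maintenance`; below that threshold the
#' flux balance LP is infeasible, which makes the network a convenient
#' stand-in for substrate-exhaustion infeasibility. At the biomass
#' optimum the overflow flux `EX_eth` is nonunique (any split of the
#' surplus energy `uptake/2` with `R_atpm`) until a lower-priority
#' objective pins it.
#'
#' @param uptake_bound maximal glucose uptake, mmol/gDW/h (default 10).
#' @param maintenance ATP maintenance demand, mmol/gDW/h (default 0).
#' @return A list with elements `model` (a `metabolic_model`) and `exmap`
#'   (mapping `"glc"`, `"co2"`, `"eth"`; positive flux = secretion).
#' @export
make_growth_toy <- function(uptake_bound = 10, maintenance = 0) {
  mets <- c("glc_c", "prec_c", "nrg_c", "co2_c")
  rxns <- c("EX_glc", "R_glyc", "R_biomass", "R_atpm", "EX_co2", "EX_eth")
  S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
  S["glc_c", "EX_glc"] <- -1
  S["glc_c", "R_glyc"] <- -1
  S["prec_c", "R_glyc"] <- 1
  S["nrg_c", "R_glyc"] <- 1
  S["prec_c", "R_biomass"] <- -10
  S["nrg_c", "R_biomass"] <- -5
  S["co2_c", "R_biomass"] <- 2
  S["nrg_c", "R_atpm"] <- -1
  S["co2_c", "EX_co2"] <- -1
  S["nrg_c", "EX_eth"] <- -1
  lb <- c(-uptake_bound, 0, 0, maintenance, 0, 0)
  ub <- c(0, Inf, Inf, Inf, Inf, Inf)
  model <- metabolic_model(
    model_id = "growth_toy",
    metabolite_ids = mets, reaction_ids = rxns, S = S,
    lb_default = lb, ub_default = ub,
    biomass_reaction = "R_biomass"
  )
  exmap <- exchange_map(model,
                        species = c("glc", "co2", "eth"),
                        reactions = c("EX_glc", "EX_co2", "EX_eth"),
                        sign = 1)
  list(model = model, exmap = exmap)
}

#' Dual-substrate toy network
#'
#' Extends the growth toy with a second substrate (xylose) entering the
#' same lumped pathway at a lower energy yield, for diauxic-style batch
#' protocols: glucose and xylose uptakes are bounded separately and a
#' glucose inhibition term on xylose uptake reproduces sequential
#' consumption.
#'
#' @inheritParams make_growth_toy
#' @param xyl_uptake_bound maximal xylose uptake (default 10).
#' @return list(`model`, `exmap`) with species `"glc"`, `"xyl"`,
#'   `"co2"`, `"eth"`.
#' @export
make_dual_substrate_toy <- function(uptake_bound = 10,
                                    xyl_uptake_bound = 10,
                                    maintenance = 0) {
  mets <- c("glc_c", "xyl_c", "prec_c", "nrg_c", "co2_c")
  rxns <- c("EX_glc", "EX_xyl", "R_glyc", "R_xylp",
            "R_biomass", "R_atpm", "EX_co2", "EX_eth")
  S <- matrix(0, 5, 8, dimnames = list(mets, rxns))
  S["glc_c", "EX_glc"] <- -1
  S["xyl_c", "EX_xyl"] <- -1
  S["glc_c", "R_glyc"] <- -1
  S["prec_c", "R_glyc"] <- 1
  S["nrg_c", "R_glyc"] <- 1
  S["xyl_c", "R_xylp"] <- -1
  S["prec_c", "R_xylp"] <- 0.8
  S["nrg_c", "R_xylp"] <- 0.8
  S["prec_c", "R_biomass"] <- -10
  S["nrg_c", "R_biomass"] <- -5
  S["co2_c", "R_biomass"] <- 2
  S["nrg_c", "R_atpm"] <- -1
  S["co2_c", "EX_co2"] <- -1
  S["nrg_c", "EX_eth"] <- -1
  lb <- c(-uptake_bound, -xyl_uptake_bound, 0, 0, 0, maintenance, 0, 0)
  ub <- c(0, 0, Inf, Inf, Inf, Inf, Inf, Inf)
  model <- metabolic_model(
    model_id = "dual_substrate_toy",
    metabolite_ids = mets, reaction_ids = rxns, S = S,
    lb_default = lb, ub_default = ub,
    biomass_reaction = "R_biomass"
  )
  exmap <- exchange_map(model,
                        species = c("glc", "xyl", "co2", "eth"),
                        reactions = c("EX_glc", "EX_xyl", "EX_co2", "EX_eth"),
                        sign = 1)
  list(model = model, exmap = exmap)
}

#' Random bounded LP with controlled feasibility
#'
#' Generates small integer-coefficient LPs (`S v = 0`, box bounds) for
#' oracle testing of the feasibility construction. Feasible instances
#' plant an interior point: an integer vector `w` is drawn and every row
#' of `S` is a random integer combination of elementary vectors orthogonal
#' to `w`, so `S w = 0` with `w` strictly inside the box
#' `[w - margin, w + margin]`. Infeasible instances plant a certificate
#' row with all-positive coefficients over a box with `lb >= 1`, so the
#' row's minimum over the box is strictly positive and `S v = 0` is
#' unattainable. Integer coefficients in `[-3, 3]` keep brute-force
#' verification exact.
#'
#' @param n_q,n_r metabolite and reaction counts (`n_q <= n_r <= 10`).
#' @param feasible logical: plant a feasible point or a certificate.
#' @param seed integer seed (mandatory; the global RNG state is
#'   preserved).
#' @return A [bounded_lp()] (zero cost vector).
#' @export
random_bounded_lp <- function(n_q, n_r, feasible, seed) {
  stopifnot(n_q <= n_r, n_r <= 10)
  with_seed(seed, {
    if (feasible) {
      w <- sample(c(-2L, -1L, 1L, 2L), n_r, replace = TRUE)
      S <- matrix(0, n_q, n_r)
      for (i in seq_len(n_q)) {
        row <- numeric(n_r)
        for (rep in seq_len(n_r)) {
          ij <- sample.int(n_r, 2L)
          mult <- sample(-3:3, 1L)
          # elementary vector orthogonal to w
          row[ij[1L]] <- row[ij[1L]] + mult * w[ij[2L]]
          row[ij[2L]] <- row[ij[2L]] - mult * w[ij[1L]]
        }
        S[i, ] <- row
      }
      margin <- sample(1:2, n_r, replace = TRUE)
      bounded_lp(S, w - margin, w + margin)
    } else {
      S <- matrix(sample(-3:3, n_q * n_r, replace = TRUE), n_q, n_r)
      cert <- sample(1:3, n_r, replace = TRUE)
      S[n_q, ] <- cert
      lb <- sample(1:2, n_r, replace = TRUE)
      ub <- lb + sample(1:2, n_r, replace = TRUE)
      bounded_lp(S, lb, ub)
    }
  })
}

#' Replicate a monoculture into n identical community members
#'
#' Splits the biomass of a single-species configuration evenly among
#' `n_copies` independent copies of the species model sharing the same
#' environment. By symmetry the replica trajectories coincide and their
#' sum equals the single-model run, while the LP work per right-hand-side
#' evaluation grows linearly in `n_copies` — the construction used to
#' demonstrate linear scaling with the number of models.
#'
#' @param config a single-species [community_config()].
#' @param x0 named initial state for `config` (see
#'   [simulate_community()]).
#' @param n_copies number of replicas (`>= 1`).
#' @return list(`config`, `x0`) for the replicated community.
#' @export
replicate_community <- function(config, x0, n_copies) {
  stopifnot(inherits(config, "community_config"),
            length(config$species) == 1L, n_copies >= 1L)
  base <- config$species[[1L]]
  copies <- lapply(seq_len(n_copies), function(i) {
    sp <- base
    sp$name <- if (n_copies == 1L) base$name else
      sprintf("%s_%d", base$name, i)
    sp
  })
  new_config <- community_config(
    species = copies, metabolites = config$metabolites,
    reactor = config$reactor, gas = config$gas,
    clamp = config$clamp, ph = config$ph
  )
  old_b <- paste0("biomass_", base$name)
  y_b <- x0[[old_b]] / n_copies
  rest <- x0[setdiff(names(x0), old_b)]
  bio <- stats::setNames(rep(y_b, n_copies),
                         paste0("biomass_", vapply(copies, `[[`, "", "name")))
  list(config = new_config, x0 = c(bio, rest))
}
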