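#' Construct a constraint-based metabolic model
#'
#' In-memory representation of a stoichiometric model: identities, the
#' stoichiometry matrix, default flux bounds and the designated biomass and
#' exchange reactions. Flux units are mmol/gDW/h (biomass 1/h). Bound
#' magnitudes at or above `inf_cap` are treated as unbounded: COBRA files
#' commonly use +/-1000 or +/-1e6 as infinity sentinels.
#'
#' @param model_id character scalar.
#' @param metabolite_ids,reaction_ids character vectors (unique ids, file
#'   order preserved).
#' @param S numeric matrix, metabolites x reactions.
#' @param lb_default,ub_default numeric bound vectors, length `ncol(S)`.
#' @param biomass_reaction index (or id) of the biomass reaction.
#' @param exchange_reactions integer indices of exchange reactions; when
#'   `NULL` they are auto-detected as columns with a single nonzero entry.
#' @param inf_cap bound magnitude mapped to infinity. Default `1e6`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(model_id, metabolite_ids, reaction_ids, S,
                            lb_default, ub_default,
                            biomass_reaction = NULL,
                            exchange_reactions = NULL,
                            inf_cap = 1e6) {
  S <- as.matrix(S)
  if (is.character(biomass_reaction)) {
    biomass_reaction <- match(biomass_reaction, reaction_ids)
  }
  lb <- as.numeric(lb_default)
  ub <- as.numeric(ub_default)
  lb[lb <= -inf_cap] <- -Inf
  ub[ub >= inf_cap] <- Inf
  if (is.null(exchange_reactions)) {
    exchange_reactions <- which(colSums(S != 0) == 1L)
  }
  m <- structure(
    list(model_id = model_id,
         metabolite_ids = as.character(metabolite_ids),
         reaction_ids = as.character(reaction_ids),
         S = S, lb_default = lb, ub_default = ub,
         biomass_reaction = biomass_reaction,
         exchange_reactions = as.integer(exchange_reactions)),
    class = "metabolic_model"
  )
  diags <- validate_model(m)
  errs <- diags[vapply(diags, function(d) d$severity == "error", logical(1))]
  if (length(errs)) {
    stop("invalid metabolic model:\n  ",
         paste(vapply(errs, `[[`, "", "message"), collapse = "\n  "))
  }
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites x %d reactions, %d exchanges\n",
              x$model_id, nrow(x$S), ncol(x$S),
              length(x$exchange_reactions)))
  invisible(x)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants (consistent dimensions, `lb <= ub`,
#' unique reaction ids, valid biomass/exchange indices, no all-zero
#' reaction columns) and returns one diagnostic per violation rather than
#' raising, so callers can triage.
#'
#' @param model a `metabolic_model` (or a bare list with its fields).
#' @return A list of diagnostics, each `list(severity, message)`;
#'   empty iff all invariants hold (warnings excepted: an all-zero column
#'   yields a `"warning"` diagnostic).
#' @export
validate_model <- function(model) {
  d <- list()
  add <- function(severity, message) {
    d[[length(d) + 1L]] <<- list(severity = severity, message = message)
  }
  S <- model$S
  n_q <- nrow(S)
  n_r <- ncol(S)
  if (length(model$metabolite_ids) != n_q) {
    add("error", "metabolite_ids length does not match nrow(S)")
  }
  if (length(model$reaction_ids) != n_r) {
    add("error", "reaction_ids length does not match ncol(S)")
  }
  if (length(model$lb_default) != n_r || length(model$ub_default) != n_r) {
    add("error", "bound vectors do not match ncol(S)")
  } else {
    bad <- which(model$lb_default > model$ub_default)
    for (j in bad) {
      add("error", sprintf("lb > ub for reaction '%s'",
                           model$reaction_ids[j]))
    }
  }
  dup <- unique(model$reaction_ids[duplicated(model$reaction_ids)])
  for (id in dup) add("error", sprintf("duplicated reaction id '%s'", id))
  if (is.null(model$biomass_reaction) || is.na(model$biomass_reaction)) {
    add("error", paste("no biomass reaction designated; set one via the",
                       "'biomass_reaction' argument or an objective",
                       "coefficient in the model file"))
  } else if (model$biomass_reaction < 1L || model$biomass_reaction > n_r) {
    add("error", "biomass_reaction index out of range")
  }
  bad_ex <- setdiff(model$exchange_reactions, seq_len(n_r))
  if (length(bad_ex)) add("error", "exchange reaction index out of range")
  zero_cols <- which(colSums(S != 0) == 0L)
  for (j in zero_cols) {
    add("warning", sprintf("reaction '%s' has an all-zero column (affects no metabolite)",
                           model$reaction_ids[j]))
  }
  d
}

#' Map extracellular species to exchange reactions
#'
#' Associates each extracellular species name with one exchange reaction of
#' a model and a sign convention. `sign = +1` (the default and the SBML
#' exchange convention) means a positive model flux secretes the species
#' into the medium; consumption is then the negative flux direction.
#'
#' @param model a `metabolic_model`.
#' @param species character vector of extracellular species names.
#' @param reactions reaction ids or indices, one per species.
#' @param sign numeric vector of +1/-1 convention flags (recycled).
#' @return An object of class `exchange_map` with a data frame `entries`
#'   (`species`, `reaction`, `sign`).
#' @export
exchange_map <- function(model, species, reactions, sign = 1) {
  if (is.character(reactions)) {
    idx <- match(reactions, model$reaction_ids)
    if (anyNA(idx)) {
      stop("unknown reaction id(s): ",
           paste(reactions[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(reactions)
  }
  stopifnot(length(species) == length(idx))
  if (anyDuplicated(species)) {
    stop("species mapped twice: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  bad <- setdiff(idx, model$exchange_reactions)
  if (length(bad)) {
    stop("reaction(s) not in the model's exchange set: ",
         paste(model$reaction_ids[bad], collapse = ", "))
  }
  structure(
    list(entries = data.frame(species = as.character(species),
                              reaction = idx,
                              sign = rep_len(as.numeric(sign), length(idx)),
                              stringsAsFactors = FALSE)),
    class = "exchange_map"
  )
}

#' Read a COBRA-dialect JSON model
#'
#' Parses the COBRA toolbox JSON serialization: a `metabolites` array of
#' objects with `id`, and a `reactions` array with `id`, a `metabolites`
#' coefficient map, `lower_bound`/`upper_bound` and optionally
#' `objective_coefficient`. A nonzero objective coefficient designates the
#' biomass reaction; otherwise pass `biomass` explicitly.
#'
#' @param path file path.
#' @param biomass optional reaction id or index overriding the objective
#'   annotation.
#' @param inf_cap bound magnitude treated as infinite (default `1e6`).
#' @return A validated `metabolic_model`.
#' @export
read_cobra_json <- function(path, biomass = NULL, inf_cap = 1e6) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed COBRA JSON in '", path, "': ",
                             conditionMessage(e))
  )
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("malformed COBRA JSON: missing '", field, "' array")
    }
  }
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed COBRA JSON: metabolite without 'id'")
    as.character(m$id)
  }, character(1))
  n_q <- length(met_ids)
  n_r <- length(doc$reactions)
  S <- matrix(0, n_q, n_r, dimnames = list(met_ids, NULL))
  rxn_ids <- character(n_r)
  lb <- numeric(n_r)
  ub <- numeric(n_r)
  objc <- numeric(n_r)
  for (j in seq_len(n_r)) {
    r <- doc$reactions[[j]]
    if (is.null(r$id)) stop("malformed COBRA JSON: reaction without 'id'")
    rxn_ids[j] <- as.character(r$id)
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      stop("reaction '", rxn_ids[j], "' is missing lower_bound/upper_bound")
    }
    lb[j] <- as.numeric(r$lower_bound)
    ub[j] <- as.numeric(r$upper_bound)
    objc[j] <- if (is.null(r$objective_coefficient)) 0 else
      as.numeric(r$objective_coefficient)
    for (met in names(r$metabolites)) {
      i <- match(met, met_ids)
      if (is.na(i)) {
        stop("reaction '", rxn_ids[j], "' references unknown metabolite '",
             met, "'")
      }
      S[i, j] <- as.numeric(r$metabolites[[met]])
    }
  }
  dimnames(S) <- list(met_ids, rxn_ids)
  if (is.null(biomass)) {
    hit <- which(objc != 0)
    if (length(hit) == 1L) biomass <- hit
    if (length(hit) > 1L) biomass <- hit[1L]
  }
  metabolic_model(
    model_id = if (!is.null(doc$id)) as.character(doc$id) else
      tools::file_path_sans_ext(basename(path)),
    metabolite_ids = met_ids, reaction_ids = rxn_ids, S = S,
    lb_default = lb, ub_default = ub,
    biomass_reaction = biomass, inf_cap = inf_cap
  )
}

#' Write a model as COBRA-dialect JSON
#'
#' Inverse of [read_cobra_json()]: `read_cobra_json(write_cobra_json(m))`
#' reproduces ids, stoichiometry and bounds exactly. Infinite bounds are
#' written as +/-`inf_cap`.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param inf_cap sentinel magnitude for infinite bounds.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(model, path, inf_cap = 1e6) {
  lb <- model$lb_default
  ub <- model$ub_default
  lb[!is.finite(lb)] <- -inf_cap
  ub[!is.finite(ub)] <- inf_cap
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S[, j] != 0)
    mets <- as.list(model$S[nz, j])
    names(mets) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j],
         metabolites = mets,
         lower_bound = lb[j], upper_bound = ub[j],
         objective_coefficient =
           if (identical(j, as.integer(model$biomass_reaction))) 1 else 0)
  })
  doc <- list(
    id = model$model_id,
    metabolites = lapply(model$metabolite_ids, function(id) list(id = id)),
    reactions = rxns
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an SBML Level 3 model with fbc flux bounds
#'
#' Parses the subset of SBML Level 3 (with the flux-balance-constraints
#' package) needed for constraint-based simulation: species, reactions with
#' reactant/product stoichiometries, flux bounds referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters, and the active
#' fbc objective (which designates the biomass reaction).
#'
#' @param path file path to an (uncompressed) SBML document.
#' @param biomass optional reaction id or index overriding the fbc
#'   objective.
#' @param inf_cap bound magnitude treated as infinite.
#' @return A validated `metabolic_model`.
#' @export
read_sbml <- function(path, biomass = NULL, inf_cap = 1e6) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  level <- xml2::xml_attr(doc, "level")
  if (!is.na(level) && as.integer(level) < 3L) {
    stop("unsupported SBML level ", level,
         ": this reader supports Level 3 with fbc flux bounds")
  }
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(model_node) || inherits(model_node, "xml_missing")) {
    stop("malformed SBML: no <model> element")
  }
  # global parameters (bound values)
  pars <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  met_ids <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  keep <- !boundary     # boundary species are outside the mass balance
  met_ids <- met_ids[keep]
  rx <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("malformed SBML: no reactions")
  n_q <- length(met_ids)
  n_r <- length(rx)
  S <- matrix(0, n_q, n_r, dimnames = list(met_ids, NULL))
  rxn_ids <- xml2::xml_attr(rx, "id")
  lb <- rep(NA_real_, n_r)
  ub <- rep(NA_real_, n_r)
  for (j in seq_len(n_r)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                      side))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        i <- match(met, met_ids)
        if (!is.na(i)) S[i, j] <- S[i, j] + sgn * st
      }
    }
    lbid <- xml2::xml_attr(node, "lowerFluxBound")
    ubid <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(par_val)) lb[j] <- par_val[[lbid]]
    if (!is.na(ubid) && ubid %in% names(par_val)) ub[j] <- par_val[[ubid]]
  }
  if (anyNA(lb) || anyNA(ub)) {
    bad <- rxn_ids[is.na(lb) | is.na(ub)]
    stop("SBML document lacks flux bounds for reaction(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         " (fbc lowerFluxBound/upperFluxBound parameters required)")
  }
  dimnames(S) <- list(met_ids, rxn_ids)
  if (is.null(biomass)) {
    obj_ref <- xml2::xml_find_first(
      model_node, ".//*[local-name()='fluxObjective']")
    if (!inherits(obj_ref, "xml_missing")) {
      rid <- xml2::xml_attr(obj_ref, "reaction")
      biomass <- match(rid, rxn_ids)
    }
  }
  mid <- xml2::xml_attr(model_node, "id")
  metabolic_model(
    model_id = if (is.na(mid)) tools::file_path_sans_ext(basename(path)) else mid,
    metabolite_ids = met_ids, reaction_ids = rxn_ids, S = S,
    lb_default = lb, ub_default = ub,
    biomass_reaction = biomass, inf_cap = inf_cap
  )
}

#' Write a model as SBML Level 3 with fbc flux bounds
#'
#' Minimal SBML Level 3 serialization (species, reactions, parameter-
#' referenced flux bounds, fbc objective on the biomass reaction) suitable
#' for interchange with [read_sbml()].
#'
#' @inheritParams write_cobra_json
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, inf_cap = 1e6) {
  lb <- model$lb_default
  ub <- model$ub_default
  lb[!is.finite(lb)] <- -inf_cap
  ub[!is.finite(ub)] <- inf_cap
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$model_id)),
    '    <listOfParameters>'
  )
  for (j in seq_along(model$reaction_ids)) {
    out <- c(out,
      sprintf('      <parameter id="lb_%d" value="%.17g" constant="true"/>', j, lb[j]),
      sprintf('      <parameter id="ub_%d" value="%.17g" constant="true"/>', j, ub[j]))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfSpecies>')
  for (m in model$metabolite_ids) {
    out <- c(out, sprintf(
      '      <species id="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m)))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfReactions>')
  for (j in seq_along(model$reaction_ids)) {
    out <- c(out, sprintf(
      '      <reaction id="%s" reversible="true" fast="false" fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">',
      esc(model$reaction_ids[j]), j, j))
    col <- model$S[, j]
    rs <- which(col < 0)
    ps <- which(col > 0)
    if (length(rs)) {
      out <- c(out, '        <listOfReactants>',
               sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                       esc(model$metabolite_ids[rs]), -col[rs]),
               '        </listOfReactants>')
    }
    if (length(ps)) {
      out <- c(out, '        <listOfProducts>',
               sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                       esc(model$metabolite_ids[ps]), col[ps]),
               '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (!is.null(model$biomass_reaction)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              esc(model$reaction_ids[model$biomass_reaction])),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

#' Flux balance LP of a model at given bounds
#'
#' Convenience constructor for the growth LP `max c_biomass' v` over
#' `S v = 0`, `lb <= v <= ub`.
#'
#' @param model a `metabolic_model`.
#' @param lb,ub optional bound overrides (default: the model defaults).
#' @return A [bounded_lp()].
#' @export
model_lp <- function(model, lb = NULL, ub = NULL) {
  cc <- rep(0, ncol(model$S))
  cc[model$biomass_reaction] <- 1
  bounded_lp(model$S,
             if (is.null(lb)) model$lb_default else lb,
             if (is.null(ub)) model$ub_default else ub,
             c = cc, sense = "max")
}
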