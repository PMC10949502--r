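#' Metabolic network data model
#'
#' A `metabolic_model` is a plain-R representation of a stoichiometric
#' network: metabolites (optionally with elemental formulas), bounded
#' reactions, and an objective. It is the substrate for [fba()], [fva()],
#' [geometric_fba()] and the strain-design analytics.
#'
#' @name metabolic_model
NULL

#' Create a metabolite
#'
#' @param id short unique token, e.g. `"pyr"`.
#' @param name free-text name.
#' @param compartment compartment token; the core model uses a single
#'   cytosolic compartment `"c"` plus boundary `"e"`.
#' @param formula named numeric vector of elemental counts, e.g.
#'   `c(C = 3)` or `c(C = 5, N = 1)`. `NULL` for lumped pseudo-species.
#'   The bundled models track carbon and nitrogen; carrier moieties that
#'   are netted out of every reaction (CoA, NAD(P), adenosine phosphates,
#'   menaquinone) carry zero counts.
#' @return a list of class `"metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("metabolite id must be a non-empty string")
  if (!is.null(formula)) {
    formula <- unlist(formula)
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("formula must be a named vector of element counts (", id, ")")
    if (any(formula < 0) || any(formula != round(formula)))
      stop("formula counts must be non-negative integers (", id, ")")
    storage.mode(formula) <- "double"
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula),
            class = "metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed, positive =
#' produced. Flux bounds are in mmol/gCDW/h. Exchange reactions touch
#' exactly one metabolite and connect it to the environment; pseudo
#' reactions (biomass, ATP maintenance) are exempt from elemental balance.
#'
#' @param id short unique token, e.g. `"PDH"`.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds; `lower_bound <= upper_bound`.
#' @param name free-text name.
#' @param gene optional gene tag, e.g. `"aceE"` (annotation only; no
#'   gene-protein-reaction logic is evaluated).
#' @param subsystem optional subsystem token, e.g. `"TCA"`.
#' @param is_exchange flag marking an exchange reaction.
#' @param is_pseudo flag marking a lumped pseudo reaction.
#' @return a list of class `"reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id, gene = NA_character_,
                     subsystem = NA_character_, is_exchange = FALSE,
                     is_pseudo = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a non-empty string")
  stoichiometry <- unlist(stoichiometry)
  if (length(stoichiometry) == 0L)
    stop("reaction ", id, " has empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry of ", id, " must be named by metabolite id")
  if (anyDuplicated(names(stoichiometry)))
    stop("duplicate metabolite in stoichiometry of ", id)
  if (!(lower_bound <= upper_bound))
    stop("reaction ", id, ": lower_bound > upper_bound")
  if (is_exchange && length(stoichiometry) != 1L)
    stop("exchange reaction ", id, " must touch exactly one metabolite")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene = if (is.null(gene) || is.na(gene[1])) NA_character_
                        else as.character(gene),
                 subsystem = if (is.null(subsystem) || is.na(subsystem[1]))
                   NA_character_ else as.character(subsystem),
                 is_exchange = isTRUE(is_exchange),
                 is_pseudo = isTRUE(is_pseudo)),
            class = "reaction")
}

#' Assemble and validate a metabolic model
#'
#' @param id model identifier.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective list with `reaction` (a reaction id) and `sense`
#'   (`"max"` or `"min"`); or just a reaction id (sense defaults to max).
#' @param annotations free-form named list.
#' @return a validated object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            annotations = list()) {
  if (is.character(objective))
    objective <- list(reaction = objective, sense = "max")
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      objective = objective,
                      annotations = annotations),
                 class = "metabolic_model")
  names(m$metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(m$reactions) <- vapply(reactions, `[[`, "", "id")
  validate_model(m)
  m
}

#' Structural validation of a metabolic model
#'
#' Checks id uniqueness, bound ordering, resolvable stoichiometry, the
#' exchange-reaction contract and the objective reference. Elemental
#' balance is checked separately by [check_mass_balance()].
#'
#' @param model a `metabolic_model`.
#' @return invisibly `TRUE`; otherwise an error describing the defect.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- vapply(model$metabolites, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(mids))
    stop("duplicate metabolite id: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), mids)
    if (length(unknown))
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (r$lower_bound > r$upper_bound)
      stop("reaction ", r$id, ": lower_bound > upper_bound")
    if (r$is_exchange && length(r$stoichiometry) != 1L)
      stop("exchange reaction ", r$id, " must touch exactly one metabolite")
  }
  if (!model$objective$reaction %in% rids)
    stop("objective reaction ", model$objective$reaction,
         " not present in model")
  if (!model$objective$sense %in% c("max", "min"))
    stop("objective sense must be max or min")
  invisible(TRUE)
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S, metabolites in rows, reactions in
#'   columns, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Elemental balance check
#'
#' Verifies, per element, that every internal reaction conserves mass.
#' Pseudo reactions (biomass, maintenance) and exchange reactions are
#' skipped; reactions touching a metabolite without a formula are reported
#' as unchecked rather than failed.
#'
#' @param model a `metabolic_model`.
#' @return data frame with columns `reaction_id`, `element`, `imbalance`
#'   (net production of the element, should be 0); zero rows when the model
#'   balances. The ids of unchecked reactions are attached as attribute
#'   `"unchecked"`.
#' @export
check_mass_balance <- function(model) {
  out <- data.frame(reaction_id = character(), element = character(),
                    imbalance = numeric(), stringsAsFactors = FALSE)
  unchecked <- character()
  for (r in model$reactions) {
    if (r$is_pseudo || r$is_exchange) next
    mets <- model$metabolites[names(r$stoichiometry)]
    if (any(vapply(mets, function(m) is.null(m$formula), logical(1)))) {
      unchecked <- c(unchecked, r$id)
      next
    }
    elements <- unique(unlist(lapply(mets, function(m) names(m$formula))))
    for (el in elements) {
      counts <- vapply(mets, function(m) {
        if (el %in% names(m$formula)) m$formula[[el]] else 0
      }, numeric(1))
      imb <- sum(r$stoichiometry * counts)
      if (abs(imb) > 1e-9)
        out <- rbind(out, data.frame(reaction_id = r$id, element = el,
                                     imbalance = imb,
                                     stringsAsFactors = FALSE))
    }
  }
  attr(out, "unchecked") <- unchecked
  out
}

#' Knock out reactions
#'
#' Returns a copy of the model with both flux bounds of the named
#' reactions set to zero, emulating a gene deletion. The input model is
#' unmodified; the operation is idempotent and commutes over disjoint id
#' sets.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids.
#' @return the modified model.
#' @export
knock_out <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, names(model$reactions))
  if (length(unknown))
    stop("knock_out: unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  for (id in reaction_ids) {
    model$reactions[[id]]$lower_bound <- 0
    model$reactions[[id]]$upper_bound <- 0
  }
  model
}

#' Set flux bounds of one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param lower_bound,upper_bound new bounds; `NULL` leaves a bound as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lower_bound = NULL,
                       upper_bound = NULL) {
  if (!reaction_id %in% names(model$reactions))
    stop("set_bounds: unknown reaction id: ", reaction_id)
  r <- model$reactions[[reaction_id]]
  if (!is.null(lower_bound)) r$lower_bound <- as.numeric(lower_bound)
  if (!is.null(upper_bound)) r$upper_bound <- as.numeric(upper_bound)
  if (r$lower_bound > r$upper_bound)
    stop("set_bounds would leave ", reaction_id, " with lower > upper bound")
  model$reactions[[reaction_id]] <- r
  model
}

#' Simulation configuration
#'
#' Bundles the solver-facing knobs of the flux workflows: the substrate
#' cap, the biomass fraction of the production constraint, LP and
#' classification tolerances, and the attenuation-sweep fractions.
#'
#' @param substrate_exchange_id exchange reaction id of the carbon
#'   substrate (default the core model's glucose exchange).
#' @param substrate_uptake_max maximal substrate uptake, mmol/gCDW/h
#'   (default 4.67). Imposed as `lower_bound = -substrate_uptake_max` on
#'   the substrate exchange (uptake is negative flux).
#' @param biomass_reaction_id id of the biomass pseudo reaction.
#' @param biomass_fraction fraction f in `[0,1]` of the maximal biomass
#'   flux imposed as a lower bound during production simulation
#'   (default 0.2).
#' @param lp_tolerance LP feasibility/optimality tolerance (default 1e-9).
#' @param classification_tolerance tolerance epsilon used by the
#'   essentiality classifier and regulation recommender (default 1e-6).
#' @param sweep_fractions strictly descending fractions in (0,1] for
#'   [sweep_relative_flux()] (default 1.0 down to 0.1 by 0.1).
#' @param max_iter geometric-FBA iteration cap (default 30).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(substrate_exchange_id = "EX_glc",
                       substrate_uptake_max = 4.67,
                       biomass_reaction_id = "BIOMASS",
                       biomass_fraction = 0.2,
                       lp_tolerance = 1e-9,
                       classification_tolerance = 1e-6,
                       sweep_fractions = seq(1.0, 0.1, by = -0.1),
                       max_iter = 30L) {
  if (substrate_uptake_max <= 0) stop("substrate_uptake_max must be positive")
  if (biomass_fraction < 0 || biomass_fraction > 1)
    stop("biomass_fraction must lie in [0,1]")
  if (lp_tolerance <= 0 || classification_tolerance <= 0)
    stop("tolerances must be positive")
  if (any(sweep_fractions <= 0) || any(sweep_fractions > 1))
    stop("sweep_fractions must lie in (0,1]")
  if (any(diff(sweep_fractions) >= 0))
    stop("sweep_fractions must be strictly descending")
  structure(list(substrate_exchange_id = substrate_exchange_id,
                 substrate_uptake_max = substrate_uptake_max,
                 biomass_reaction_id = biomass_reaction_id,
                 biomass_fraction = biomass_fraction,
                 lp_tolerance = lp_tolerance,
                 classification_tolerance = classification_tolerance,
                 sweep_fractions = sweep_fractions,
                 max_iter = as.integer(max_iter)),
            class = "sim_config")
}

#' @export
print.metabolic_model <- function(x, ...) {
  nr <- length(x$reactions)
  nm <- length(x$metabolites)
  nex <- sum(vapply(x$reactions, `[[`, logical(1), "is_exchange"))
  nps <- sum(vapply(x$reactions, `[[`, logical(1), "is_pseudo"))
  cat("Metabolic model '", x$id, "': ", nm, " metabolites, ", nr,
      " reactions (", nex, " exchanges, ", nps, " pseudo)\n", sep = "")
  cat("Objective: ", x$objective$sense, " ", x$objective$reaction, "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  sub <- vapply(object$reactions, function(r)
    if (is.na(r$subsystem)) "(none)" else r$subsystem, "")
  print(object)
  cat("Reactions by subsystem:\n")
  print(sort(table(sub), decreasing = TRUE))
  imb <- check_mass_balance(object)
  cat("Elemental imbalances: ", nrow(imb), "; unchecked reactions: ",
      length(attr(imb, "unchecked")), "\n", sep = "")
  invisible(object)
}
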