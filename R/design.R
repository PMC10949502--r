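#' Strain-design analytics
#'
#' The design workflow mirrors model-guided producer engineering: compute a
#' growth state (biomass objective) and a production state (product
#' objective under a biomass lower bound), classify every reaction's
#' essentiality from the production-constrained FVA intervals, recommend a
#' regulation mode per reaction (U/D/KO/none), compute theoretical product
#' yields, and sweep a target reaction's capacity downwards to map the
#' trade-off between growth and product synthesis.
#'
#' @name strain-design
NULL

## Build the biomass-floored production model: substrate cap applied,
## biomass >= f * (max biomass), objective switched to the product export.
production_model <- function(model, config, product_exchange_id = NULL) {
  m <- apply_config(model, config)
  if (is.null(product_exchange_id)) {
    product_exchange_id <- model$objective$reaction
    if (identical(product_exchange_id, config$biomass_reaction_id))
      stop("no product objective: the model objective is the biomass ",
           "reaction; pass product_exchange_id explicitly")
  }
  if (!product_exchange_id %in% names(m$reactions))
    stop("product exchange ", product_exchange_id, " not in model")
  bm <- config$biomass_reaction_id
  if (!bm %in% names(m$reactions))
    stop("biomass reaction ", bm, " not in model")
  mg <- m
  mg$objective <- list(reaction = bm, sense = "max")
  g <- fba(mg)
  if (g$status != "optimal")
    stop("biomass maximisation returned status ", g$status)
  floor_val <- config$biomass_fraction * g$objective_value
  mp <- set_bounds(m, bm, lower_bound = floor_val)
  mp$objective <- list(reaction = product_exchange_id, sense = "max")
  attr(mp, "biomass_floor") <- floor_val
  attr(mp, "max_biomass") <- g$objective_value
  mp
}

#' Classify reactions as essential, substitutable or blocked
#'
#' Classification rule, applied to the FVA interval `(v_min, v_max)` of
#' each reaction after rounding values within `eps` of zero to zero:
#' blocked when both endpoints are zero; essential when the interval
#' excludes zero (`v_min * v_max > 0`), which subsumes the textbook
#' "identical nonzero minimum and maximum" case; substitutable otherwise
#' (the interval spans or touches zero with nonzero width). The three
#' classes partition the reaction set.
#'
#' @param fva_result an [fva()] result (or any data frame with columns
#'   `reaction_id`, `min`, `max`).
#' @param eps classification tolerance (default 1e-6).
#' @return a data frame of class `"essentiality"` with columns
#'   `reaction_id`, `class`, `v_min`, `v_max`.
#' @export
classify_reactions <- function(fva_result, eps = 1e-6) {
  stopifnot(all(c("reaction_id", "min", "max") %in% names(fva_result)))
  mn <- fva_result$min
  mx <- fva_result$max
  if (any(mn > mx + eps)) stop("malformed FVA intervals: min > max")
  rmn <- ifelse(abs(mn) <= eps, 0, mn)
  rmx <- ifelse(abs(mx) <= eps, 0, mx)
  cls <- ifelse(rmn == 0 & rmx == 0, "blocked",
                ifelse(rmn * rmx > 0, "essential", "substitutable"))
  structure(data.frame(reaction_id = fva_result$reaction_id,
                       class = cls, v_min = mn, v_max = mx,
                       stringsAsFactors = FALSE),
            class = c("essentiality", "data.frame"))
}

#' Production-constrained essentiality analysis
#'
#' Convenience wrapper: builds the biomass-floored production model, runs
#' [fva()] at objective fraction 1.0 and classifies every reaction with
#' [classify_reactions()].
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param product_exchange_id product export reaction (defaults to the
#'   model objective).
#' @return an `"essentiality"` data frame covering all reactions.
#' @export
essentiality_analysis <- function(model, config,
                                  product_exchange_id = NULL) {
  mp <- production_model(model, config, product_exchange_id)
  iv <- fva(mp, config, objective_fraction = 1.0)
  classify_reactions(iv, config$classification_tolerance)
}

#' Recommend a regulation mode per reaction
#'
#' Compares the growth state (biomass objective) with the production state
#' (product objective under the biomass floor), both ideally geometric-FBA
#' central distributions, against the essentiality classes:
#' `U` (upregulate) when the production flux magnitude exceeds the growth
#' flux magnitude by more than `eps`; `D` (downregulate) when an essential
#' reaction carries less flux in production than in growth; `KO` when a
#' substitutable or blocked reaction carries no production flux; `none`
#' otherwise.
#'
#' @param growth_state,production_state objects with a `fluxes` element
#'   (e.g. [fba()] or [geometric_fba()] fits) over the same reaction set.
#' @param essentiality result of [classify_reactions()].
#' @param eps comparison tolerance (default 1e-6).
#' @return a data frame of class `"design_recommendation"`, ordered by
#'   reaction id, with columns `reaction_id`, `class`, `mode`,
#'   `growth_flux`, `production_flux`.
#' @export
recommend_regulation <- function(growth_state, production_state,
                                 essentiality, eps = 1e-6) {
  gf <- growth_state$fluxes
  pf <- production_state$fluxes
  if (!setequal(names(gf), names(pf)) ||
      !setequal(names(gf), essentiality$reaction_id))
    stop("growth state, production state and essentiality records must ",
         "cover the same reaction set")
  ids <- sort(essentiality$reaction_id)
  cls <- essentiality$class[match(ids, essentiality$reaction_id)]
  g <- abs(gf[ids])
  p <- abs(pf[ids])
  mode <- rep("none", length(ids))
  mode[cls %in% c("substitutable", "blocked") & p <= eps] <- "KO"
  mode[p > g + eps] <- "U"
  mode[p < g - eps & cls == "essential"] <- "D"
  structure(data.frame(reaction_id = ids, class = cls, mode = mode,
                       growth_flux = as.numeric(gf[ids]),
                       production_flux = as.numeric(pf[ids]),
                       stringsAsFactors = FALSE),
            class = c("design_recommendation", "data.frame"))
}

#' Theoretical maximum product yield
#'
#' The stoichiometric ceiling: substrate uptake fixed at 1 mmol/gCDW/h,
#' biomass lower bound and maintenance demands released to zero, product
#' export maximised. The yield is mol product per mol substrate.
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()] naming the substrate exchange.
#' @param product_exchange_id product export reaction id.
#' @return a list of class `"yield_report"`: `product_id`, `substrate_id`,
#'   `yield`, `biomass_fraction_used` (0), `status`, plus the raw product
#'   and substrate fluxes and, when formulas are available, the carbon
#'   counts backing the conservation check.
#' @export
max_theoretical_yield <- function(model, config, product_exchange_id) {
  if (!product_exchange_id %in% names(model$reactions))
    stop("product exchange ", product_exchange_id, " not in model")
  m <- model
  ex <- config$substrate_exchange_id
  if (!ex %in% names(m$reactions))
    stop("substrate exchange ", ex, " not in model")
  m <- set_bounds(m, ex, lower_bound = -1, upper_bound = -1)
  bm <- config$biomass_reaction_id
  if (bm %in% names(m$reactions) && m$reactions[[bm]]$lower_bound > 0)
    m <- set_bounds(m, bm, lower_bound = 0)
  ## release maintenance-type demands (pseudo reactions other than biomass)
  for (r in m$reactions)
    if (r$is_pseudo && r$id != bm && r$lower_bound > 0)
      m <- set_bounds(m, r$id, lower_bound = 0)
  m$objective <- list(reaction = product_exchange_id, sense = "max")
  fit <- fba(m)
  carbon_of <- function(rxn_id) {
    met <- names(m$reactions[[rxn_id]]$stoichiometry)
    f <- m$metabolites[[met]]$formula
    if (is.null(f) || !"C" %in% names(f)) NA_real_ else unname(f[["C"]])
  }
  yield <- if (fit$status == "optimal")
    unname(fit$fluxes[product_exchange_id]) / 1 else NA_real_
  structure(list(product_id = product_exchange_id,
                 substrate_id = ex,
                 yield = yield,
                 biomass_fraction_used = 0,
                 status = fit$status,
                 product_flux = if (fit$status == "optimal")
                   unname(fit$fluxes[product_exchange_id]) else NA_real_,
                 substrate_uptake = 1,
                 product_carbon = carbon_of(product_exchange_id),
                 substrate_carbon = carbon_of(ex)),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Theoretical yield: ", x$product_id, " / ", x$substrate_id, " = ",
      format(x$yield, digits = 8), " mol/mol (status ", x$status, ")\n",
      sep = "")
  invisible(x)
}

#' Biomass-constrained production simulation
#'
#' Imposes biomass >= f x (max biomass), with f from the configuration
#' (default 0.2), then maximises the product export by geometric FBA,
#' returning the unique central distribution.
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param product_exchange_id product export reaction (defaults to the
#'   model objective when that is not the biomass reaction).
#' @return a `gfba_fit` with attributes `biomass_floor` and `max_biomass`.
#' @export
simulate_production <- function(model, config, product_exchange_id = NULL) {
  mp <- production_model(model, config, product_exchange_id)
  fit <- geometric_fba(mp, config)
  attr(fit, "biomass_floor") <- attr(mp, "biomass_floor")
  attr(fit, "max_biomass") <- attr(mp, "max_biomass")
  fit
}

#' Relative-flux attenuation sweep
#'
#' Emulates promoter attenuation of one target reaction: its flux is
#' capped at `r` times its flux in the biomass-floored production state
#' (the control), for each fraction `r` of `config$sweep_fractions`. Each
#' row re-solves lexicographically — maximise biomass under the cap, then
#' maximise the product at that biomass, then (optionally) centre the
#' remaining degeneracy by geometric FBA — so the `r = 1` row reproduces
#' the unswept production state and lower caps trade biomass for product.
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param target_reaction_id the attenuated reaction (e.g. the aconitase
#'   reaction).
#' @param product_exchange_id product export (defaults to the model
#'   objective).
#' @param refine `"gfba"` (default) centres every row; `"fba"` records the
#'   raw lexicographic FBA vertex (faster).
#' @param cap_mode `"upper"` (default) caps the flux magnitude from above;
#'   `"equality"` pins it, which can manufacture infeasibility artefacts.
#' @return an object of class `"sweep_result"`: `target_reaction_id`,
#'   `control_flux`, `fractions`, `rows` (per fraction: a fit or an
#'   infeasible marker), `relative` (fraction x reaction matrix of fluxes
#'   relative to control, 0/0 mapped to 1) and `control_fluxes`.
#' @export
sweep_relative_flux <- function(model, config, target_reaction_id,
                                product_exchange_id = NULL,
                                refine = c("gfba", "fba"),
                                cap_mode = c("upper", "equality")) {
  refine <- match.arg(refine)
  cap_mode <- match.arg(cap_mode)
  eps <- config$classification_tolerance
  mp <- production_model(model, config, product_exchange_id)
  if (!target_reaction_id %in% names(mp$reactions))
    stop("target reaction ", target_reaction_id, " not in model")
  control <- geometric_fba(mp, config)
  vc <- control$fluxes
  cflux <- unname(vc[target_reaction_id])
  if (abs(cflux) <= eps)
    stop("target reaction ", target_reaction_id,
         " carries no flux in the control production state")
  bm <- config$biomass_reaction_id
  prod_id <- mp$objective$reaction
  fracs <- config$sweep_fractions
  rows <- vector("list", length(fracs))
  names(rows) <- format(fracs)
  for (k in seq_along(fracs)) {
    r <- fracs[k]
    cap <- r * cflux
    mr <- set_bounds(mp, bm, lower_bound = 0)      # floor re-derived below
    if (cap_mode == "equality") {
      mr <- set_bounds(mr, target_reaction_id, cap, cap)
    } else if (cflux > 0) {
      mr <- set_bounds(mr, target_reaction_id, upper_bound = cap)
    } else {
      mr <- set_bounds(mr, target_reaction_id, lower_bound = cap)
    }
    ## stage 1: maximal biomass under the cap
    mg <- mr
    mg$objective <- list(reaction = bm, sense = "max")
    g <- fba(mg)
    if (g$status != "optimal") {
      rows[[k]] <- list(status = "infeasible", fraction = r)
      next
    }
    bio <- g$objective_value
    ## stage 2: maximal product at that biomass
    slack <- 1e-9 * (1 + abs(bio))
    mr2 <- set_bounds(mr, bm, lower_bound = max(0, bio - slack))
    mr2$objective <- list(reaction = prod_id, sense = "max")
    fit <- if (refine == "gfba") geometric_fba(mr2, config) else fba(mr2)
    if (fit$status != "optimal") {
      rows[[k]] <- list(status = "infeasible", fraction = r)
      next
    }
    fit$fraction <- r
    rows[[k]] <- fit
  }
  rel <- matrix(NA_real_, length(fracs), length(vc),
                dimnames = list(format(fracs), names(vc)))
  for (k in seq_along(fracs)) {
    if (!is.null(rows[[k]]$fluxes)) {
      v <- rows[[k]]$fluxes[names(vc)]
      ratio <- ifelse(abs(vc) <= eps,
                      ifelse(abs(v) <= eps, 1, Inf * sign(v)),
                      v / vc)
      rel[k, ] <- ratio
    }
  }
  structure(list(target_reaction_id = target_reaction_id,
                 control_flux = cflux,
                 fractions = fracs,
                 rows = rows,
                 relative = rel,
                 control_fluxes = vc,
                 product_exchange_id = prod_id),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  ok <- vapply(x$rows, function(r) !is.null(r$fluxes), logical(1))
  cat("Attenuation sweep of ", x$target_reaction_id, " (control flux ",
      format(x$control_flux, digits = 6), "): ", sum(ok), "/",
      length(x$rows), " fractions feasible\n", sep = "")
  prod <- vapply(x$rows, function(r)
    if (is.null(r$fluxes)) NA_real_ else
      unname(r$fluxes[x$product_exchange_id]), numeric(1))
  print(data.frame(fraction = x$fractions, product_flux = prod))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Tabular exports (12 significant digits, deterministic)
## ---------------------------------------------------------------------------
fmt12 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) if (v > 0) "Inf" else "-Inf"
    else sprintf("%.12g", v)
  }, "")
  out
}

#' Write an essentiality table as TSV
#'
#' @param x a [classify_reactions()] result.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_essentiality_tsv <- function(x, path) {
  df <- data.frame(reaction_id = x$reaction_id, class = x$class,
                   v_min = fmt12(x$v_min), v_max = fmt12(x$v_max))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a sweep result as TSV (one row per fraction x reaction)
#'
#' @param x a [sweep_relative_flux()] result.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_sweep_tsv <- function(x, path) {
  rel <- x$relative
  df <- data.frame(fraction = rep(x$fractions, each = ncol(rel)),
                   reaction_id = rep(colnames(rel), nrow(rel)),
                   relative_flux = fmt12(as.vector(t(rel))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a yield report as JSON
#'
#' @param x a [max_theoretical_yield()] result.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_yield_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
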