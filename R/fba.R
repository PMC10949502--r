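#' Flux balance analysis and variability analysis
#'
#' [fba()] maximises (or minimises) the model objective under the
#' steady-state constraint S v = 0 and the flux bounds; [fva()] computes,
#' per reaction, the attainable flux interval while the objective is held
#' at a fraction of its optimum; [geometric_fba()] selects the unique
#' central flux distribution among alternate optima.
#'
#' @name flux-analysis
NULL

## Build the lp_problem for a model; optionally apply the substrate cap
## from a sim_config and/or override the objective reaction.
model_lp <- function(model, config = NULL, objective_id = NULL,
                     sense = NULL) {
  if (!is.null(config)) model <- apply_config(model, config)
  S <- stoichiometric_matrix(model)
  rxns <- model$reactions
  lb <- vapply(rxns, `[[`, numeric(1), "lower_bound")
  ub <- vapply(rxns, `[[`, numeric(1), "upper_bound")
  if (is.null(objective_id)) objective_id <- model$objective$reaction
  if (is.null(sense)) sense <- model$objective$sense
  obj <- numeric(ncol(S))
  names(obj) <- colnames(S)
  if (!objective_id %in% colnames(S))
    stop("objective reaction ", objective_id, " not in model")
  obj[objective_id] <- 1
  lp_problem(obj, S, rep(0, nrow(S)), lb, ub, sense = sense,
             var_names = colnames(S))
}

#' Apply a simulation configuration to a model
#'
#' Imposes the substrate uptake cap as `lower_bound = -substrate_uptake_max`
#' on the substrate exchange reaction (uptake carries negative flux).
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @return the capped model.
#' @export
apply_config <- function(model, config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$substrate_exchange_id
  if (!ex %in% names(model$reactions))
    stop("substrate exchange ", ex, " not present in model")
  set_bounds(model, ex, lower_bound = -config$substrate_uptake_max)
}

#' Flux balance analysis
#'
#' @param model a `metabolic_model` with its objective set.
#' @param config optional [sim_config()]; when given, the substrate uptake
#'   cap is imposed before solving.
#' @return an object of class `"fba_fit"`: a list with `fluxes` (named
#'   vector, mmol/gCDW/h), `objective_value`, `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective` and `model_id`.
#'   An infeasible model yields `status = "infeasible"`, not an error.
#' @export
fba <- function(model, config = NULL) {
  prob <- model_lp(model, config)
  tol <- if (is.null(config)) 1e-9 else config$lp_tolerance
  sol <- solve_lp(prob, tol = tol)
  structure(list(fluxes = sol$x,
                 objective_value = sol$objective_value,
                 status = sol$status,
                 objective = model$objective,
                 model_id = model$id),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA fit (", x$model_id, "): status ", x$status, sep = "")
  if (x$status == "optimal")
    cat("; ", x$objective$sense, " ", x$objective$reaction, " = ",
        format(x$objective_value, digits = 8), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.fba_fit <- function(object, ...) object$fluxes

#' @export
summary.fba_fit <- function(object, ...) {
  print(object)
  if (object$status == "optimal") {
    nz <- object$fluxes[abs(object$fluxes) > 1e-9]
    cat(length(nz), "of", length(object$fluxes),
        "reactions carry flux; largest magnitudes:\n")
    print(round(head(nz[order(-abs(nz))], 10), 6))
  }
  invisible(object)
}

## Threshold for "objective >= fraction * optimum": multiplicative for a
## positive optimum, as-is for a zero (or negative) one -- a fraction of
## zero is zero and scaling a negative optimum would loosen nothing.
objective_threshold <- function(opt, fraction, tol) {
  if (opt > tol) fraction * opt else opt
}

#' Flux variability analysis
#'
#' For every reaction, minimises and maximises its flux subject to the
#' model constraints and the objective held at `objective_fraction` times
#' its FBA optimum (2N LP solves).
#'
#' @param model a `metabolic_model`.
#' @param config optional [sim_config()].
#' @param objective_fraction fraction of the FBA optimum to retain, in
#'   `[0,1]` (default 1.0).
#' @param reactions optional character vector restricting the analysis to
#'   a subset of reactions (default: all).
#' @return an object of class `"fva_fit"`: a data frame with columns
#'   `reaction_id`, `min`, `max` and attributes `objective_fraction` and
#'   `optimum`.
#' @export
fva <- function(model, config = NULL, objective_fraction = 1.0,
                reactions = NULL) {
  if (objective_fraction < 0 || objective_fraction > 1)
    stop("objective_fraction must lie in [0,1]")
  tol <- if (is.null(config)) 1e-9 else config$lp_tolerance
  prob <- model_lp(model, config)
  base <- solve_lp(prob, tol = tol)
  if (base$status != "optimal")
    stop("model is ", base$status, " at objective fraction ",
         objective_fraction, "; cannot run FVA")
  opt <- base$objective_value
  out <- fva_core(prob, model$objective$reaction, model$objective$sense,
                  opt, objective_fraction, tol,
                  reactions %||% prob$var_names)
  structure(out, objective_fraction = objective_fraction, optimum = opt,
            class = c("fva_fit", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## FVA engine over a prepared lp_problem; `opt` is the base optimum.
fva_core <- function(prob, objective_id, sense, opt, fraction, tol,
                     reactions) {
  thr <- objective_threshold(opt, fraction, 1e-7)
  slack <- 1e-9 * (1 + abs(thr))
  oi <- match(objective_id, prob$var_names)
  p <- prob
  if (sense == "max") p$lb[oi] <- max(p$lb[oi], thr - slack)
  else p$ub[oi] <- min(p$ub[oi], thr + slack)
  idx <- match(reactions, prob$var_names)
  if (anyNA(idx)) stop("unknown reaction(s) in FVA request")
  mn <- mx <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (p$ub[j] - p$lb[j] < 1e-15) {      # pinned: no LP needed
      mn[k] <- p$lb[j]
      mx[k] <- p$ub[j]
      next
    }
    q <- p
    q$objective <- numeric(length(p$objective))
    q$objective[j] <- 1
    q$sense <- "min"
    smin <- solve_lp(q, tol = tol)
    q$sense <- "max"
    smax <- solve_lp(q, tol = tol)
    if (smin$status != "optimal" || smax$status != "optimal")
      stop("FVA subproblem for ", reactions[k], " returned ",
           smin$status, "/", smax$status)
    mn[k] <- smin$objective_value
    mx[k] <- smax$objective_value
  }
  ## numerical guard: intervals must nest within bounds and be ordered
  mn <- pmax(mn, p$lb[idx])
  mx <- pmin(mx, p$ub[idx])
  sw <- mn > mx
  if (any(sw)) { mid <- (mn[sw] + mx[sw]) / 2; mn[sw] <- mid; mx[sw] <- mid }
  data.frame(reaction_id = reactions, min = mn, max = mx,
             stringsAsFactors = FALSE)
}

#' @export
print.fva_fit <- function(x, ...) {
  cat("FVA at objective fraction ", attr(x, "objective_fraction"),
      " (optimum ", format(attr(x, "optimum"), digits = 8), "), ",
      nrow(x), " reactions\n", sep = "")
  print.data.frame(head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' Geometric flux balance analysis
#'
#' Among the typically many alternate optima of [fba()], selects a unique,
#' central flux distribution: iteratively (i) compute the FVA intervals at
#' objective fraction 1.0, (ii) find the flux vector minimising the L1
#' distance to the interval midpoints, (iii) restrict each flux to the
#' segment between that vector and the midpoints, until the widest
#' remaining interval is below `sqrt(lp_tolerance)`. The result attains
#' the FBA optimum and is invariant under reaction reordering and under
#' common positive rescaling of the network.
#'
#' @param model a `metabolic_model`.
#' @param config optional [sim_config()]; supplies `lp_tolerance` and the
#'   iteration cap `max_iter` (defaults 1e-9 and 30).
#' @return an object of class `c("gfba_fit", "fba_fit")` with the extra
#'   fields `iterations` and `max_interval_width`.
#' @export
geometric_fba <- function(model, config = NULL) {
  tol <- if (is.null(config)) 1e-9 else config$lp_tolerance
  max_iter <- if (is.null(config)) 30L else config$max_iter
  prob <- model_lp(model, config)
  base <- solve_lp(prob, tol = tol)
  if (base$status != "optimal")
    stop("geometric FBA requires a feasible, bounded model (status ",
         base$status, ")")
  opt <- base$objective_value
  oi <- match(model$objective$reaction, prob$var_names)
  slack <- 1e-9 * (1 + abs(opt))
  if (model$objective$sense == "max") prob$lb[oi] <- max(prob$lb[oi], opt - slack)
  else prob$ub[oi] <- min(prob$ub[oi], opt + slack)

  n <- length(prob$objective)
  width_tol <- sqrt(tol)
  v <- base$x
  it <- 0L
  repeat {
    it <- it + 1L
    ## only reactions whose current interval is still wide need new FVA
    active <- which(prob$ub - prob$lb > width_tol)
    if (length(active)) {
      iv <- fva_core(prob, model$objective$reaction, model$objective$sense,
                     opt, 1.0, tol, prob$var_names[active])
      prob$lb[active] <- iv$min
      prob$ub[active] <- iv$max
    }
    width <- prob$ub - prob$lb
    if (max(width) < width_tol) {
      v <- (prob$lb + prob$ub) / 2
      names(v) <- prob$var_names
      break
    }
    if (it > max_iter) {
      cond <- simpleError(paste0("geometric FBA did not converge in ",
                                 max_iter, " iterations (max width ",
                                 format(max(width)), ")"))
      cond$last_iterate <- v
      stop(cond)
    }
    mid <- (prob$lb + prob$ub) / 2
    v <- l1_fit(prob, prob$lb, prob$ub, mid, tol,
                active = which(width > width_tol))
    prob$lb <- pmin(pmax(pmin(v, mid), prob$lb), prob$ub)
    prob$ub <- pmax(pmin(pmax(v, mid), prob$ub), prob$lb)
  }
  structure(list(fluxes = v,
                 objective_value = unname(v[oi]),
                 status = "optimal",
                 objective = model$objective,
                 model_id = model$id,
                 iterations = it,
                 max_interval_width = max(prob$ub - prob$lb)),
            class = c("gfba_fit", "fba_fit"))
}

## min sum |v - mid| subject to S v = 0 and interval bounds:
## v_j - p_j + q_j = mid_j with p, q >= 0 for the active (still-wide)
## reactions; pinned reactions need no deviation variables.
l1_fit <- function(prob, lo, hi, mid, tol, active = seq_along(mid)) {
  n <- length(prob$objective)
  m <- nrow(prob$Aeq)
  a <- length(active)
  Aeq <- cbind(prob$Aeq, matrix(0, m, 2 * a))
  dev <- matrix(0, a, n + 2 * a)
  dev[cbind(seq_len(a), active)] <- 1
  dev[cbind(seq_len(a), n + seq_len(a))] <- -1
  dev[cbind(seq_len(a), n + a + seq_len(a))] <- 1
  A <- rbind(Aeq, dev)
  b <- c(prob$beq, mid[active])
  lb <- c(lo, rep(0, 2 * a))
  ub <- c(hi, rep(Inf, 2 * a))
  obj <- c(rep(0, n), rep(1, 2 * a))
  p <- lp_problem(obj, A, b, lb, ub, sense = "min",
                  var_names = c(prob$var_names,
                                paste0(".p", seq_len(a)),
                                paste0(".q", seq_len(a))))
  s <- solve_lp(p, tol = tol)
  if (s$status != "optimal")
    stop("L1 centring subproblem returned ", s$status)
  out <- s$x[seq_len(n)]
  names(out) <- prob$var_names
  out
}

#' @export
print.gfba_fit <- function(x, ...) {
  cat("Geometric FBA fit (", x$model_id, "): ", x$objective$sense, " ",
      x$objective$reaction, " = ", format(x$objective_value, digits = 8),
      " after ", x$iterations, " refinement iterations (max interval width ",
      format(x$max_interval_width, digits = 3), ")\n", sep = "")
  invisible(x)
}
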