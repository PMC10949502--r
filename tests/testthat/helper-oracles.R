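# Independent brute-force oracles for the LP layer, plus shared fixtures.
# The vertex enumerator is deliberately naive: it enumerates all basic
# solutions (choose rank(A) basic columns, pin the rest at a bound, solve
# the square-ish system, keep consistent feasible points) and never calls
# the package's simplex.

enumerate_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  r <- qr(A)$rank
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  verts <- list()
  combos <- utils::combn(n, r, simplify = FALSE)
  for (cols in combos) {
    B <- A[, cols, drop = FALSE]
    if (qr(B)$rank < r) next
    nb <- setdiff(seq_len(n), cols)
    k <- length(nb)
    for (mask in seq_len(2^k) - 1L) {
      x <- numeric(n)
      bits <- as.integer(intToBits(mask))[seq_len(max(k, 1L))]
      if (k > 0) x[nb] <- ifelse(bits[seq_len(k)] == 1L, ub[nb], lb[nb])
      rhs <- b - if (k > 0) A[, nb, drop = FALSE] %*% x[nb] else 0
      qrB <- qr(B)
      xb <- qr.coef(qrB, rhs)
      xb[is.na(xb)] <- 0
      x[cols] <- xb
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
      if (k == 0) break
    }
  }
  if (!length(verts)) return(NULL)
  do.call(rbind, verts)
}

# max c'v over the polytope {Av = b, lb <= v <= ub} by vertex enumeration
oracle_lp_max <- function(A, b, cc, lb, ub) {
  V <- enumerate_vertices(A, b, lb, ub)
  if (is.null(V)) return(NULL)          # infeasible
  max(V %*% cc)
}

# per-coordinate min/max over the optimal face (objective pinned at opt)
oracle_fva <- function(A, b, cc, lb, ub, opt) {
  A2 <- rbind(A, cc)
  b2 <- c(b, opt)
  V <- enumerate_vertices(A2, b2, lb, ub)
  if (is.null(V)) return(NULL)
  list(min = apply(V, 2, min), max = apply(V, 2, max))
}

# assemble the FBA LP of a model by an independent path (no model_lp)
hand_lp <- function(model, objective_id = model$objective$reaction) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  A <- matrix(0, length(mids), length(rids),
              dimnames = list(mids, rids))
  for (r in model$reactions)
    for (met in names(r$stoichiometry))
      A[met, r$id] <- r$stoichiometry[[met]]
  list(A = A, b = rep(0, length(mids)),
       lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"),
       cc = as.numeric(rids == objective_id))
}

# lazily computed shared fixtures (expensive geometric-FBA states)
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache))
    assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

core_cfg <- function() sim_config()
core_wt <- function() cached("core_wt", build_core_model())
core_growth_gfba <- function() cached(
  "core_growth_gfba",
  geometric_fba(apply_config(core_wt(), core_cfg()), core_cfg()))
core_leu_production <- function() cached(
  "core_leu_production",
  simulate_production(core_wt(), core_cfg(), "EX_leu"))
core_leu_essentiality <- function() cached(
  "core_leu_essentiality",
  essentiality_analysis(core_wt(), core_cfg(), "EX_leu"))
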