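#' Linear programming layer
#'
#' All flux computations in this package reduce to linear programmes of the
#' form: optimise \eqn{c'v} subject to \eqn{A v = b} and \eqn{l \le v \le u},
#' optionally extended by extra linear rows with relation `<=`, `>=` or `=`.
#' The solver is a dense bounded-variable two-phase revised simplex with
#' Bland's-rule anti-cycling and periodic basis refactorisation. It is
#' deterministic: a fixed problem always returns the same vertex.
#'
#' @name lp
NULL

#' Construct a linear programme
#'
#' @param objective numeric objective vector, one entry per variable.
#' @param Aeq equality-constraint matrix (rows are constraints). May have
#'   zero rows.
#' @param beq right-hand side of the equality constraints (default all zero,
#'   the steady-state case).
#' @param lb,ub numeric vectors of lower/upper variable bounds; `-Inf`/`Inf`
#'   allowed.
#' @param sense `"max"` or `"min"`.
#' @param extra optional extra linear constraints: a list with components
#'   `A` (matrix, one row per constraint), `relation` (character vector of
#'   `"<="`, `">="`, `"="`) and `rhs` (numeric).
#' @param var_names optional variable names (defaults to `colnames(Aeq)`).
#' @return an object of class `"lp_problem"`.
#' @export
lp_problem <- function(objective, Aeq, beq = NULL, lb, ub,
                       sense = c("max", "min"), extra = NULL,
                       var_names = NULL) {
  sense <- match.arg(sense)
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  if (length(objective) != n)
    stop("objective length ", length(objective), " != number of variables ", n)
  if (is.null(beq)) beq <- rep(0, nrow(Aeq))
  if (length(beq) != nrow(Aeq)) stop("beq length does not match Aeq rows")
  if (length(lb) != n || length(ub) != n) stop("bound lengths != n variables")
  if (any(lb > ub + 1e-12)) stop("lower bound exceeds upper bound for some variable")
  if (is.null(var_names)) var_names <- colnames(Aeq)
  if (is.null(var_names)) var_names <- paste0("v", seq_len(n))
  if (!is.null(extra)) {
    extra$A <- matrix(extra$A, ncol = n)
    if (ncol(extra$A) != n) stop("extra constraint matrix column count != n")
    if (!all(extra$relation %in% c("<=", ">=", "=")))
      stop("extra relations must be one of <=, >=, =")
    if (length(extra$rhs) != nrow(extra$A) ||
        length(extra$relation) != nrow(extra$A))
      stop("extra constraint components have inconsistent lengths")
  }
  structure(list(objective = as.numeric(objective), Aeq = Aeq,
                 beq = as.numeric(beq), lb = as.numeric(lb),
                 ub = as.numeric(ub), sense = sense, extra = extra,
                 var_names = var_names),
            class = "lp_problem")
}

#' Solve a linear programme
#'
#' @param problem an [lp_problem()].
#' @param tol numeric feasibility/optimality tolerance.
#' @param max_iter simplex iteration cap (default scales with problem size).
#' @return a list of class `"lp_solution"` with components `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `x` (named solution
#'   vector, only for optimal), `objective_value` and `iterations`.
#' @export
solve_lp <- function(problem, tol = 1e-9, max_iter = NULL) {
  stopifnot(inherits(problem, "lp_problem"))
  n <- length(problem$objective)
  A <- problem$Aeq
  b <- problem$beq
  lb <- problem$lb
  ub <- problem$ub
  cc <- problem$objective
  nm <- problem$var_names

  ## fold extra rows in: "=" rows appended plainly, inequalities get a slack
  if (!is.null(problem$extra)) {
    ex <- problem$extra
    for (k in seq_len(nrow(ex$A))) {
      row <- ex$A[k, ]
      rel <- ex$relation[k]
      if (rel == "=") {
        A <- rbind(A, c(row, rep(0, ncol(A) - n)))
        b <- c(b, ex$rhs[k])
      } else {
        ## row' v + s = rhs, s >= 0 for "<=", s <= 0 for ">="
        A <- rbind(cbind(A, 0), c(row, rep(0, ncol(A) - n), 1))
        b <- c(b, ex$rhs[k])
        if (rel == "<=") { lb <- c(lb, 0); ub <- c(ub, Inf) }
        else { lb <- c(lb, -Inf); ub <- c(ub, 0) }
        cc <- c(cc, 0)
      }
    }
  }

  maximize <- problem$sense == "max"
  res <- simplex_bounded(A, b, if (maximize) -cc else cc, lb, ub,
                         tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    names(x) <- nm
    obj <- sum(problem$objective * x)
    out <- list(status = "optimal", x = x, objective_value = obj,
                iterations = res$iterations)
  } else {
    out <- list(status = res$status, x = NULL, objective_value = NA_real_,
                iterations = res$iterations)
  }
  class(out) <- "lp_solution"
  out
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("LP solution: status =", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 10))
  cat(" (", x$iterations, " simplex iterations)\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Bounded-variable two-phase revised simplex (minimisation).
## Variables may have -Inf/Inf bounds; nonbasic variables sit at a finite
## bound or (if free) at zero. Phase 1 introduces one artificial per row.
## ---------------------------------------------------------------------------
simplex_bounded <- function(A, b, cc, lb, ub, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)

  ## no equality rows: solve by inspection of signs
  if (m == 0L) {
    x <- numeric(n)
    for (j in seq_len(n)) {
      if (cc[j] > tol) {
        if (!is.finite(lb[j]))
          return(list(status = "unbounded", iterations = 0L))
        x[j] <- lb[j]
      } else if (cc[j] < -tol) {
        if (!is.finite(ub[j]))
          return(list(status = "unbounded", iterations = 0L))
        x[j] <- ub[j]
      } else x[j] <- if (is.finite(lb[j])) lb[j] else if (is.finite(ub[j])) ub[j] else 0
    }
    return(list(status = "optimal", x = x, objective = sum(cc * x),
                iterations = 0L))
  }

  ## initial nonbasic point: bound nearest zero, or zero for free variables
  x <- numeric(n)
  status <- character(n)           # "L", "U", "F"
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) { x[j] <- lb[j]; status[j] <- "L" }
      else { x[j] <- ub[j]; status[j] <- "U" }
    } else if (is.finite(lb[j])) { x[j] <- lb[j]; status[j] <- "L" }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; status[j] <- "U" }
    else { x[j] <- 0; status[j] <- "F" }
  }
  r <- b - drop(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)

  nt <- n + m
  Afull <- cbind(A, diag(sgn, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x, abs(r))
  statf <- c(status, rep("B", m))
  basis <- (n + 1L):nt
  Binv <- diag(sgn, nrow = m)       # inverse of diag(sgn)

  if (is.null(max_iter)) max_iter <- max(2000L, 60L * nt)
  iters_total <- 0L

  run_phase <- function(cost, xf, statf, basis, Binv, phase1) {
    degen <- 0L
    bland <- FALSE
    since_refactor <- 0L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "iterlimit", xf = xf, statf = statf,
                    basis = basis, Binv = Binv, iter = iter))
      cB <- cost[basis]
      y <- drop(crossprod(Binv, cB))          # y = Binv' cB
      d <- cost - drop(y %*% Afull)
      ## entering candidate
      nonbasic <- which(statf != "B")
      viol <- numeric(length(nonbasic))
      for (k in seq_along(nonbasic)) {
        j <- nonbasic[k]
        if (lbf[j] == ubf[j]) { viol[k] <- 0; next }  # fixed variable
        viol[k] <- switch(statf[j],
                          L = max(-d[j], 0),
                          U = max(d[j], 0),
                          F = abs(d[j]))
      }
      cmax <- if (length(viol)) max(viol) else 0
      dtol <- tol * (1 + max(abs(cost)))
      if (cmax <= dtol) {
        return(list(status = "optimal", xf = xf, statf = statf,
                    basis = basis, Binv = Binv, iter = iter))
      }
      jin <- if (bland) nonbasic[which(viol > dtol)[1L]]
             else nonbasic[which.max(viol)]
      sigma <- if (statf[jin] == "U") -1 else if (statf[jin] == "L") 1
               else if (d[jin] < 0) 1 else -1
      w <- drop(Binv %*% Afull[, jin])
      ## ratio test: x_jin moves by sigma*t, basic values move by -sigma*t*w
      tflip <- if (is.finite(lbf[jin]) && is.finite(ubf[jin]))
                 ubf[jin] - lbf[jin] else Inf
      tbest <- tflip
      ileave <- 0L
      piv_tol <- 1e-10
      for (i in seq_len(m)) {
        g <- sigma * w[i]
        bi <- basis[i]
        ti <- Inf
        if (g > piv_tol) {
          if (is.finite(lbf[bi])) ti <- (xf[bi] - lbf[bi]) / g
        } else if (g < -piv_tol) {
          if (is.finite(ubf[bi])) ti <- (xf[bi] - ubf[bi]) / g
        }
        if (!is.finite(ti)) next
        ti <- max(ti, 0)             # numerical guard against tiny negatives
        take <- ti < tbest - 1e-12 ||
          (ti <= tbest + 1e-12 &&
             (ileave == 0L ||
                (!bland && abs(w[i]) > abs(w[ileave]))))
        if (take) {
          tbest <- ti
          ileave <- i
        }
      }
      if (!is.finite(tbest))
        return(list(status = "unbounded", xf = xf, statf = statf,
                    basis = basis, Binv = Binv, iter = iter))
      if (tbest <= 1e-11) degen <- degen + 1L else degen <- 0L
      if (degen > 200L) bland <- TRUE
      ## apply the step
      if (ileave == 0L) {
        ## bound flip, basis unchanged
        xf[basis] <- xf[basis] - sigma * tbest * w
        xf[jin] <- xf[jin] + sigma * tbest
        statf[jin] <- if (statf[jin] == "L") "U" else "L"
      } else {
        bout <- basis[ileave]
        xf[basis] <- xf[basis] - sigma * tbest * w
        xf[jin] <- xf[jin] + sigma * tbest
        g <- sigma * w[ileave]
        statf[bout] <- if (g > 0) "L" else "U"
        if (statf[bout] == "L" && !is.finite(lbf[bout])) statf[bout] <- "F"
        if (statf[bout] == "U" && !is.finite(ubf[bout])) statf[bout] <- "F"
        ## snap the leaver exactly onto its bound
        if (statf[bout] == "L") xf[bout] <- lbf[bout]
        if (statf[bout] == "U") xf[bout] <- ubf[bout]
        statf[jin] <- "B"
        basis[ileave] <- jin
        ## update Binv by pivoting on w[ileave]
        piv <- w[ileave]
        Binv[ileave, ] <- Binv[ileave, ] / piv
        for (i in seq_len(m)) {
          if (i != ileave && abs(w[i]) > 0) {
            Binv[i, ] <- Binv[i, ] - w[i] * Binv[ileave, ]
          }
        }
        since_refactor <- since_refactor + 1L
        if (since_refactor >= 60L) {
          Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                           error = function(e) Binv)
          since_refactor <- 0L
        }
      }
      ## recompute basic values from scratch occasionally for accuracy
      if (iter %% 120L == 0L) {
        nb <- setdiff(seq_len(nt), basis)
        xf[basis] <- drop(Binv %*% (b - Afull[, nb, drop = FALSE] %*% xf[nb]))
      }
    }
  }

  ## phase 1: minimise the sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(cost1, xf, statf, basis, Binv, TRUE)
  iters_total <- iters_total + p1$iter
  if (p1$status == "iterlimit")
    stop("simplex iteration limit reached in phase 1")
  xf <- p1$xf; statf <- p1$statf; basis <- p1$basis; Binv <- p1$Binv
  art_sum <- sum(xf[(n + 1L):nt])
  if (art_sum > tol * (1 + max(abs(b))) * 10)
    return(list(status = "infeasible", iterations = iters_total))
  ## freeze artificials at zero
  lbf[(n + 1L):nt] <- 0
  ubf[(n + 1L):nt] <- 0
  xf[(n + 1L):nt][statf[(n + 1L):nt] != "B"] <- 0

  ## phase 2 (run_phase reads lbf/ubf from this frame, so the freeze above
  ## is already visible to it)
  cost2 <- c(cc, rep(0, m))
  p2 <- run_phase(cost2, xf, statf, basis, Binv, FALSE)
  iters_total <- iters_total + p2$iter
  if (p2$status == "iterlimit")
    stop("simplex iteration limit reached in phase 2")
  if (p2$status == "unbounded")
    return(list(status = "unbounded", iterations = iters_total))
  xf <- p2$xf
  ## final cleanup solve for accuracy
  basis <- p2$basis
  nb <- setdiff(seq_len(nt), basis)
  Bmat <- Afull[, basis, drop = FALSE]
  xb <- tryCatch(solve(Bmat, b - Afull[, nb, drop = FALSE] %*% xf[nb]),
                 error = function(e) xf[basis])
  xf[basis] <- drop(xb)
  x <- xf[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cc * x),
       iterations = iters_total)
}
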