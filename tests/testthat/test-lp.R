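# The simplex layer: basic contracts and agreement with brute force.

test_that("a box-constrained objective is driven to its bound", {
  p <- lp_problem(1, matrix(numeric(0), 0, 1), numeric(0), 0, 10,
                  sense = "max")
  s <- solve_lp(p)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10)
})

test_that("contradictory constraints are reported infeasible", {
  ## v1 pinned to 5 by an equality row, but bounded above by 3
  p <- lp_problem(1, matrix(1, 1, 1), 5, 0, 3, sense = "max")
  s <- solve_lp(p)
  expect_equal(s$status, "infeasible")
})

test_that("an uncapped improving direction is reported unbounded", {
  A <- matrix(c(1, -1), 1, 2)      # v1 = v2, both unbounded above
  p <- lp_problem(c(1, 0), A, 0, c(0, 0), c(Inf, Inf), sense = "max")
  expect_equal(solve_lp(p)$status, "unbounded")
})

test_that("extra inequality rows constrain the solution", {
  ## max v1 + v2, v1 = v2 (row), v1 + v2 <= 7
  A <- matrix(c(1, -1), 1, 2)
  p <- lp_problem(c(1, 1), A, 0, c(0, 0), c(10, 10), sense = "max",
                  extra = list(A = matrix(c(1, 1), 1, 2),
                               relation = "<=", rhs = 7))
  s <- solve_lp(p)
  expect_equal(s$objective_value, 7, tolerance = 1e-9)
  expect_equal(unname(s$x), c(3.5, 3.5), tolerance = 1e-8)
})

test_that("objectives agree with exhaustive vertex enumeration on random
           small problems", {
  set.seed(421)
  for (trial in 1:60) {
    m <- sample(2:4, 1)
    n <- sample(3:6, 1)
    A <- matrix(sample(c(-1, 0, 0, 1), m * n, replace = TRUE), m, n)
    lb <- ifelse(runif(n) < 0.5, 0, -round(runif(n, 1, 5), 1))
    ub <- round(runif(n, 1, 8), 1)
    cc <- round(runif(n, -1, 1), 2)
    p <- lp_problem(cc, A, rep(0, m), lb, ub, sense = "max")
    s <- solve_lp(p)
    ref <- oracle_lp_max(A, rep(0, m), cc, lb, ub)
    expect_equal(s$status, "optimal")  # origin is always feasible here
    expect_equal(s$objective_value, ref, tolerance = 1e-7)
  }
})

test_that("the solver is deterministic for a fixed problem", {
  m <- build_toy_network("random", seed = 99, size = 8)
  f1 <- fba(m)
  f2 <- fba(m)
  expect_identical(f1$fluxes, f2$fluxes)
})
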