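# FBA, FVA and geometric FBA against fixed fixtures and oracles.

test_that("a linear chain pushes its full capacity through every step", {
  m <- build_toy_network("chain")
  f <- fba(m)
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 10)
  expect_equal(unname(f$fluxes), rep(10, 3))
})

test_that("fba assembles the same LP as an independent hand assembly", {
  for (seed in c(3, 17, 42)) {
    m <- build_toy_network("random", seed = seed, size = 9)
    f <- fba(m)
    h <- hand_lp(m)
    p <- lp_problem(h$cc, h$A, h$b, h$lb, h$ub, sense = "max")
    s <- solve_lp(p)
    expect_equal(f$objective_value, s$objective_value, tolerance = 1e-8)
  }
})

test_that("an infeasible model yields status infeasible, not an error", {
  m <- build_toy_network("chain")
  ## force the sink while closing the source: no steady state exists
  m <- set_bounds(m, "SRC", 0, 0)
  m <- set_bounds(m, "SNK", 5, 10)
  f <- fba(m)
  expect_equal(f$status, "infeasible")
})

test_that("chain FVA collapses to points; diamond branches span (0,10)", {
  ch <- fva(build_toy_network("chain"), objective_fraction = 1.0)
  expect_equal(ch$min, rep(10, 3), tolerance = 1e-8)
  expect_equal(ch$max, rep(10, 3), tolerance = 1e-8)
  di <- fva(build_toy_network("diamond"), objective_fraction = 1.0)
  for (br in c("BR1", "BR2")) {
    expect_equal(di$min[di$reaction_id == br], 0, tolerance = 1e-8)
    expect_equal(di$max[di$reaction_id == br], 10, tolerance = 1e-8)
  }
})

test_that("FVA is sound: each endpoint is attainable at the required
           objective level", {
  m <- build_toy_network("random", seed = 7, size = 8)
  frac <- 0.8
  iv <- fva(m, objective_fraction = frac)
  opt <- attr(iv, "optimum")
  for (i in seq_len(nrow(iv))) {
    for (endpoint in c(iv$min[i], iv$max[i])) {
      m2 <- set_bounds(m, iv$reaction_id[i], endpoint - 1e-7,
                       endpoint + 1e-7)
      f2 <- fba(m2)
      expect_equal(f2$status, "optimal")
      expect_gte(f2$objective_value, frac * opt - 1e-6)
    }
  }
})

test_that("FVA intervals at fraction 1.0 nest inside lower-fraction
           intervals", {
  for (seed in c(5, 23)) {
    m <- build_toy_network("random", seed = seed, size = 8)
    hi <- fva(m, objective_fraction = 1.0)
    lo <- fva(m, objective_fraction = 0.5)
    expect_true(all(hi$min >= lo$min - 1e-7))
    expect_true(all(hi$max <= lo$max + 1e-7))
  }
})

test_that("FVA against vertex enumeration on small random networks", {
  for (seed in c(2, 11, 31)) {
    m <- build_toy_network("random", seed = seed, size = 5)
    iv <- fva(m, objective_fraction = 1.0)
    h <- hand_lp(m)
    opt <- fba(m)$objective_value
    ref <- oracle_fva(h$A, h$b, h$cc, h$lb, h$ub, opt)
    expect_equal(iv$min, unname(ref$min), tolerance = 1e-6)
    expect_equal(iv$max, unname(ref$max), tolerance = 1e-6)
  }
})

test_that("geometric FBA equals FBA when the optimum is unique and
           splits symmetric branches at the midpoint", {
  ch <- build_toy_network("chain")
  g <- geometric_fba(ch)
  expect_equal(g$fluxes, fba(ch)$fluxes, tolerance = 1e-7)
  di <- build_toy_network("diamond")
  gd <- geometric_fba(di)
  expect_equal(unname(gd$fluxes["BR1"]), 5, tolerance = 1e-6)
  expect_equal(unname(gd$fluxes["BR2"]), 5, tolerance = 1e-6)
  expect_equal(gd$objective_value, 10, tolerance = 1e-8)
})

test_that("geometric FBA lies within the fraction-1.0 FVA intervals and
           attains the FBA optimum", {
  m <- core_wt()
  cfg <- core_cfg()
  g <- core_growth_gfba()
  iv <- fva(m, cfg, objective_fraction = 1.0)
  expect_equal(g$objective_value,
               fba(m, cfg)$objective_value, tolerance = 1e-7)
  idx <- match(iv$reaction_id, names(g$fluxes))
  expect_true(all(g$fluxes[idx] >= iv$min - 1e-5))
  expect_true(all(g$fluxes[idx] <= iv$max + 1e-5))
})

test_that("geometric FBA is invariant under reaction reordering", {
  base <- build_toy_network("diamond")
  g1 <- geometric_fba(base)
  perm <- base
  ord <- c(3, 1, 4, 2)
  perm$reactions <- perm$reactions[ord]
  g2 <- geometric_fba(perm)
  expect_equal(g2$fluxes[names(g1$fluxes)], g1$fluxes, tolerance = 1e-6)
  m <- build_toy_network("random", seed = 13, size = 7)
  g3 <- geometric_fba(m)
  mp <- m
  set.seed(1)
  mp$reactions <- mp$reactions[sample(seq_along(mp$reactions))]
  g4 <- geometric_fba(mp)
  expect_equal(g4$fluxes[names(g3$fluxes)], g3$fluxes, tolerance = 1e-6)
})

test_that("geometric FBA commutes with a common positive rescaling", {
  m <- build_toy_network("diamond")
  g1 <- geometric_fba(m)
  ## scaling only S leaves the flux polytope untouched
  ms <- m
  for (id in names(ms$reactions))
    ms$reactions[[id]]$stoichiometry <-
      3 * ms$reactions[[id]]$stoichiometry
  expect_equal(geometric_fba(ms)$fluxes, g1$fluxes, tolerance = 1e-6)
  ## scaling S and bounds together scales the selected point
  a <- 2.5
  mb <- ms
  for (id in names(mb$reactions)) {
    mb$reactions[[id]]$lower_bound <- a * mb$reactions[[id]]$lower_bound
    mb$reactions[[id]]$upper_bound <- a * mb$reactions[[id]]$upper_bound
  }
  expect_equal(geometric_fba(mb)$fluxes, a * g1$fluxes,
               tolerance = 1e-6)
})

test_that("no rejection-sampled feasible point beats the FBA optimum", {
  set.seed(77)
  m <- build_toy_network("random", seed = 8, size = 6)
  f <- fba(m)
  S <- stoichiometric_matrix(m)
  lb <- vapply(m$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(m$reactions, `[[`, numeric(1), "upper_bound")
  obj <- names(m$reactions) == m$objective$reaction
  best <- -Inf
  for (i in 1:2000) {
    v <- runif(ncol(S), pmax(lb, -20), pmin(ub, 20))
    if (max(abs(S %*% v)) < 1e-6) best <- max(best, sum(v[obj]))
  }
  ## random sampling rarely hits the null space exactly; also project a
  ## few random directions through the null-space basis
  N <- MASS::Null(t(S))
  if (length(N)) {
    for (i in 1:500) {
      z <- N %*% runif(ncol(N), -20, 20)
      if (all(z >= lb - 1e-9) && all(z <= ub + 1e-9))
        best <- max(best, sum(z[obj]))
    }
  }
  expect_lte(best, f$objective_value + 1e-6)
})
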