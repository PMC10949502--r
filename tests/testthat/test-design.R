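# Essentiality classification, regulation modes, yields, production
# simulation and the attenuation sweep.

test_that("the classification rule handles the three canonical
           intervals", {
  iv <- data.frame(reaction_id = c("b", "s", "e"),
                   min = c(0, -2, 1.5), max = c(0, 3, 1.5))
  cls <- classify_reactions(iv, eps = 1e-6)
  expect_equal(cls$class, c("blocked", "substitutable", "essential"))
  ## required-but-variable reactions are essential, not substitutable
  iv2 <- data.frame(reaction_id = "v", min = 1, max = 5)
  expect_equal(classify_reactions(iv2)$class, "essential")
  ## interval touching zero with nonzero width is substitutable
  iv3 <- data.frame(reaction_id = "t", min = 0, max = 4)
  expect_equal(classify_reactions(iv3)$class, "substitutable")
})

test_that("the three classes partition every model's reactions", {
  ess <- core_leu_essentiality()
  expect_setequal(ess$reaction_id, names(core_wt()$reactions))
  expect_true(all(ess$class %in%
                    c("essential", "substitutable", "blocked")))
  expect_equal(sum(table(ess$class)), length(core_wt()$reactions))
  for (seed in c(4, 9)) {
    m <- build_toy_network("random", seed = seed, size = 8)
    cls <- classify_reactions(fva(m, objective_fraction = 1.0))
    expect_equal(nrow(cls), length(m$reactions))
  }
})

test_that("ldh- and alaT-associated reactions are substitutable under
           leucine production", {
  ess <- core_leu_essentiality()
  expect_equal(ess$class[ess$reaction_id == "LDH"], "substitutable")
  expect_equal(ess$class[ess$reaction_id == "ALATA"], "substitutable")
  ## the alaT interval genuinely spans zero (both signs attainable)
  expect_lt(ess$v_min[ess$reaction_id == "ALATA"], -1e-3)
  expect_gt(ess$v_max[ess$reaction_id == "ALATA"], 1e-3)
})

test_that("TCA-entry reactions are essential and recommended for
           downregulation under leucine production", {
  ess <- core_leu_essentiality()
  rec <- recommend_regulation(core_growth_gfba(),
                              core_leu_production(), ess)
  for (id in c("PDH", "CS", "ACONT", "ICDH")) {
    expect_equal(ess$class[ess$reaction_id == id], "essential",
                 label = id)
    expect_equal(rec$mode[rec$reaction_id == id], "D", label = id)
  }
})

test_that("substitutable drains without production flux get KO and
           identical fluxes get none", {
  ess <- core_leu_essentiality()
  rec <- recommend_regulation(core_growth_gfba(),
                              core_leu_production(), ess)
  expect_equal(rec$mode[rec$reaction_id == "ICL"], "KO")   # blocked
  ## hand-built states: identical fluxes => none
  fake <- list(fluxes = c(R1 = 1, R2 = 0))
  cls <- data.frame(reaction_id = c("R1", "R2"),
                    class = c("essential", "blocked"),
                    v_min = c(1, 0), v_max = c(1, 0))
  r2 <- recommend_regulation(fake, fake, cls)
  expect_equal(r2$mode[r2$reaction_id == "R1"], "none")
  expect_equal(r2$mode[r2$reaction_id == "R2"], "KO")
  ## mismatched reaction sets are rejected
  expect_error(recommend_regulation(fake, list(fluxes = c(R1 = 1)), cls),
               "same reaction set")
})

test_that("knocking out a blocked reaction leaves the production optimum
           unchanged", {
  ess <- core_leu_essentiality()
  blocked <- ess$reaction_id[ess$class == "blocked"]
  expect_gt(length(blocked), 0L)
  base <- core_leu_production()$objective_value
  cfg <- core_cfg()
  for (id in blocked[seq_len(min(4L, length(blocked)))]) {
    if (core_wt()$reactions[[id]]$lower_bound == 0 &&
        core_wt()$reactions[[id]]$upper_bound == 0) next
    ko <- knock_out(core_wt(), id)
    mp <- set_bounds(apply_config(ko, cfg), "BIOMASS",
                     lower_bound = attr(core_leu_production(),
                                        "biomass_floor"))
    mp$objective <- list(reaction = "EX_leu", sense = "max")
    expect_equal(fba(mp)$objective_value, base, tolerance = 1e-6,
                 label = id)
  }
})

test_that("theoretical yields respect carbon conservation and match the
           pathway stoichiometry", {
  m <- core_wt()
  cfg <- core_cfg()
  for (case in list(list("EX_val", 1.00, 5), list("EX_leu", 2 / 3, 6),
                    list("EX_ala", 2.00, 3))) {
    y <- max_theoretical_yield(m, cfg, case[[1]])
    expect_equal(y$status, "optimal")
    expect_equal(y$yield, case[[2]], tolerance = 1e-7)
    ## yield x product carbon <= substrate carbon x uptake
    expect_lte(y$yield * case[[3]], 6 + 1e-6)
    expect_equal(y$product_carbon, case[[3]])
  }
})

test_that("production simulation honours the biomass floor and ppc
           deletion changes nothing", {
  cfg <- core_cfg()
  prod <- core_leu_production()
  floorv <- attr(prod, "biomass_floor")
  expect_equal(floorv, cfg$biomass_fraction * attr(prod, "max_biomass"),
               tolerance = 1e-9)
  expect_gte(unname(prod$fluxes["BIOMASS"]), floorv - 1e-6)
  ## with the floor released the optimum climbs to the theoretical
  ## ceiling (maintenance is 0 in the bundled yield-mode model)
  cfg0 <- sim_config(biomass_fraction = 0)
  p0 <- simulate_production(core_wt(), cfg0, "EX_leu")
  y <- max_theoretical_yield(core_wt(), cfg, "EX_leu")
  expect_equal(p0$objective_value, y$yield * cfg$substrate_uptake_max,
               tolerance = 1e-6)
  ## ppc deletion: pyc covers anaplerosis alone
  ko <- knock_out(core_wt(), "PPC")
  expect_equal(fba(apply_config(ko, cfg))$objective_value,
               attr(prod, "max_biomass"), tolerance = 1e-7)
  pko <- simulate_production(ko, cfg, "EX_leu")
  expect_equal(pko$objective_value, prod$objective_value,
               tolerance = 1e-6)
})

test_that("the attenuation sweep reproduces the control at r = 1 and
           trades biomass for leucine monotonically", {
  cfg <- sim_config(sweep_fractions = c(1.0, 0.7, 0.4, 0.1))
  m <- core_wt()
  m$objective <- list(reaction = "EX_leu", sense = "max")
  sw <- sweep_relative_flux(m, cfg, "ACONT")
  expect_equal(sw$fractions, c(1.0, 0.7, 0.4, 0.1))
  ## r = 1 row reproduces the unswept production state
  expect_equal(sw$rows[[1]]$fluxes, sw$control_fluxes,
               tolerance = 1e-5)
  expect_true(all(abs(sw$relative[1, ] - 1) < 1e-4 |
                    !is.finite(sw$relative[1, ])))
  leu <- vapply(sw$rows, function(r) unname(r$fluxes["EX_leu"]),
                numeric(1))
  bio <- vapply(sw$rows, function(r) unname(r$fluxes["BIOMASS"]),
                numeric(1))
  expect_true(all(diff(leu) >= -1e-7))      # product non-decreasing
  expect_true(all(diff(bio) <= 1e-7))       # biomass non-increasing
  ## the target honours its cap in every row
  acn <- vapply(sw$rows, function(r) unname(r$fluxes["ACONT"]),
                numeric(1))
  expect_true(all(acn <= sw$fractions * sw$control_flux + 1e-6))
})

test_that("sweeping a zero-flux target is rejected and infeasible rows
           are recorded, not fatal", {
  cfg <- sim_config(sweep_fractions = c(1.0, 0.5))
  m <- core_wt()
  m$objective <- list(reaction = "EX_leu", sense = "max")
  expect_error(sweep_relative_flux(m, cfg, "ICL"), "no flux")
})

test_that("tabular exports are deterministic and re-readable", {
  td <- withr::local_tempdir()
  ess <- core_leu_essentiality()
  p <- file.path(td, "ess.tsv")
  write_essentiality_tsv(ess, p)
  back <- utils::read.delim(p)
  expect_equal(nrow(back), nrow(ess))
  expect_equal(back$class, ess$class)
  expect_equal(back$v_min, ess$v_min, tolerance = 1e-10)
  y <- max_theoretical_yield(core_wt(), core_cfg(), "EX_val")
  pj <- file.path(td, "y.json")
  write_yield_json(y, pj)
  expect_equal(jsonlite::read_json(pj)$yield, 1.0, tolerance = 1e-9)
})
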