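# Network data model: constructors, validation, mass balance, knockouts.

test_that("constructor contracts reject malformed components", {
  expect_error(metabolite(""), "non-empty")
  expect_error(metabolite("x", formula = c(C = -1)), "non-negative")
  expect_error(reaction("r", c(a = 1), lower_bound = 2, upper_bound = 1),
               "lower_bound > upper_bound")
  expect_error(reaction("r", numeric()), "empty stoichiometry")
  expect_error(reaction("ex", c(a = -1, b = 1), is_exchange = TRUE),
               "exactly one metabolite")
})

test_that("model validation names the offending reaction and metabolite", {
  mets <- list(metabolite("A"), metabolite("B"))
  bad <- list(reaction("R1", c(A = -1, XYZ = 1)))
  expect_error(metabolic_model("m", mets, bad, "R1"), "R1.*XYZ")
  dup <- list(metabolite("A"), metabolite("A"))
  expect_error(metabolic_model("m", dup,
                               list(reaction("R1", c(A = 1))), "R1"),
               "duplicate metabolite")
  expect_error(metabolic_model("m", mets,
                               list(reaction("R1", c(A = 1)),
                                    reaction("R1", c(B = 1))), "R1"),
               "duplicate reaction")
  expect_error(metabolic_model("m", mets,
                               list(reaction("R1", c(A = 1))), "NOPE"),
               "objective reaction")
})

test_that("the stoichiometric matrix matches the model dimensions", {
  m <- build_core_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(length(m$metabolites), length(m$reactions)))
  expect_equal(rownames(S), names(m$metabolites))
  ## spot check the PDH column: pyruvate in, acetyl-CoA + CO2 out
  expect_equal(S["pyr", "PDH"], -1)
  expect_equal(S["accoa", "PDH"], 1)
  expect_equal(S["co2", "PDH"], 1)
})

test_that("mass balance passes pyruvate decarboxylation and flags a
           corrupted reaction", {
  mets <- list(metabolite("pyr", formula = c(C = 3)),
               metabolite("accoa", formula = c(C = 2)),
               metabolite("co2", formula = c(C = 1)))
  good <- reaction("PDH", c(pyr = -1, accoa = 1, co2 = 1))
  bad <- reaction("PDHX", c(pyr = -1, accoa = 1))   # drops the CO2
  m <- metabolic_model("t", mets, list(good, bad), "PDH")
  imb <- check_mass_balance(m)
  expect_equal(nrow(imb), 1L)
  expect_equal(imb$reaction_id, "PDHX")
  expect_equal(imb$element, "C")
  expect_equal(imb$imbalance, -1)
})

test_that("metabolites without formulas are reported unchecked, not
           failed", {
  mets <- list(metabolite("A"), metabolite("B", formula = c(C = 1)))
  m <- metabolic_model("t", mets,
                       list(reaction("R", c(A = -1, B = 1))), "R")
  imb <- check_mass_balance(m)
  expect_equal(nrow(imb), 0L)
  expect_equal(attr(imb, "unchecked"), "R")
})

test_that("knock_out zeroes bounds, is idempotent and commutes", {
  m <- core_wt()
  k1 <- knock_out(m, "PYC")
  expect_equal(k1$reactions$PYC$lower_bound, 0)
  expect_equal(k1$reactions$PYC$upper_bound, 0)
  ## original untouched
  expect_equal(m$reactions$PYC$upper_bound, 1000)
  expect_identical(knock_out(k1, "PYC"), k1)
  ab <- knock_out(knock_out(m, "PYC"), "PPC")
  ba <- knock_out(knock_out(m, "PPC"), "PYC")
  expect_identical(ab, ba)
  expect_error(knock_out(m, "NOPE"), "unknown reaction")
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(substrate_uptake_max = -1), "positive")
  expect_error(sim_config(biomass_fraction = 1.5), "0,1")
  expect_error(sim_config(sweep_fractions = c(0.5, 0.9)), "descending")
  expect_error(sim_config(sweep_fractions = c(1.0, 0)), "0,1")
  cfg <- sim_config()
  expect_equal(cfg$substrate_uptake_max, 4.67)
  expect_equal(cfg$biomass_fraction, 0.2)
  expect_equal(cfg$sweep_fractions, seq(1, 0.1, by = -0.1))
})
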