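# The bundled central-carbon core model and its presets.

test_that("the generator output validates and is elementally balanced", {
  m <- core_wt()
  expect_true(validate_model(m))
  imb <- check_mass_balance(m)
  expect_equal(nrow(imb), 0L)
  expect_length(attr(imb, "unchecked"), 0L)
  expect_gte(length(m$reactions), 45L)
  expect_lte(length(m$reactions), 62L)
})

test_that("the wild type grows on glucose and carbon closes at any
           optimum", {
  m <- core_wt()
  f <- fba(m, core_cfg())
  expect_equal(f$status, "optimal")
  expect_gt(f$objective_value, 0)
  ## carbon closure with uptake fixed to 1: exports carry 6 C total
  m1 <- set_bounds(m, "EX_glc", -1, -1)
  m1$objective <- list(reaction = "EX_ala", sense = "max")
  f1 <- fba(m1)
  carbon <- vapply(m1$reactions, function(r) {
    if (!r$is_exchange) return(0)
    met <- m1$metabolites[[names(r$stoichiometry)]]
    unname(met$formula["C"]) * unname(f1$fluxes[r$id])
  }, numeric(1))
  ## uptake is negative: net export carbon equals imported carbon
  expect_equal(sum(carbon), 0, tolerance = 1e-6)
  expect_equal(-carbon[["EX_glc"]], 6, tolerance = 1e-6)
})

test_that("anaplerosis-free growth is abolished and the glyoxylate
           genotype rescues it", {
  cfg <- core_cfg()
  m28 <- build_core_model(genotype = "LEU-28")
  expect_equal(fba(m28, cfg)$objective_value, 0, tolerance = 1e-9)
  m29 <- build_core_model(genotype = "LEU-29")
  expect_gt(fba(m29, cfg)$objective_value, 0)
})

test_that("LEU-29 equals LEU-28 plus glyoxylate opening and icd
           attenuation", {
  a <- build_core_model(genotype = "LEU-29")
  b <- build_core_model(genotype = "LEU-28")
  b <- set_bounds(b, "ICL", 0, 1000)
  b <- set_bounds(b, "MALS", 0, 1000)
  b <- set_bounds(b, "ICDH", 0, 0.2 * 1000)
  b$annotations$genotype <- "LEU-29"
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("unknown genotype presets fail listing the known ones", {
  expect_error(build_core_model(genotype = "LEU-99"),
               "unknown genotype.*LEU-28")
})

test_that("bifido augmentation adds exactly the two FxpK reactions and
           is not idempotent", {
  m <- core_wt()
  m2 <- augment_with_bifido_shunt(m)
  expect_equal(length(m2$reactions), length(m$reactions) + 2L)
  expect_true(all(c("FXPK1", "FXPK2") %in% names(m2$reactions)))
  expect_equal(nrow(check_mass_balance(m2)), 0L)
  expect_error(augment_with_bifido_shunt(m2), "not idempotent")
})

test_that("pyc knockout increases the ppc flux in the growth-optimal
           geometric-FBA state", {
  cfg <- core_cfg()
  wt <- core_growth_gfba()
  ko <- geometric_fba(apply_config(knock_out(core_wt(), "PYC"), cfg),
                      cfg)
  expect_gt(unname(ko$fluxes["PPC"]),
            unname(wt$fluxes["PPC"]) + 1e-6)
})

test_that("acetate medium supports growth with the glyoxylate shunt
           open", {
  mac <- build_core_model(media = "acetate")
  f <- fba(mac)
  expect_gt(f$objective_value, 0)
  expect_gt(unname(f$fluxes["ICL"]), 0)
})

test_that("toy networks are reproducible from their seed and leave the
           global RNG untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  m1 <- build_toy_network("random", seed = 7, size = 8)
  m2 <- build_toy_network("random", seed = 7, size = 8)
  after <- runif(1)
  expect_identical(m1, m2)
  expect_identical(before, after)
  m3 <- build_toy_network("random", seed = 8, size = 8)
  expect_false(identical(m1, m3))
  expect_error(build_toy_network("random", size = 13), "capped")
})

test_that("every toy network validates, balances and has a positive
           optimum", {
  for (seed in 1:10) {
    m <- build_toy_network("random", seed = seed, size = 10)
    expect_true(validate_model(m))
    expect_equal(nrow(check_mass_balance(m)), 0L)
    expect_gt(fba(m)$objective_value, 0)
  }
})
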