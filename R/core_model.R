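#' Central-carbon core model of Corynebacterium glutamicum
#'
#' [build_core_model()] constructs a curated, elementally balanced
#' central-carbon network of C. glutamicum at reduced scale: glucose
#' uptake (PTS and permease/glucokinase), glycolysis and gluconeogenesis,
#' the oxidative and non-oxidative pentose phosphate pathway, pyruvate
#' dehydrogenase, the full TCA cycle, the glyoxylate shunt (present but
#' closed on glucose), pyc/ppc anaplerosis, malic enzyme, the ldh/alaT
#' pyruvate drains, the valine/leucine/alanine synthesis pathways,
#' acetate activation, lumped respiration, a lumped biomass pseudo
#' reaction and an ATP maintenance pseudo reaction. Elemental bookkeeping
#' covers carbon and nitrogen; carrier moieties (CoA, NAD(P), adenine
#' nucleotides, menaquinone) are treated as invariant and carry zero
#' counts.
#'
#' @name core-model
NULL

core_metabolites <- function() {
  M <- function(id, C = 0, N = 0, name = id, comp = "c") {
    f <- c(C = C, N = N)
    metabolite(id, name = name, compartment = comp, formula = f)
  }
  list(
    M("glc_e", 6, name = "D-glucose (extracellular)", comp = "e"),
    M("g6p", 6, name = "glucose 6-phosphate"),
    M("f6p", 6, name = "fructose 6-phosphate"),
    M("fdp", 6, name = "fructose 1,6-bisphosphate"),
    M("dhap", 3, name = "dihydroxyacetone phosphate"),
    M("g3p", 3, name = "glyceraldehyde 3-phosphate"),
    M("pep", 3, name = "phosphoenolpyruvate"),
    M("pyr", 3, name = "pyruvate"),
    M("pgc6", 6, name = "6-phosphogluconate"),
    M("ru5p", 5, name = "ribulose 5-phosphate"),
    M("r5p", 5, name = "ribose 5-phosphate"),
    M("x5p", 5, name = "xylulose 5-phosphate"),
    M("s7p", 7, name = "sedoheptulose 7-phosphate"),
    M("e4p", 4, name = "erythrose 4-phosphate"),
    M("accoa", 2, name = "acetyl-CoA (acetyl moiety)"),
    M("coa", 0, name = "coenzyme A"),
    M("acp", 2, name = "acetyl phosphate"),
    M("ac", 2, name = "acetate"),
    M("lac", 3, name = "L-lactate"),
    M("cit", 6, name = "citrate"),
    M("icit", 6, name = "isocitrate"),
    M("akg", 5, name = "2-oxoglutarate"),
    M("succoa", 4, name = "succinyl-CoA (succinyl moiety)"),
    M("succ", 4, name = "succinate"),
    M("fum", 4, name = "fumarate"),
    M("mal", 4, name = "L-malate"),
    M("oaa", 4, name = "oxaloacetate"),
    M("glx", 2, name = "glyoxylate"),
    M("glu", 5, 1, name = "L-glutamate"),
    M("ala", 3, 1, name = "L-alanine"),
    M("val", 5, 1, name = "L-valine"),
    M("leu", 6, 1, name = "L-leucine"),
    M("alac", 5, name = "2-acetolactate"),
    M("dhiv", 5, name = "2,3-dihydroxy-3-methylbutanoate"),
    M("kiv", 5, name = "2-oxoisovalerate"),
    M("ipm", 7, name = "2-isopropylmalate"),
    M("ipm2", 7, name = "3-isopropylmalate"),
    M("kic", 6, name = "2-oxoisocaproate"),
    M("nad"), M("nadh"), M("nadp"), M("nadph"),
    M("atp"), M("adp"), M("pi", name = "phosphate"),
    M("mq", name = "menaquinone"), M("mqh2", name = "menaquinol"),
    M("nh4", 0, 1, name = "ammonium"),
    M("co2", 1, name = "carbon dioxide"),
    M("o2", name = "dioxygen")
  )
}

core_reactions <- function(maintenance_atp = 0) {
  R <- function(id, s, lb = 0, ub = 1000, gene = NA, sub = NA, name = id,
                ex = FALSE, ps = FALSE)
    reaction(id, s, lb, ub, name = name, gene = gene, subsystem = sub,
             is_exchange = ex, is_pseudo = ps)
  rev <- -1000
  list(
    ## exchanges (uptake = negative flux)
    R("EX_glc", c(glc_e = -1), -4.67, 1000, sub = "exchange",
      name = "glucose exchange", ex = TRUE),
    R("EX_o2", c(o2 = -1), -1000, 1000, sub = "exchange",
      name = "oxygen exchange (uptake unrestricted)", ex = TRUE),
    R("EX_co2", c(co2 = -1), 0, 1000, sub = "exchange", ex = TRUE),
    R("EX_nh4", c(nh4 = -1), -1000, 1000, sub = "exchange", ex = TRUE),
    R("EX_pi", c(pi = -1), -1000, 1000, sub = "exchange", ex = TRUE),
    R("EX_ac", c(ac = -1), 0, 1000, sub = "exchange",
      name = "acetate exchange", ex = TRUE),
    R("EX_lac", c(lac = -1), 0, 1000, sub = "exchange", ex = TRUE),
    R("EX_ala", c(ala = -1), 0, 1000, sub = "exchange", ex = TRUE),
    R("EX_val", c(val = -1), 0, 1000, sub = "exchange", ex = TRUE),
    R("EX_leu", c(leu = -1), 0, 1000, sub = "exchange", ex = TRUE),
    R("EX_mal", c(mal = -1), 0, 1000, sub = "exchange", ex = TRUE),
    ## glucose uptake
    R("PTS", c(glc_e = -1, pep = -1, g6p = 1, pyr = 1), 0, 1000,
      gene = "ptsG", sub = "glucose uptake",
      name = "phosphotransferase system"),
    R("GLK", c(glc_e = -1, atp = -1, g6p = 1, adp = 1), 0, 1000,
      gene = "iolT1-glk", sub = "glucose uptake",
      name = "glucose permease + glucokinase"),
    ## glycolysis / gluconeogenesis
    R("PGI", c(g6p = -1, f6p = 1), rev, 1000, gene = "pgi",
      sub = "glycolysis"),
    R("PFK", c(f6p = -1, atp = -1, fdp = 1, adp = 1), 0, 1000,
      gene = "pfkA", sub = "glycolysis"),
    R("FBP", c(fdp = -1, f6p = 1, pi = 1), 0, 1000, gene = "fbp",
      sub = "gluconeogenesis", name = "fructose 1,6-bisphosphatase"),
    R("FBA", c(fdp = -1, dhap = 1, g3p = 1), rev, 1000, gene = "fda",
      sub = "glycolysis", name = "fructose-bisphosphate aldolase"),
    R("TPI", c(dhap = -1, g3p = 1), rev, 1000, gene = "tpi",
      sub = "glycolysis"),
    R("GAPD", c(g3p = -1, nad = -1, adp = -1, pi = -1,
                pep = 1, nadh = 1, atp = 1), rev, 1000, gene = "gapA",
      sub = "glycolysis",
      name = "lower glycolysis, lumped GAPDH-PGK-PGM-ENO"),
    R("PYK", c(pep = -1, adp = -1, pyr = 1, atp = 1), 0, 1000,
      gene = "pyk", sub = "glycolysis", name = "pyruvate kinase"),
    ## pentose phosphate pathway
    R("ZWF", c(g6p = -1, nadp = -1, pgc6 = 1, nadph = 1), 0, 1000,
      gene = "zwf", sub = "PPP",
      name = "G6P dehydrogenase + lactonase, lumped"),
    R("GND", c(pgc6 = -1, nadp = -1, ru5p = 1, co2 = 1, nadph = 1),
      0, 1000, gene = "gnd", sub = "PPP",
      name = "6-phosphogluconate dehydrogenase"),
    R("RPE", c(ru5p = -1, x5p = 1), rev, 1000, gene = "rpe", sub = "PPP"),
    R("RPI", c(ru5p = -1, r5p = 1), rev, 1000, gene = "rpi", sub = "PPP"),
    R("TKT1", c(x5p = -1, r5p = -1, g3p = 1, s7p = 1), rev, 1000,
      gene = "tkt", sub = "PPP", name = "transketolase 1"),
    R("TAL", c(g3p = -1, s7p = -1, e4p = 1, f6p = 1), rev, 1000,
      gene = "tal", sub = "PPP", name = "transaldolase"),
    R("TKT2", c(x5p = -1, e4p = -1, g3p = 1, f6p = 1), rev, 1000,
      gene = "tkt", sub = "PPP", name = "transketolase 2"),
    ## pyruvate node
    R("PDH", c(pyr = -1, coa = -1, nad = -1, accoa = 1, co2 = 1,
               nadh = 1), 0, 1000, gene = "aceE",
      sub = "pyruvate metabolism", name = "pyruvate dehydrogenase complex"),
    R("PYC", c(pyr = -1, co2 = -1, atp = -1, oaa = 1, adp = 1, pi = 1),
      0, 1000, gene = "pyc", sub = "anaplerosis",
      name = "pyruvate carboxylase"),
    R("PPC", c(pep = -1, co2 = -1, oaa = 1, pi = 1), 0, 1000,
      gene = "ppc", sub = "anaplerosis", name = "PEP carboxylase"),
    R("PCK", c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1), 0, 1000,
      gene = "pck", sub = "gluconeogenesis", name = "PEP carboxykinase"),
    R("MALE", c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
      0, 1000, gene = "malE", sub = "pyruvate metabolism",
      name = "malic enzyme (NADP)"),
    R("LDH", c(pyr = -1, nadh = -1, lac = 1, nad = 1), 0, 1000,
      gene = "ldhA", sub = "fermentation", name = "lactate dehydrogenase"),
    R("LLD", c(lac = -1, mq = -1, pyr = 1, mqh2 = 1), 0, 1000,
      gene = "lldD", sub = "fermentation",
      name = "quinone-dependent L-lactate dehydrogenase"),
    ## TCA cycle
    R("CS", c(accoa = -1, oaa = -1, cit = 1, coa = 1), 0, 1000,
      gene = "gltA", sub = "TCA", name = "citrate synthase"),
    R("ACONT", c(cit = -1, icit = 1), rev, 1000, gene = "acn",
      sub = "TCA", name = "aconitase"),
    R("ICDH", c(icit = -1, nadp = -1, akg = 1, co2 = 1, nadph = 1),
      0, 1000, gene = "icd", sub = "TCA",
      name = "isocitrate dehydrogenase (NADP)"),
    R("AKGDH", c(akg = -1, coa = -1, nad = -1, succoa = 1, co2 = 1,
                 nadh = 1), 0, 1000, gene = "odhA", sub = "TCA",
      name = "2-oxoglutarate dehydrogenase"),
    R("SUCOAS", c(succoa = -1, adp = -1, pi = -1, succ = 1, coa = 1,
                  atp = 1), rev, 1000, gene = "sucCD", sub = "TCA",
      name = "succinyl-CoA synthetase"),
    R("SUCDH", c(succ = -1, mq = -1, fum = 1, mqh2 = 1), 0, 1000,
      gene = "sdh", sub = "TCA", name = "succinate dehydrogenase"),
    R("FUM", c(fum = -1, mal = 1), rev, 1000, gene = "fum", sub = "TCA",
      name = "fumarase"),
    R("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), rev, 1000,
      gene = "mdh", sub = "TCA", name = "malate dehydrogenase"),
    ## glyoxylate shunt: present but closed for glucose-grown wild type
    R("ICL", c(icit = -1, succ = 1, glx = 1), 0, 0, gene = "aceA",
      sub = "glyoxylate shunt", name = "isocitrate lyase"),
    R("MALS", c(accoa = -1, glx = -1, mal = 1, coa = 1), 0, 0,
      gene = "aceB", sub = "glyoxylate shunt", name = "malate synthase"),
    ## nitrogen assimilation
    R("GDH", c(akg = -1, nh4 = -1, nadph = -1, glu = 1, nadp = 1),
      0, 1000, gene = "gdh", sub = "nitrogen metabolism",
      name = "glutamate dehydrogenase (NADPH)"),
    ## alanine drains
    R("ALATA", c(pyr = -1, glu = -1, ala = 1, akg = 1), rev, 1000,
      gene = "alaT", sub = "amino acid synthesis",
      name = "alanine transaminase"),
    R("ALADH", c(pyr = -1, nh4 = -1, nadh = -1, ala = 1, nad = 1),
      0, 1000, gene = "alaD", sub = "amino acid synthesis",
      name = "alanine dehydrogenase"),
    ## valine / leucine pathway
    R("ACLS", c(pyr = -2, alac = 1, co2 = 1), 0, 1000, gene = "ilvBN",
      sub = "amino acid synthesis", name = "acetolactate synthase"),
    R("KARA", c(alac = -1, nadph = -1, dhiv = 1, nadp = 1), 0, 1000,
      gene = "ilvC", sub = "amino acid synthesis",
      name = "ketol-acid reductoisomerase"),
    R("DHAD", c(dhiv = -1, kiv = 1), 0, 1000, gene = "ilvD",
      sub = "amino acid synthesis", name = "dihydroxy-acid dehydratase"),
    R("VALTA", c(kiv = -1, glu = -1, val = 1, akg = 1), rev, 1000,
      gene = "ilvE", sub = "amino acid synthesis",
      name = "valine transaminase"),
    R("IPPS", c(kiv = -1, accoa = -1, ipm = 1, coa = 1), 0, 1000,
      gene = "leuA", sub = "amino acid synthesis",
      name = "2-isopropylmalate synthase"),
    R("IPMI", c(ipm = -1, ipm2 = 1), rev, 1000, gene = "leuCD",
      sub = "amino acid synthesis", name = "isopropylmalate isomerase"),
    R("IPMD", c(ipm2 = -1, nad = -1, kic = 1, co2 = 1, nadh = 1),
      0, 1000, gene = "leuB", sub = "amino acid synthesis",
      name = "3-isopropylmalate dehydrogenase"),
    R("LEUTA", c(kic = -1, glu = -1, leu = 1, akg = 1), rev, 1000,
      gene = "ilvE", sub = "amino acid synthesis",
      name = "leucine transaminase"),
    ## acetate activation / overflow
    R("PTA", c(accoa = -1, pi = -1, acp = 1, coa = 1), rev, 1000,
      gene = "pta", sub = "acetate metabolism",
      name = "phosphate acetyltransferase"),
    R("ACK", c(acp = -1, adp = -1, ac = 1, atp = 1), rev, 1000,
      gene = "ackA", sub = "acetate metabolism", name = "acetate kinase"),
    ## lumped respiration
    R("NADHDH", c(nadh = -1, o2 = -0.5, adp = -2, pi = -2, nad = 1,
                  atp = 2), 0, 1000, gene = "ndh",
      sub = "oxidative phosphorylation",
      name = "NADH oxidation, lumped (P/O = 2)"),
    R("MQOX", c(mqh2 = -1, o2 = -0.5, adp = -1, pi = -1, mq = 1,
                atp = 1), 0, 1000, gene = "ctaD",
      sub = "oxidative phosphorylation",
      name = "menaquinol oxidation, lumped (P/O = 1)"),
    ## pseudo reactions
    R("ATPM", c(atp = -1, adp = 1, pi = 1), maintenance_atp, 1000,
      sub = "maintenance", name = "ATP maintenance demand", ps = TRUE),
    R("BIOMASS",
      c(g6p = -0.3, r5p = -0.2, e4p = -0.1, pep = -0.6, pyr = -1.5,
        accoa = -1.2, oaa = -0.9, glu = -1.2, ala = -0.3, atp = -40,
        nadph = -6, coa = 1.2, adp = 40, pi = 40, nadp = 6),
      0, 1000, sub = "biomass",
      name = "lumped biomass precursor demand", ps = TRUE)
  )
}

#' Build the C. glutamicum central-carbon core model
#'
#' @param include_glyoxylate_shunt keep the glyoxylate-shunt reactions in
#'   the network (default `TRUE`). They ship with closed bounds (0, 0) on
#'   glucose medium, reflecting their repression in glucose-grown
#'   C. glutamicum; genotype or media presets open them.
#' @param include_bifido_shunt add the phosphoketolase (FxpK) reactions via
#'   [augment_with_bifido_shunt()] (default `FALSE`).
#' @param maintenance_atp lower bound of the ATP maintenance demand,
#'   mmol/gCDW/h. Default 0 (the stoichiometric-ceiling yield mode); 2.0
#'   is a reasonable growth-mode convention.
#' @param genotype optional genotype preset name, see [genotype_presets()].
#' @param media `"glucose"` (uptake capped at 4.67 mmol/gCDW/h) or
#'   `"acetate"` (glucose closed, acetate uptake 1 mmol/gCDW/h, glyoxylate
#'   shunt open, as required for growth on acetate).
#' @return a validated `metabolic_model` with biomass maximisation as the
#'   default objective; [check_mass_balance()] is empty by construction.
#' @export
build_core_model <- function(include_glyoxylate_shunt = TRUE,
                             include_bifido_shunt = FALSE,
                             maintenance_atp = 0,
                             genotype = NULL,
                             media = c("glucose", "acetate")) {
  media <- match.arg(media)
  if (maintenance_atp < 0) stop("maintenance_atp must be non-negative")
  rxns <- core_reactions(maintenance_atp)
  if (!include_glyoxylate_shunt) {
    keep <- !vapply(rxns, function(r) r$id %in% c("ICL", "MALS"),
                    logical(1))
    rxns <- rxns[keep]
  }
  model <- metabolic_model(
    id = "cg_core",
    metabolites = core_metabolites(),
    reactions = rxns,
    objective = list(reaction = "BIOMASS", sense = "max"),
    annotations = list(
      organism = "Corynebacterium glutamicum",
      description = "central-carbon core model",
      media = media,
      maintenance_atp = maintenance_atp))
  if (media == "acetate") {
    model <- set_bounds(model, "EX_glc", lower_bound = 0)
    model <- set_bounds(model, "EX_ac", lower_bound = -1)
    if (include_glyoxylate_shunt) {
      model <- set_bounds(model, "ICL", 0, 1000)
      model <- set_bounds(model, "MALS", 0, 1000)
    }
  }
  if (!is.null(genotype)) model <- apply_genotype(model, genotype)
  if (include_bifido_shunt) model <- augment_with_bifido_shunt(model)
  model
}

#' Genotype presets for the core model
#'
#' Each preset carries reaction knockouts, multiplicative bound scalings
#' (an attenuated enzyme keeps its direction but loses capacity) and
#' explicit bound overrides (used to open the glyoxylate shunt).
#'
#' * `WT` — wild type, no modification.
#' * `dpyc` — pyruvate carboxylase deletion.
#' * `dppc` — PEP carboxylase deletion.
#' * `LEU-28` — both C4 anaplerotic routes deleted (pyc, ppc); the
#'   glyoxylate shunt stays closed. Aerobic growth on glucose is abolished.
#' * `LEU-29` — LEU-28 background plus the evolved icd R543S allele
#'   (isocitrate dehydrogenase capacity scaled to 0.2, an ~80% activity
#'   loss) with the glyoxylate shunt open; growth on glucose is restored
#'   through glyoxylate-derived C4 replenishment.
#'
#' @return named list of `genotype_preset` objects.
#' @export
genotype_presets <- function() {
  P <- function(name, knockouts = character(), bound_scalings = numeric(),
                bound_overrides = list(), notes = "") {
    structure(list(name = name, knockouts = knockouts,
                   bound_scalings = bound_scalings,
                   bound_overrides = bound_overrides, notes = notes),
              class = "genotype_preset")
  }
  list(
    "WT" = P("WT", notes = "wild type"),
    "dpyc" = P("dpyc", knockouts = "PYC",
               notes = "pyruvate carboxylase deletion"),
    "dppc" = P("dppc", knockouts = "PPC",
               notes = "PEP carboxylase deletion"),
    "LEU-28" = P("LEU-28", knockouts = c("PYC", "PPC"),
                 notes = paste("both C4 anaplerotic pathways blocked;",
                               "no aerobic growth on glucose")),
    "LEU-29" = P("LEU-29", knockouts = c("PYC", "PPC"),
                 bound_scalings = c(ICDH = 0.2),
                 bound_overrides = list(ICL = c(0, 1000),
                                        MALS = c(0, 1000)),
                 notes = paste("LEU-28 + icd R543S (~80% IDH activity",
                               "loss) with active glyoxylate shunt"))
  )
}

#' Apply a genotype preset to a model
#'
#' @param model a `metabolic_model`.
#' @param genotype a preset name (see [genotype_presets()]) or a
#'   `genotype_preset` object.
#' @return the modified model. Knockouts are applied first, then bound
#'   overrides, then bound scalings.
#' @export
apply_genotype <- function(model, genotype) {
  if (is.character(genotype)) {
    presets <- genotype_presets()
    if (!genotype %in% names(presets))
      stop("unknown genotype preset '", genotype, "'; known presets: ",
           paste(names(presets), collapse = ", "))
    genotype <- presets[[genotype]]
  }
  stopifnot(inherits(genotype, "genotype_preset"))
  if (any(genotype$bound_scalings < 0) || any(genotype$bound_scalings > 1))
    stop("bound scaling factors must lie in [0,1]")
  if (length(genotype$knockouts))
    model <- knock_out(model, genotype$knockouts)
  for (id in names(genotype$bound_overrides)) {
    bo <- genotype$bound_overrides[[id]]
    model <- set_bounds(model, id, bo[1], bo[2])
  }
  for (id in names(genotype$bound_scalings)) {
    f <- genotype$bound_scalings[[id]]
    r <- model$reactions[[id]]
    if (is.null(r)) stop("bound scaling targets unknown reaction ", id)
    model <- set_bounds(model, id, r$lower_bound * f, r$upper_bound * f)
  }
  model$annotations$genotype <- genotype$name
  model
}

#' Add the phosphoketolase (bifido shunt) reactions
#'
#' Adds the two reactions of the bifunctional phosphoketolase FxpK —
#' F6P + Pi -> E4P + AcP and X5P + Pi -> G3P + AcP, both irreversible —
#' and verifies that phosphate acetyltransferase (pta) is present to link
#' acetyl phosphate to acetyl-CoA. Together with the non-oxidative PPP
#' rearrangements and fructose bisphosphatase this permits three
#' acetyl-CoA per glucose with no carbon loss.
#'
#' @param model a `metabolic_model` without FxpK reactions.
#' @return the augmented model (exactly two reactions more).
#' @export
augment_with_bifido_shunt <- function(model) {
  if (any(c("FXPK1", "FXPK2") %in% names(model$reactions)))
    stop("model already carries the bifido-shunt (FxpK) reactions; ",
         "augmentation is not idempotent by design")
  if (!"PTA" %in% names(model$reactions))
    stop("bifido-shunt augmentation requires the pta reaction (AcP <-> ",
         "acetyl-CoA link)")
  fx1 <- reaction("FXPK1", c(f6p = -1, pi = -1, e4p = 1, acp = 1),
                  0, 1000, name = "phosphoketolase (F6P)", gene = "fxpK",
                  subsystem = "bifido shunt")
  fx2 <- reaction("FXPK2", c(x5p = -1, pi = -1, g3p = 1, acp = 1),
                  0, 1000, name = "phosphoketolase (X5P)", gene = "fxpK",
                  subsystem = "bifido shunt")
  model$reactions <- c(model$reactions, list(FXPK1 = fx1, FXPK2 = fx2))
  validate_model(model)
  model$annotations$bifido_shunt <- TRUE
  model
}

#' Toy networks for solver validation
#'
#' * `chain` — uptake (cap 10) -> A -> B -> export; unique optimum 10 with
#'   every flux 10.
#' * `diamond` — uptake (cap 10) feeding two parallel A -> B branches of
#'   capacity 10 each; the optimum is 10, each branch interval is (0, 10)
#'   and geometric FBA splits them 5/5.
#' * `random` — a reproducible random connected network built on a linear
#'   backbone (guaranteeing a positive optimum) with extra random internal
#'   edges, for property tests against brute-force LP oracles.
#'
#' @param kind `"chain"`, `"diamond"` or `"random"`.
#' @param seed integer seed (random kind only; the global RNG state is
#'   preserved).
#' @param size total number of internal reactions for the random kind
#'   (at most 12).
#' @return a `metabolic_model`.
#' @export
build_toy_network <- function(kind = c("chain", "diamond", "random"),
                              seed = 1L, size = 6L) {
  kind <- match.arg(kind)
  M <- function(id) metabolite(id, formula = c(C = 1))
  if (kind == "chain") {
    return(metabolic_model(
      "toy_chain", list(M("A"), M("B")),
      list(reaction("SRC", c(A = 1), 0, 10, is_exchange = TRUE),
           reaction("CONV", c(A = -1, B = 1), 0, 1000),
           reaction("SNK", c(B = -1), 0, 1000, is_exchange = TRUE)),
      objective = "SNK"))
  }
  if (kind == "diamond") {
    return(metabolic_model(
      "toy_diamond", list(M("A"), M("B")),
      list(reaction("SRC", c(A = 1), 0, 10, is_exchange = TRUE),
           reaction("BR1", c(A = -1, B = 1), 0, 10),
           reaction("BR2", c(A = -1, B = 1), 0, 10),
           reaction("SNK", c(B = -1), 0, 1000, is_exchange = TRUE)),
      objective = "SNK"))
  }
  if (size > 12) stop("random toy networks are capped at size 12")
  if (size < 2) stop("random toy networks need size >= 2")
  ## localise the RNG so model generation never disturbs the caller's seed
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  nmet <- max(2L, min(size - 1L, 6L))
  mids <- paste0("M", seq_len(nmet))
  mets <- lapply(mids, M)
  rxns <- list(reaction("SRC", structure(1, names = mids[1]), 0, 10,
                        is_exchange = TRUE))
  ## backbone guarantees a feasible positive optimum
  for (i in seq_len(nmet - 1L)) {
    s <- structure(c(-1, 1), names = c(mids[i], mids[i + 1]))
    rxns <- c(rxns, list(reaction(paste0("B", i), s, 0, 1000)))
  }
  nextra <- max(0L, size - (nmet - 1L))
  for (k in seq_len(nextra)) {
    ij <- sort(sample.int(nmet, 2L))
    s <- structure(c(-1, 1), names = mids[ij])
    lb <- if (stats::runif(1) < 0.4) -1000 else 0
    ub <- sample(c(5, 10, 1000), 1L)
    rxns <- c(rxns, list(reaction(paste0("X", k), s, lb, ub)))
  }
  rxns <- c(rxns, list(reaction("SNK", structure(-1, names = mids[nmet]),
                                0, 1000, is_exchange = TRUE)))
  metabolic_model(paste0("toy_random_", seed), mets, rxns,
                  objective = "SNK")
}
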