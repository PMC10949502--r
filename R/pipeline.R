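#' Declarative analysis pipeline
#'
#' [run_pipeline()] wires the package's stages — model construction or
#' loading, genotype application, bifido-shunt augmentation, FBA,
#' geometric FBA, FVA, essentiality classification, regulation
#' recommendation, theoretical yields, the attenuation sweep and sRNA
#' design — into one reproducible run driven by a single YAML
#' configuration file. Every stage writes its artifact (TSV/JSON/FASTA)
#' into the output directory, and a manifest records the configuration
#' snapshot, input digests, package version and per-stage status.
#' Outputs are byte-identical across repeated runs on the same inputs.
#'
#' @section Configuration keys:
#' \preformatted{
#' model:
#'   source: core            # or "file"
#'   path: model.json        # when source = file
#'   options:                # when source = core; build_core_model() args
#'     media: glucose
#'     maintenance_atp: 0
#' genotype: LEU-28          # optional preset name
#' bifido: false             # augment with the FxpK reactions
#' config:                   # sim_config() arguments
#'   substrate_uptake_max: 4.67
#'   biomass_fraction: 0.2
#' product_exchange: EX_leu
#' stages: [fba, gfba, fva, classify, recommend, yield, sweep]
#' sweep_target: ACONT
#' yield_products: [EX_ala, EX_val, EX_leu]
#' srna:                     # used by the design-srna stage
#'   target_id: gltA
#'   cds: ATG...             # or cds_fasta: path
#'   window: [1, 24]
#'   scaffold: MicC
#' seed: 1
#' output_dir: out
#' }
#'
#' @param config_path path to the YAML configuration.
#' @param output_dir overrides the configuration's `output_dir`.
#' @param quiet suppress progress messages.
#' @return invisibly the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config_path, output_dir = NULL, quiet = FALSE) {
  if (!file.exists(config_path))
    stop("pipeline configuration not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  out_dir <- output_dir %||% cfg$output_dir %||% "cgflux_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cgflux] ", ...)

  manifest <- list(
    tool = "cgflux",
    version = as.character(utils::packageVersion("cgflux")),
    config_path = normalizePath(config_path),
    config_digest = unname(tools::md5sum(config_path)),
    config = cfg,
    seed = cfg$seed %||% 1L,
    ## no timestamps: repeated runs must produce byte-identical artifacts
    stages = list())
  note_stage <- function(name, status, artifact = NULL,
                         message = NULL) {
    manifest$stages[[name]] <<- list(status = status,
                                     artifact = artifact,
                                     message = message)
  }
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) { note_stage(name, "skipped"); return(invisible(NULL)) }
    say("stage ", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note_stage(name, "error", message = conditionMessage(res))
      failed <<- TRUE
      invisible(NULL)
    } else res
  }

  ## -- model stage ---------------------------------------------------------
  model <- run_stage("model", function() {
    src <- cfg$model$source %||% "core"
    m <- if (identical(src, "core")) {
      opts <- cfg$model$options %||% list()
      do.call(build_core_model, opts)
    } else {
      manifest$input_digest <<- unname(tools::md5sum(cfg$model$path))
      load_model(cfg$model$path, cfg$model$format %||% "auto")
    }
    if (!is.null(cfg$genotype)) m <- apply_genotype(m, cfg$genotype)
    if (isTRUE(cfg$bifido)) m <- augment_with_bifido_shunt(m)
    p <- file.path(out_dir, "model.json")
    write_model(m, p, "json")
    note_stage("model", "ok", "model.json")
    m
  })
  if (failed) return(finish_manifest(manifest, out_dir))

  simcfg <- do.call(sim_config, cfg$config %||% list())
  product <- cfg$product_exchange %||% NULL
  stages <- cfg$stages %||% c("fba", "gfba", "fva", "classify",
                              "recommend", "yield")

  growth_fit <- NULL
  prod_fit <- NULL
  ess <- NULL

  if ("fba" %in% stages) run_stage("fba", function() {
    fit <- fba(model, simcfg)
    p <- file.path(out_dir, "fba_fluxes.json")
    write_fluxes_json(fit, p)
    note_stage("fba", "ok", "fba_fluxes.json")
    fit
  })
  if ("gfba" %in% stages) growth_fit <- run_stage("gfba", function() {
    fit <- geometric_fba(apply_config(model, simcfg), simcfg)
    p <- file.path(out_dir, "gfba_fluxes.json")
    write_fluxes_json(fit, p)
    note_stage("gfba", "ok", "gfba_fluxes.json")
    fit
  })
  if ("fva" %in% stages) run_stage("fva", function() {
    iv <- fva(model, simcfg, objective_fraction = 1.0)
    p <- file.path(out_dir, "fva.tsv")
    df <- data.frame(reaction_id = iv$reaction_id, min = fmt12(iv$min),
                     max = fmt12(iv$max))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    note_stage("fva", "ok", "fva.tsv")
    iv
  })
  if ("classify" %in% stages) ess <- run_stage("classify", function() {
    e <- essentiality_analysis(model, simcfg, product)
    p <- file.path(out_dir, "classification.tsv")
    write_essentiality_tsv(e, p)
    note_stage("classify", "ok", "classification.tsv")
    e
  })
  if ("recommend" %in% stages) run_stage("recommend", function() {
    if (is.null(ess)) stop("recommend requires the classify stage")
    gfit <- growth_fit %||% geometric_fba(apply_config(model, simcfg),
                                          simcfg)
    pfit <- simulate_production(model, simcfg, product)
    rec <- recommend_regulation(gfit, pfit, ess,
                                simcfg$classification_tolerance)
    p <- file.path(out_dir, "recommendation.tsv")
    df <- rec
    df$growth_flux <- fmt12(df$growth_flux)
    df$production_flux <- fmt12(df$production_flux)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    note_stage("recommend", "ok", "recommendation.tsv")
    rec
  })
  if ("yield" %in% stages) run_stage("yield", function() {
    prods <- cfg$yield_products %||% product
    if (is.null(prods)) stop("yield stage needs yield_products or ",
                             "product_exchange")
    arts <- character()
    for (pr in prods) {
      y <- max_theoretical_yield(model, simcfg, pr)
      a <- paste0("yield_", pr, ".json")
      write_yield_json(y, file.path(out_dir, a))
      arts <- c(arts, a)
    }
    if (isTRUE(cfg$compare_bifido)) {
      maug <- if ("FXPK1" %in% names(model$reactions)) model else
        augment_with_bifido_shunt(model)
      for (pr in prods) {
        y <- max_theoretical_yield(maug, simcfg, pr)
        a <- paste0("yield_", pr, "_bifido.json")
        write_yield_json(y, file.path(out_dir, a))
        arts <- c(arts, a)
      }
    }
    note_stage("yield", "ok", arts)
  })
  if ("sweep" %in% stages) run_stage("sweep", function() {
    if (is.null(cfg$sweep_target)) stop("sweep stage needs sweep_target")
    sw <- sweep_relative_flux(model, simcfg, cfg$sweep_target, product)
    p <- file.path(out_dir, "sweep.tsv")
    write_sweep_tsv(sw, p)
    note_stage("sweep", "ok", "sweep.tsv")
    sw
  })
  if ("design-srna" %in% stages) run_stage("design-srna", function() {
    sc <- cfg$srna
    if (is.null(sc)) stop("design-srna stage needs an srna block")
    cds <- if (!is.null(sc$cds)) sc$cds else {
      rec <- read_fasta_first(sc$cds_fasta)
      rec$seq
    }
    win <- if (is.null(sc$window)) target_window() else
      target_window(sc$window[[1]], sc$window[[2]])
    binding <- design_binding_sequence(cds, sc$start_index %||% 1L, win)
    d <- assemble_srna(binding, sc$scaffold %||% "MicC",
                       scaffold_fasta = sc$scaffold_fasta,
                       terminator_fasta = sc$terminator_fasta,
                       target_id = sc$target_id %||% NA_character_)
    write_srna_fasta(d, file.path(out_dir, "srna.fasta"))
    write_srna_report_tsv(d, file.path(out_dir, "srna_report.tsv"))
    note_stage("design-srna", "ok", c("srna.fasta", "srna_report.tsv"))
    d
  })
  finish_manifest(manifest, out_dir)
}

write_fluxes_json <- function(fit, path) {
  obj <- list(model_id = fit$model_id,
              objective = fit$objective,
              status = fit$status,
              objective_value = fit$objective_value,
              fluxes = as.list(fit$fluxes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

finish_manifest <- function(manifest, out_dir) {
  statuses <- vapply(manifest$stages, `[[`, "", "status")
  manifest$ok <- !any(statuses == "error")
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
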