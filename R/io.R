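#' Model readers and writers
#'
#' Three exchange dialects are supported:
#' \describe{
#'   \item{json}{the package's native dialect: a single object with `id`,
#'     `metabolites`, `reactions`, `objective` and `annotations`, numbers
#'     at full precision, fixed key order (bit-stable output).}
#'   \item{sbml}{SBML Level 3 Version 1 with the FBC version 2 package:
#'     flux bounds as parameters, the objective as an FBC objective,
#'     elemental formulas as `fbc:chemicalFormula`. Gene, subsystem and
#'     the exchange/pseudo flags travel in reaction notes; model
#'     annotations travel as a JSON payload in the model notes.}
#'   \item{tsv}{a flat reaction table (columns `id`, `name`, `equation`,
#'     `lower_bound`, `upper_bound`, `gene`, `subsystem`, `is_exchange`,
#'     `is_pseudo`) with a `*_metabolites.tsv` sidecar species table and
#'     `#!` header lines carrying the model id and objective. Equations
#'     use `"a A + b B -> c C"` (or `<=>` when the lower bound is
#'     negative).}
#' }
#' All files are UTF-8; numbers round-trip to 12 significant digits or
#' better.
#'
#' @name model-io
NULL

#' Load a metabolic model from file
#'
#' @param path input file.
#' @param format `"json"`, `"sbml"` or `"tsv"` (default: guessed from the
#'   file extension).
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", xml = "sbml", sbml = "sbml",
                     tsv = "tsv",
                     stop("cannot guess model format from extension of ",
                          path))
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         json = read_model_json(path),
         sbml = read_model_sbml(path),
         tsv = read_model_tsv(path))
}

#' Write a metabolic model to file
#'
#' @param model a validated `metabolic_model`.
#' @param path output file.
#' @param format `"json"`, `"sbml"` or `"tsv"` (default: guessed from the
#'   file extension). The TSV writer also emits a `*_metabolites.tsv`
#'   sidecar next to `path`.
#' @return invisibly `path`.
#' @export
write_model <- function(model, path,
                        format = c("auto", "json", "sbml", "tsv")) {
  validate_model(model)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", xml = "sbml", sbml = "sbml",
                     tsv = "tsv",
                     stop("cannot guess model format from extension of ",
                          path))
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         tsv = write_model_tsv(model, path))
  invisible(path)
}

## ---------------------------------------------------------------------------
## JSON dialect
## ---------------------------------------------------------------------------
write_model_json <- function(model, path) {
  mets <- lapply(model$metabolites, function(m) {
    f <- if (is.null(m$formula)) NULL else as.list(m$formula)
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = f)
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene = if (is.na(r$gene)) NULL else r$gene,
         subsystem = if (is.na(r$subsystem)) NULL else r$subsystem,
         is_exchange = r$is_exchange, is_pseudo = r$is_pseudo)
  })
  obj <- list(id = model$id,
              metabolites = unname(mets),
              reactions = unname(rxns),
              objective = model$objective,
              annotations = model$annotations)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
}

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("not parseable as model JSON: ", path, " (",
                         conditionMessage(e), ")"))
  need <- c("id", "metabolites", "reactions", "objective")
  if (!all(need %in% names(obj)))
    stop("model JSON lacks required field(s): ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  mets <- lapply(obj$metabolites, function(m)
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "c",
               if (is.null(m$formula)) NULL else unlist(m$formula)))
  rxns <- lapply(obj$reactions, function(r)
    reaction(r$id, unlist(r$stoichiometry),
             r$lower_bound, r$upper_bound, name = r$name %||% r$id,
             gene = r$gene %||% NA_character_,
             subsystem = r$subsystem %||% NA_character_,
             is_exchange = isTRUE(r$is_exchange),
             is_pseudo = isTRUE(r$is_pseudo)))
  metabolic_model(obj$id, mets, rxns,
                  objective = list(reaction = obj$objective$reaction,
                                   sense = obj$objective$sense),
                  annotations = obj$annotations %||% list())
}

## ---------------------------------------------------------------------------
## SBML Level 3 + FBC v2
## ---------------------------------------------------------------------------
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

formula_string <- function(f) {
  if (is.null(f)) return(NULL)
  paste0(vapply(seq_along(f), function(i)
    paste0(names(f)[i], sprintf("%g", f[[i]])), ""), collapse = "")
}

parse_formula_string <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  stats::setNames(ct, el)
}

num12 <- function(x) sprintf("%.12g", x)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")
  if (length(model$annotations)) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(
      body, "p",
      paste0("annotations: ",
             jsonlite::toJSON(model$annotations, auto_unbox = TRUE,
                              digits = NA)))
  }
  comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", m$id),
                              name = m$name, compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    fs <- formula_string(m$formula)
    if (!is.null(fs)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", fs)
  }
  ## one parameter per distinct bound value
  bvals <- sort(unique(c(
    vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
    vapply(model$reactions, `[[`, numeric(1), "upper_bound"))))
  bid <- stats::setNames(paste0("bnd_", seq_along(bvals)), num12(bvals))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bvals))
    xml2::xml_add_child(lp, "parameter", id = bid[[i]],
                        value = num12(bvals[i]), constant = "true")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid[[num12(r$lower_bound)]],
      "fbc:upperFluxBound" = bid[[num12(r$upper_bound)]])
    meta <- c(
      if (!is.na(r$gene)) paste0("GENE_ASSOCIATION: ", r$gene),
      if (!is.na(r$subsystem)) paste0("SUBSYSTEM: ", r$subsystem),
      if (r$is_exchange) "EXCHANGE: true",
      if (r$is_pseudo) "PSEUDO: true")
    if (length(meta)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      for (line in meta) xml2::xml_add_child(body, "p", line)
    }
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in seq_along(reac))
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", names(reac)[i]),
                            stoichiometry = num12(-reac[[i]]),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in seq_along(prod))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", names(prod)[i]),
                            stoichiometry = num12(prod[[i]]),
                            constant = "true")
    }
  }
  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = if (model$objective$sense == "max")
                              "maximize" else "minimize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_",
                                              model$objective$reaction),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("not parseable as SBML: ", path, " (",
                         conditionMessage(e), ")"))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  notes_lines <- function(node) {
    ps <- xml2::xml_find_all(node, "./s:notes//*[local-name()='p']", ns)
    xml2::xml_text(ps)
  }
  ## annotations from model notes
  annotations <- list()
  for (line in notes_lines(mdl)) {
    if (startsWith(line, "annotations: "))
      annotations <- jsonlite::fromJSON(sub("^annotations: ", "", line),
                                        simplifyVector = TRUE)
  }
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter",
                               ns)
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(sp, function(x) {
    metabolite(strip(xml2::xml_attr(x, "id"), "M_"),
               name = xml2::xml_attr(x, "name"),
               compartment = xml2::xml_attr(x, "compartment"),
               formula = parse_formula_string(
                 xml2::xml_attr(x, "chemicalFormula")))
  })
  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(x) {
    id <- strip(xml2::xml_attr(x, "id"), "R_")
    sref <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(x, xpath, ns)
      if (!length(nodes)) return(numeric())
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
        strip(xml2::xml_attr(nodes, "species"), "M_"))
    }
    stoich <- c(sref("./s:listOfReactants/s:speciesReference", -1),
                sref("./s:listOfProducts/s:speciesReference", 1))
    lines <- notes_lines(x)
    pick <- function(key) {
      hit <- lines[startsWith(lines, paste0(key, ": "))]
      if (length(hit)) sub(paste0("^", key, ": "), "", hit[1])
      else NA_character_
    }
    reaction(id, stoich,
             lower_bound = pval[[xml2::xml_attr(x, "lowerFluxBound")]],
             upper_bound = pval[[xml2::xml_attr(x, "upperFluxBound")]],
             name = xml2::xml_attr(x, "name"),
             gene = pick("GENE_ASSOCIATION"),
             subsystem = pick("SUBSYSTEM"),
             is_exchange = identical(pick("EXCHANGE"), "true"),
             is_pseudo = identical(pick("PSEUDO"), "true"))
  })
  obj_node <- xml2::xml_find_first(doc, ".//fbc:objective", ns)
  if (inherits(obj_node, "xml_missing"))
    stop("SBML file carries no FBC objective: ", path)
  fo <- xml2::xml_find_first(obj_node, ".//fbc:fluxObjective", ns)
  metabolic_model(
    xml2::xml_attr(mdl, "id"), mets, rxns,
    objective = list(
      reaction = strip(xml2::xml_attr(fo, "reaction"), "R_"),
      sense = if (identical(xml2::xml_attr(obj_node, "type"),
                            "maximize")) "max" else "min"),
    annotations = as.list(annotations))
}

## ---------------------------------------------------------------------------
## TSV reaction table (+ metabolite sidecar)
## ---------------------------------------------------------------------------
equation_string <- function(r) {
  side <- function(s) {
    if (!length(s)) return("")
    paste(vapply(seq_along(s), function(i) {
      cf <- abs(s[[i]])
      if (cf == 1) names(s)[i] else paste(sprintf("%.12g", cf),
                                          names(s)[i])
    }, ""), collapse = " + ")
  }
  arrow <- if (r$lower_bound < 0) "<=>" else "->"
  lhs <- side(r$stoichiometry[r$stoichiometry < 0])
  rhs <- side(r$stoichiometry[r$stoichiometry > 0])
  trimws(paste(lhs, arrow, rhs))
}

parse_equation <- function(eq, rid) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("reaction ", rid, ": equation lacks an arrow (-> or <=>): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms) {
      bits <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(bits) == 1L) { cf <- 1; met <- bits }
      else if (length(bits) == 2L) {
        cf <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(cf)) stop("reaction ", rid,
                            ": unparseable coefficient in term '", tm, "'")
        met <- bits[2]
      } else stop("reaction ", rid, ": unparseable term '", tm, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * cf
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  s <- lhs
  for (i in seq_along(rhs)) {
    met <- names(rhs)[i]
    s[met] <- (if (met %in% names(s)) s[[met]] else 0) + rhs[[i]]
  }
  s[s != 0]
}

tsv_sidecar_path <- function(path)
  file.path(dirname(path),
            paste0(sub("\\.tsv$", "", basename(path)),
                   "_metabolites.tsv"))

write_model_tsv <- function(model, path) {
  hdr <- c(paste0("#! model_id=", model$id),
           paste0("#! objective=", model$objective$reaction, " ",
                  model$objective$sense))
  if (length(model$annotations))
    hdr <- c(hdr, paste0("#! annotations=",
                         jsonlite::toJSON(model$annotations,
                                          auto_unbox = TRUE, digits = NA)))
  df <- data.frame(
    id = vapply(model$reactions, `[[`, "", "id"),
    name = vapply(model$reactions, `[[`, "", "name"),
    equation = vapply(model$reactions, equation_string, ""),
    lower_bound = num12(vapply(model$reactions, `[[`, numeric(1),
                               "lower_bound")),
    upper_bound = num12(vapply(model$reactions, `[[`, numeric(1),
                               "upper_bound")),
    gene = vapply(model$reactions, `[[`, "", "gene"),
    subsystem = vapply(model$reactions, `[[`, "", "subsystem"),
    is_exchange = vapply(model$reactions, `[[`, logical(1),
                         "is_exchange"),
    is_pseudo = vapply(model$reactions, `[[`, logical(1), "is_pseudo"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  mdf <- data.frame(
    id = vapply(model$metabolites, `[[`, "", "id"),
    name = vapply(model$metabolites, `[[`, "", "name"),
    compartment = vapply(model$metabolites, `[[`, "", "compartment"),
    formula = vapply(model$metabolites, function(m) {
      fs <- formula_string(m$formula)
      if (is.null(fs)) "" else fs
    }, ""))
  utils::write.table(mdf, tsv_sidecar_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_model_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#!")]
  kv <- list()
  for (h in hdr) {
    h <- sub("^#!\\s*", "", h)
    key <- sub("=.*$", "", h)
    kv[[key]] <- sub("^[^=]*=", "", h)
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#!")],
                          stringsAsFactors = FALSE)
  if (!all(c("id", "equation", "lower_bound", "upper_bound") %in%
           names(df)))
    stop("TSV reaction table lacks required columns (id, equation, ",
         "lower_bound, upper_bound): ", path)
  side <- tsv_sidecar_path(path)
  mets <- NULL
  if (file.exists(side)) {
    mdf <- utils::read.delim(side, stringsAsFactors = FALSE,
                             colClasses = "character")
    mets <- lapply(seq_len(nrow(mdf)), function(i)
      metabolite(mdf$id[i], mdf$name[i], mdf$compartment[i],
                 parse_formula_string(mdf$formula[i])))
    known <- mdf$id
  } else known <- NULL
  rxns <- lapply(seq_len(nrow(df)), function(i) {
    stoich <- parse_equation(df$equation[i], df$id[i])
    if (!is.null(known)) {
      unknown <- setdiff(names(stoich), known)
      if (length(unknown))
        stop("reaction ", df$id[i], " references metabolite(s) absent ",
             "from the species table: ", paste(unknown, collapse = ", "))
    }
    reaction(df$id[i], stoich, df$lower_bound[i], df$upper_bound[i],
             name = if ("name" %in% names(df)) df$name[i] else df$id[i],
             gene = if ("gene" %in% names(df)) df$gene[i]
                    else NA_character_,
             subsystem = if ("subsystem" %in% names(df)) df$subsystem[i]
                         else NA_character_,
             is_exchange = if ("is_exchange" %in% names(df))
               isTRUE(as.logical(df$is_exchange[i])) else FALSE,
             is_pseudo = if ("is_pseudo" %in% names(df))
               isTRUE(as.logical(df$is_pseudo[i])) else FALSE)
  })
  if (is.null(mets)) {
    ids <- unique(unlist(lapply(rxns, function(r)
      names(r$stoichiometry))))
    mets <- lapply(ids, function(id)
      metabolite(id, compartment = if (endsWith(id, "_e")) "e" else "c"))
  }
  objective <- if (!is.null(kv$objective)) {
    parts <- strsplit(trimws(kv$objective), "[[:space:]]+")[[1]]
    list(reaction = parts[1],
         sense = if (length(parts) > 1) parts[2] else "max")
  } else {
    ## undocumented tables default to maximising the last listed reaction
    list(reaction = df$id[nrow(df)], sense = "max")
  }
  annotations <- if (!is.null(kv$annotations))
    as.list(jsonlite::fromJSON(kv$annotations, simplifyVector = TRUE))
  else list()
  metabolic_model(kv$model_id %||% tools::file_path_sans_ext(
    basename(path)), mets, rxns, objective, annotations)
}
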