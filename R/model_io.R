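# model serialisation: native JSON and SBML Level 3 + FBC v2

#' Load a stoichiometric model
#'
#' @param source path to a model file.
#' @param dialect `"native-json"` (the package's own format) or
#'   `"sbml-fbc"` (SBML Level 3 with the FBC package, as distributed for
#'   genome-scale reconstructions).
#' @param validate reject models with elementally imbalanced non-pseudo
#'   reactions (default `TRUE`).
#' @return a [core_model()].
#' @export
load_model <- function(source, dialect = c("native-json", "sbml-fbc"),
                       validate = TRUE) {
  dialect <- match.arg(dialect)
  model <- switch(dialect,
    "native-json" = load_model_json(source),
    "sbml-fbc" = load_model_sbml(source))
  if (validate) {
    rep <- validate_model(model)
    if (length(rep$imbalanced)) {
      deltas <- vapply(names(rep$imbalanced), function(id)
        paste0(id, " [", paste(names(rep$imbalanced[[id]]),
                               signif(rep$imbalanced[[id]], 3), sep = ":",
                               collapse = ", "), "]"), "")
      stop("elementally imbalanced non-pseudo reaction(s): ",
           paste(deltas, collapse = "; "))
    }
  }
  model
}

load_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment,
    formula = m$formula %||% "", charge = m$charge %||% 0,
    stringsAsFactors = FALSE)))
  rxns <- lapply(j$reactions, function(r) {
    list(id = r$id, name = r$name %||% r$id,
         mets = unlist(r$mets),
         lb = r$lb %||% -1000, ub = r$ub %||% 1000,
         subsystem = r$subsystem %||% "",
         genes = as.character(unlist(r$genes)),
         pseudo = isTRUE(r$pseudo))
  })
  core_model(mets, rxns, j$biomass_reaction_id, j$ngam_reaction_id,
             notes = j$notes)
}

#' Write a model to the native JSON format
#'
#' @param model a [core_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  j <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula, charge = m$charge)
    }),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name, mets = as.list(r$mets),
           lb = r$lb, ub = r$ub, subsystem = r$subsystem,
           genes = as.list(r$genes), pseudo = r$pseudo)
    })),
    biomass_reaction_id = model$biomass_reaction_id,
    ngam_reaction_id = model$ngam_reaction_id,
    notes = model$notes
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# SBML ids must match [A-Za-z_][A-Za-z0-9_]*; sanitise reversibly
sbml_id <- function(x) {
  y <- gsub("[^A-Za-z0-9_]", "__", x)
  ifelse(grepl("^[A-Za-z_]", y), y, paste0("x_", y))
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' @param model a [core_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "core_model",
                             "fbc:strict" = "false")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = sbml_id(m$id), name = m$name,
                              compartment = m$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false",
                              "fbc:charge" = as.character(m$charge))
    if (nzchar(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  bnds <- unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                   vapply(model$reactions, `[[`, 0, "ub")))
  bnd_id <- function(v) sbml_id(paste0("bnd_", gsub("[-.]", "_", format(v))))
  for (v in bnds) {
    xml2::xml_add_child(lp, "parameter", id = bnd_id(v),
                        value = format(v, digits = 15), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(
      lr, "reaction", id = sbml_id(r$id), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bnd_id(r$lb), "fbc:upperFluxBound" = bnd_id(r$ub))
    if (nzchar(r$subsystem) || r$pseudo) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("subsystem: ", r$subsystem))
      xml2::xml_add_child(body, "p", paste0("pseudo: ",
                                            tolower(as.character(r$pseudo))))
    }
    subs <- r$mets[r$mets < 0]; prods <- r$mets[r$mets > 0]
    if (length(subs)) {
      lsub <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(lsub, "speciesReference", species = sbml_id(m),
                            stoichiometry = format(-subs[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sbml_id(m),
                            stoichiometry = format(prods[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (length(r$genes)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      if (length(r$genes) == 1L) {
        xml2::xml_add_child(ga, "fbc:geneProductRef",
                            "fbc:geneProduct" = sbml_id(r$genes))
      } else {
        or <- xml2::xml_add_child(ga, "fbc:or")
        for (g in r$genes) {
          xml2::xml_add_child(or, "fbc:geneProductRef",
                              "fbc:geneProduct" = sbml_id(g))
        }
      }
    }
  }
  genes <- unique(unlist(lapply(model$reactions, `[[`, "genes")))
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = sbml_id(g),
                          "fbc:label" = g)
    }
  }
  ann <- xml2::xml_add_child(mdl, "annotation")
  xml2::xml_add_child(ann, "coreModelMeta",
                      biomass = model$biomass_reaction_id,
                      ngam = model$ngam_reaction_id)
  xml2::write_xml(doc, path)
  invisible(path)
}

load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- do.call(rbind, lapply(sp, function(x) data.frame(
    id = xml2::xml_attr(x, "id"),
    name = xml2::xml_attr(x, "name") %||NA% xml2::xml_attr(x, "id"),
    compartment = xml2::xml_attr(x, "compartment"),
    formula = xml2::xml_attr(x, "fbc:chemicalFormula", ns = ns) %||NA% "",
    charge = as.numeric(xml2::xml_attr(x, "fbc:charge", ns = ns) %||NA% "0"),
    stringsAsFactors = FALSE)))
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx, function(x) {
    get_side <- function(which, sign) {
      refs <- xml2::xml_find_all(
        x, paste0("./s:", which, "/s:speciesReference"), ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    notes <- xml2::xml_text(xml2::xml_find_all(x, ".//s:notes//*", ns))
    subsystem <- sub("^subsystem: ", "",
                     grep("^subsystem: ", notes, value = TRUE)[1])
    pseudo <- isTRUE(grepl("true",
                           grep("^pseudo: ", notes, value = TRUE)[1]))
    genes <- xml2::xml_attr(
      xml2::xml_find_all(x, ".//fbc:geneProductRef", ns), "fbc:geneProduct",
      ns = ns)
    list(id = xml2::xml_attr(x, "id"),
         name = xml2::xml_attr(x, "name") %||NA% xml2::xml_attr(x, "id"),
         mets = c(get_side("listOfReactants", -1),
                  get_side("listOfProducts", 1)),
         lb = unname(parval[xml2::xml_attr(x, "fbc:lowerFluxBound", ns = ns)]),
         ub = unname(parval[xml2::xml_attr(x, "fbc:upperFluxBound", ns = ns)]),
         subsystem = if (is.na(subsystem)) "" else subsystem,
         genes = as.character(genes), pseudo = pseudo)
  })
  meta <- xml2::xml_find_first(doc, ".//coreModelMeta")
  if (inherits(meta, "xml_missing")) {
    # fall back to conventional ids when the annotation is absent
    bid <- grep("biomass", vapply(rxns, `[[`, "", "id"), ignore.case = TRUE,
                value = TRUE)[1]
    nid <- grep("ngam|atpm", vapply(rxns, `[[`, "", "id"), ignore.case = TRUE,
                value = TRUE)[1]
    if (is.na(bid)) stop("SBML model lacks an identifiable biomass reaction")
  } else {
    bid <- xml2::xml_attr(meta, "biomass")
    nid <- xml2::xml_attr(meta, "ngam")
  }
  core_model(mets, rxns, bid, nid)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a
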