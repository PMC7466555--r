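# stoichiometric core-model container and curation operations

#' Construct a core metabolic model
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   (`c`, `m` or `e`), `formula`, `charge`.
#' @param reactions list of reactions; each a list with `id`, `name`,
#'   `mets` (named numeric stoichiometry, substrates negative), `lb`, `ub`
#'   (mmol/gDCW/h), `subsystem`, `genes` (character vector), `pseudo`
#'   (logical).
#' @param biomass_reaction_id,ngam_reaction_id ids of the biomass and NGAM
#'   pseudo-reactions.
#' @param notes optional free-text annotations preserved on write.
#' @return object of class `core_model`.
#' @export
core_model <- function(metabolites, reactions, biomass_reaction_id,
                       ngam_reaction_id, notes = NULL) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment", "formula", "charge") %in%
                  names(metabolites)))
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  names(reactions) <- rids
  for (r in reactions) {
    unknown <- setdiff(names(r$mets), metabolites$id)
    if (length(unknown)) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub")
  }
  if (length(biomass_reaction_id) != 1L || !biomass_reaction_id %in% rids) {
    stop("model must have exactly one biomass pseudo-reaction")
  }
  if (length(ngam_reaction_id) != 1L || !ngam_reaction_id %in% rids) {
    stop("model must have exactly one NGAM pseudo-reaction")
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         biomass_reaction_id = biomass_reaction_id,
         ngam_reaction_id = ngam_reaction_id,
         notes = notes),
    class = "core_model")
  for (ex in exchange_reactions(m)) {
    r <- reactions[[ex]]
    extl <- metabolites$compartment[match(names(r$mets), metabolites$id)] == "e"
    if (sum(extl) != 1L) {
      stop("exchange reaction ", ex,
           " must touch exactly one extracellular metabolite")
    }
  }
  m
}

#' Reaction ids of exchange reactions
#'
#' Exchange reactions are single-metabolite reactions over extracellular
#' species, written `met_e ->` so uptake is a negative flux.
#'
#' @param model a [core_model()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  ids <- vapply(model$reactions, function(r) {
    length(r$mets) == 1L && comp[names(r$mets)] == "e"
  }, TRUE)
  names(model$reactions)[ids]
}

#' Stoichiometric matrix of a model
#'
#' @param model a [core_model()].
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), length(model$reactions),
              dimnames = list(model$metabolites$id, names(model$reactions)))
  for (r in model$reactions) S[names(r$mets), r$id] <- r$mets
  S
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lb"),
       ub = vapply(model$reactions, `[[`, 0, "ub"))
}

#' Gene-to-reaction map of a model
#'
#' @param model a [core_model()].
#' @return named list mapping gene id to the reaction ids it catalyses.
#' @export
gene_reaction_map <- function(model) {
  out <- list()
  for (r in model$reactions) {
    for (g in r$genes) out[[g]] <- c(out[[g]], r$id)
  }
  out
}

#' Enzyme-metabolite adjacency of a model
#'
#' Derives the bipartite gene/metabolite neighbourhood used for
#' reporter-metabolite analysis: a gene is adjacent to every metabolite of
#' every reaction it catalyses, excluding ubiquitous species.
#'
#' @param model a [core_model()].
#' @param exclude metabolite ids not counted as neighbours (defaults to
#'   water and phosphate pools).
#' @return named list mapping metabolite id to adjacent gene ids.
#' @export
enzyme_metabolite_adjacency <- function(model,
    exclude = c("h2o_c", "h2o_m", "h2o_e", "pi_c", "pi_m")) {
  adj <- list()
  for (r in model$reactions) {
    if (!length(r$genes)) next
    mets <- setdiff(names(r$mets), exclude)
    for (m in mets) adj[[m]] <- unique(c(adj[[m]], r$genes))
  }
  adj
}

#' @export
print.core_model <- function(x, ...) {
  n_ex <- length(exchange_reactions(x))
  n_ps <- sum(vapply(x$reactions, `[[`, TRUE, "pseudo"))
  cat(sprintf("Core metabolic model: %d metabolites, %d reactions (%d exchanges, %d pseudo)\n",
              nrow(x$metabolites), length(x$reactions), n_ex, n_ps))
  cat("  biomass:", x$biomass_reaction_id, " NGAM:", x$ngam_reaction_id, "\n")
  invisible(x)
}

element_imbalance <- function(model, reaction) {
  counts <- list()
  for (mid in names(reaction$mets)) {
    f <- model$metabolites$formula[match(mid, model$metabolites$id)]
    if (!nzchar(f)) return(NULL)  # unformulated species: cannot audit
    cf <- parse_formula(f) * reaction$mets[[mid]]
    for (el in names(cf)) counts[[el]] <- (counts[[el]] %||% 0) + cf[[el]]
  }
  delta <- unlist(counts)
  delta[abs(delta) > 1e-6]
}

#' Validate a core model
#'
#' Reports elemental imbalances of non-pseudo reactions, charge imbalances,
#' dead-end metabolites (species produced or consumed by no more than one
#' reaction direction), and optionally blocked reactions by flux variability
#' analysis with all exchanges opened.
#'
#' @param model a [core_model()].
#' @param fva logical; also report blocked reactions (runs 2 LPs per
#'   reaction).
#' @return list with `imbalanced` (named list of element deltas),
#'   `dead_ends` (metabolite ids) and `blocked` (reaction ids or `NULL`).
#' @export
validate_model <- function(model, fva = FALSE) {
  imb <- list()
  for (r in model$reactions) {
    if (isTRUE(r$pseudo)) next
    if (r$id %in% exchange_reactions(model)) next
    d <- element_imbalance(model, r)
    if (length(d)) imb[[r$id]] <- d
  }
  S <- stoich_matrix(model)
  if (ncol(S) == 0 || nrow(S) == 0) {
    return(list(imbalanced = imb, dead_ends = character(0), blocked = NULL))
  }
  b <- reaction_bounds(open_exchanges(model))
  dead <- character(0)
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    can_produce <- any(row > 0 & b$ub > 0) || any(row < 0 & b$lb < 0)
    can_consume <- any(row < 0 & b$ub > 0) || any(row > 0 & b$lb < 0)
    if (!(can_produce && can_consume)) dead <- c(dead, rownames(S)[i])
  }
  blocked <- NULL
  if (fva) {
    open <- open_exchanges(model)
    rng <- fva(open, reactions = names(model$reactions))
    blocked <- rng$reaction[abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9]
  }
  list(imbalanced = imb, dead_ends = dead, blocked = blocked)
}

#' Open all exchange bounds of a model
#'
#' @param model a [core_model()].
#' @param limit absolute bound applied to every exchange.
#' @return modified model.
#' @export
open_exchanges <- function(model, limit = 1000) {
  for (ex in exchange_reactions(model)) {
    model$reactions[[ex]]$lb <- -limit
    model$reactions[[ex]]$ub <- limit
  }
  model
}

set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) stop("no reaction ", id)
  if (!is.null(lb)) model$reactions[[id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[id]]$ub <- ub
  model
}

# ---------------------------------------------------------------------------
# biomass composition

#' Macromolecular biomass composition
#'
#' @param protein protein content, g/gDCW.
#' @param lipid lipid content, g/gDCW.
#' @param carotenoid_total total carotenoid content, mg/gDCW.
#' @param carotenoid_fractions named fractions of the four pigment species
#'   (must sum to 1).
#' @param residual fixed RNA+ash residual, g/gDCW.
#' @return object of class `biomass_composition`; the carbohydrate fraction
#'   is the balancing remainder so components sum to 1 g/gDCW.
#' @export
biomass_composition <- function(protein = 0.44, lipid = 0.18,
                                carotenoid_total = 0.66,
                                carotenoid_fractions = c(
                                  beta_carotene = 0.25, gamma_carotene = 0.10,
                                  torulene = 0.25, torularhodin = 0.40),
                                residual = 0.05) {
  car_g <- carotenoid_total / 1000
  stopifnot(protein >= 0, lipid >= 0, car_g >= 0, residual >= 0)
  if (abs(sum(carotenoid_fractions) - 1) > 1e-8) {
    stop("carotenoid species fractions must sum to 1")
  }
  carbohydrate <- 1 - protein - lipid - car_g - residual
  if (carbohydrate < -1e-9) {
    stop("infeasible composition: components exceed 1 g/gDCW")
  }
  structure(list(protein = protein, lipid = lipid,
                 carotenoid_total = carotenoid_total,
                 carotenoid_fractions = carotenoid_fractions,
                 carbohydrate = max(carbohydrate, 0), residual = residual),
            class = "biomass_composition")
}

# molar masses of the biomass precursor species (g/mol)
BIOMASS_SPECIES_MASS <- c(
  protein_c = 128.918,   # 0.8 Glu + 0.2 Gln residue average
  glucan_c = 162.141,    # anhydroglucose unit
  tag_c = 885.453,       # average triacylglyceride C57H104O6
  bcaro_c = 536.888,     # beta-carotene C40H56
  gcaro_c = 536.888,     # gamma-carotene C40H56
  torulene_c = 534.872,  # torulene C40H54
  torularhodin_c = 564.854 # torularhodin C40H52O2
)

#' Set the biomass composition of a model
#'
#' Recomputes the biomass pseudo-reaction coefficients from measured
#' protein, lipid and carotenoid contents. Carbohydrate (plus the fixed
#' residual) absorbs the remainder so the coefficients, dotted with the
#' precursor species masses, total exactly 1 g/gDCW. The growth-associated
#' ATP cost is retained.
#'
#' @param model a [core_model()].
#' @param composition a [biomass_composition()].
#' @return the modified model, with the composition stored as an attribute
#'   of the biomass reaction.
#' @export
set_biomass_composition <- function(model, composition) {
  stopifnot(inherits(model, "core_model"),
            inherits(composition, "biomass_composition"))
  bio <- model$reactions[[model$biomass_reaction_id]]
  gam <- abs(bio$mets[["atp_c"]] %||% 30)
  car_masses <- BIOMASS_SPECIES_MASS[c("bcaro_c", "gcaro_c", "torulene_c",
                                       "torularhodin_c")]
  car_frac <- composition$carotenoid_fractions
  names(car_frac) <- c("bcaro_c", "gcaro_c", "torulene_c", "torularhodin_c")[
    match(names(car_frac), c("beta_carotene", "gamma_carotene", "torulene",
                             "torularhodin"))]
  mets <- c(
    protein_c = -composition$protein / BIOMASS_SPECIES_MASS[["protein_c"]] * 1000,
    glucan_c = -(composition$carbohydrate + composition$residual) /
      BIOMASS_SPECIES_MASS[["glucan_c"]] * 1000,
    tag_c = -composition$lipid / BIOMASS_SPECIES_MASS[["tag_c"]] * 1000,
    stats::setNames(-composition$carotenoid_total / 1000 * car_frac /
                      car_masses[names(car_frac)] * 1000, names(car_frac)),
    atp_c = -gam, h2o_c = -gam,
    adp_c = gam, pi_c = gam,
    biomass_e = 1
  )
  bio$mets <- mets[mets != 0 | names(mets) == "biomass_e"]
  model$reactions[[model$biomass_reaction_id]] <- bio
  attr(model$reactions[[model$biomass_reaction_id]], "composition") <- composition
  model
}

#' Mass of one gram of model biomass
#'
#' Dots the biomass pseudo-reaction's precursor coefficients with the
#' precursor species masses; equals 1.000 g/gDCW for a well-formed biomass
#' reaction.
#'
#' @param model a [core_model()].
#' @return total precursor mass, g/gDCW.
#' @export
biomass_precursor_mass <- function(model) {
  mets <- model$reactions[[model$biomass_reaction_id]]$mets
  prec <- intersect(names(mets), names(BIOMASS_SPECIES_MASS))
  sum(-mets[prec] * BIOMASS_SPECIES_MASS[prec]) / 1000
}

# ---------------------------------------------------------------------------
# arabitol routes

#' Add the dual arabitol production routes and the artificial arabitol pool
#'
#' Adds lumped production routes for L- and D-arabitol from xylose with a
#' configurable net cofactor stoichiometry (the "cofactor spec": moles of
#' reduced cofactor regenerated per mole arabitol; negative values denote
#' consumption), plus pseudo-reactions pooling both isoforms into an
#' isoform-agnostic "artificial" arabitol with its own exchange, and a
#' conjugate catabolic lump so pooled arabitol can be consumed after the
#' carbon switch. The route lumps are pseudo-reactions: the cofactor spec
#' is a modelling assertion about the (enzymatically unresolved) isoform
#' chemistry, not an elementally audited mechanism.
#'
#' @param model a [core_model()].
#' @param l_route,d_route named numeric cofactor specs over `"nadph"` and
#'   `"nadh"`; defaults: L regenerates 1 NADPH + 1 NADH, D regenerates
#'   1 NADH.
#' @param overwrite replace existing routes instead of erroring.
#' @return modified model.
#' @export
add_arabitol_pathways <- function(model,
                                  l_route = c(nadph = 1, nadh = 1),
                                  d_route = c(nadh = 1),
                                  overwrite = FALSE) {
  stopifnot(inherits(model, "core_model"))
  if (!"xyl_c" %in% model$metabolites$id) {
    stop("xylose assimilation must be present before adding arabitol routes")
  }
  have <- intersect(c("LAROUTE", "DAROUTE"), names(model$reactions))
  if (length(have) && !overwrite) {
    stop("arabitol route(s) already present: ", paste(have, collapse = ", "),
         " (use overwrite = TRUE)")
  }
  need_mets <- data.frame(
    id = c("laol_c", "daol_c", "abt_c", "abt_e"),
    name = c("L-arabitol", "D-arabitol", "arabitol (artificial)",
             "arabitol (artificial, extracellular)"),
    compartment = c("c", "c", "c", "e"),
    formula = rep("C5H12O5", 4), charge = 0, stringsAsFactors = FALSE
  )
  new <- !need_mets$id %in% model$metabolites$id
  model$metabolites <- rbind(model$metabolites, need_mets[new, ])

  route_mets <- function(iso_met, spec) {
    mets <- list(-1, 1)
    names(mets) <- c("xyl_c", iso_met)
    for (cf in names(spec)) {
      pair <- switch(cf, nadph = c("nadp_c", "nadph_c"),
                     nadh = c("nad_c", "nadh_c"),
                     stop("unknown cofactor in route spec: ", cf))
      v <- spec[[cf]]
      mets[[pair[1]]] <- (mets[[pair[1]]] %||% 0) - v
      mets[[pair[2]]] <- (mets[[pair[2]]] %||% 0) + v
    }
    out <- unlist(mets)
    out[out != 0]
  }
  rxn <- function(id, name, mets, lb = 0, ub = 1000, subsystem, genes = character(0),
                  pseudo = TRUE) {
    list(id = id, name = name, mets = mets, lb = lb, ub = ub,
         subsystem = subsystem, genes = genes, pseudo = pseudo)
  }
  routes <- list(
    rxn("LAROUTE", "L-arabitol production route (lumped)",
        route_mets("laol_c", l_route), subsystem = "Arabitol metabolism",
        genes = c("RHTO_00373", "RHTO_01629")),
    rxn("DAROUTE", "D-arabitol production route (lumped)",
        route_mets("daol_c", d_route), subsystem = "Arabitol metabolism",
        genes = "RHTO_07844"),
    rxn("LAPOOL", "L-arabitol to artificial arabitol pool",
        c(laol_c = -1, abt_c = 1), subsystem = "Arabitol metabolism"),
    rxn("DAPOOL", "D-arabitol to artificial arabitol pool",
        c(daol_c = -1, abt_c = 1), subsystem = "Arabitol metabolism"),
    # catabolic lump with the L-isoform enzyme chemistry (LAD + LXR + XDH:
    # one NADPH in, two NADH out per arabitol); closed by default because
    # running it against the production lumps would cycle cofactors out of
    # nothing -- apply_constraints opens it for polyol-consuming phases,
    # where the production routes carry no flux (no xylose available)
    rxn("ABTCAT", "arabitol catabolism (lumped)",
        c(abt_c = -1, nad_c = -2, nadph_c = -1, xul_c = 1, nadh_c = 2,
          nadp_c = 1),
        ub = 0,
        subsystem = "Arabitol metabolism",
        genes = c("RHTO_00373", "RHTO_01629", "RHTO_07844"), pseudo = FALSE),
    rxn("ABTt", "arabitol transport", c(abt_c = -1, abt_e = 1),
        lb = -1000, subsystem = "Transport", pseudo = FALSE),
    rxn("EX_abt", "arabitol exchange", c(abt_e = -1), lb = -1000,
        subsystem = "Exchange", pseudo = FALSE)
  )
  for (r in routes) model$reactions[[r$id]] <- r
  core_model(model$metabolites, model$reactions, model$biomass_reaction_id,
             model$ngam_reaction_id, model$notes)
}

#' Net cofactor stoichiometry of a pathway
#'
#' Solves for the minimal-total-flux steady-state mode producing one mole of
#' the sink metabolite from the source metabolite with every exchange closed
#' and only cofactor-recycling pseudo-reactions (plus free water, phosphate,
#' CO2 and O2) available, and returns the net moles of the reduced cofactor
#' regenerated (positive) or consumed (negative) per mole of sink.
#'
#' @param model a [core_model()].
#' @param source_met,sink_met metabolite ids.
#' @param cofactor `"nadph"`, `"nadh"` or `"atp"`.
#' @return net mol cofactor per mol sink.
#' @export
pathway_cofactor_audit <- function(model, source_met, sink_met, cofactor) {
  stopifnot(inherits(model, "core_model"))
  if (source_met == sink_met) return(0)
  pairs <- list(nadph = c("nadph_c", "nadp_c"), nadh = c("nadh_c", "nad_c"),
                atp = c("atp_c", "adp_c"))
  if (!cofactor %in% names(pairs)) stop("unknown cofactor: ", cofactor)
  # close all exchanges
  for (ex in exchange_reactions(model)) {
    model$reactions[[ex]]$lb <- 0
    model$reactions[[ex]]$ub <- 0
  }
  aux <- function(id, mets, lb = -1000, ub = 1000) {
    list(id = id, name = id, mets = mets, lb = lb, ub = ub,
         subsystem = "audit", genes = character(0), pseudo = TRUE)
  }
  add <- list(
    aux("AUD_SRC", stats::setNames(1, source_met)),
    aux("AUD_SINK", stats::setNames(-1, sink_met), lb = 1, ub = 1)
  )
  for (cf in names(pairs)) {
    p <- pairs[[cf]]
    if (all(p %in% model$metabolites$id)) {
      add <- c(add, list(aux(paste0("AUD_", toupper(cf)),
                             stats::setNames(c(-1, 1), p))))
    }
  }
  free <- intersect(c("h2o_c", "pi_c", "co2_c", "o2_c", "ppi_c", "amp_c"),
                    model$metabolites$id)
  for (fm in free) {
    add <- c(add, list(aux(paste0("AUD_FREE_", fm), stats::setNames(-1, fm))))
  }
  for (r in add) model$reactions[[r$id]] <- r
  # keep biomass/NGAM shut so the mode is the pathway itself
  model$reactions[[model$biomass_reaction_id]]$lb <- 0
  model$reactions[[model$biomass_reaction_id]]$ub <- 0
  model$reactions[[model$ngam_reaction_id]]$ub <- 0
  sol <- pfba_min_total_flux(model)
  if (sol$status != "optimal") stop("no feasible mode from ", source_met,
                                    " to ", sink_met)
  # flux through the recycling reaction: recycler consumes the reduced form,
  # so positive recycler flux means the pathway produced (regenerated) it
  v <- sol$flux[[paste0("AUD_", toupper(cofactor))]]
  if (is.null(v)) 0 else round(v, 6)
}
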