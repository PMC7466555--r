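ATOMIC_MASSES <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06
)

#' Parse an elemental formula
#'
#' Parses formulas such as `"C5H10O5"` or `"(NH4)2SO4"` into named element
#' counts. Fractional subscripts (e.g. `"C5H7.2N1.2O2.8"`, used for averaged
#' residues) are accepted.
#'
#' @param formula character scalar, elemental formula.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("\\s", "", formula)
  if (!nzchar(f)) return(stats::setNames(numeric(0), character(0)))
  # expand parenthesised groups, e.g. (NH4)2
  while (grepl("\\(", f)) {
    m <- regmatches(f, regexpr("\\(([^()]*)\\)([0-9.]*)", f))
    if (length(m) == 0L) stop("unbalanced parentheses in formula: ", formula)
    inner <- sub("\\(([^()]*)\\)([0-9.]*)", "\\1", m)
    mult <- sub("\\(([^()]*)\\)([0-9.]*)", "\\2", m)
    mult <- if (nzchar(mult)) as.numeric(mult) else 1
    counts <- parse_formula(inner) * mult
    rep_str <- paste0(
      names(counts), ifelse(counts == 1, "", format(counts, trim = TRUE)),
      collapse = ""
    )
    f <- sub("\\(([^()]*)\\)([0-9.]*)", rep_str, f, fixed = FALSE)
  }
  toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9.]*", f))[[1]]
  if (sum(nchar(toks)) != nchar(f)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9.].*$", "", toks)
  n <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1
  out <- tapply(n, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Molar mass of a formula
#'
#' @param formula character scalar, elemental formula.
#' @return molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(counts * ATOMIC_MASSES[names(counts)])
}

#' Compound registry for molar conversions
#'
#' Builds the registry of compounds used throughout the physiology module:
#' formula, molar mass, and carbon/nitrogen atom counts per molecule. Biomass
#' is included as a parameterised pseudo-compound whose elemental carbon and
#' nitrogen content per gram are configurable.
#'
#' @param biomass_carbon carbon content of dry biomass, g-C/gDCW.
#'   Default 0.48, a standard value for yeast.
#' @param biomass_nitrogen nitrogen content of dry biomass, mol-N/gDCW.
#' @param extra optional named list of additional compounds; each element a
#'   list with a `formula` field.
#' @return object of class `compound_registry`: a data frame with columns
#'   `compound`, `formula`, `molar_mass`, `carbon`, `nitrogen`.
#' @export
compound_registry <- function(biomass_carbon = 0.48,
                              biomass_nitrogen = 0.00548,
                              extra = NULL) {
  base <- list(
    xylose       = "C5H10O5",
    xylitol      = "C5H12O5",
    arabitol     = "C5H12O5",
    glucose      = "C6H12O6",
    glycerol     = "C3H8O3",
    ammonium_sulfate = "(NH4)2SO4",
    co2          = "CO2",
    # average triacylglyceride (tri-C18:1) used for lipid carbon accounting
    lipid        = "C57H104O6",
    # beta-carotene stoichiometry used for total-carotenoid mass accounting
    carotenoid   = "C40H56"
  )
  if (!is.null(extra)) base <- c(base, lapply(extra, `[[`, "formula"))
  rows <- lapply(names(base), function(cn) {
    counts <- parse_formula(base[[cn]])
    data.frame(
      compound = cn, formula = base[[cn]],
      molar_mass = molar_mass(base[[cn]]),
      carbon = if ("C" %in% names(counts)) counts[["C"]] else 0,
      nitrogen = if ("N" %in% names(counts)) counts[["N"]] else 0,
      stringsAsFactors = FALSE
    )
  })
  reg <- do.call(rbind, rows)
  attr(reg, "biomass_carbon") <- biomass_carbon
  attr(reg, "biomass_nitrogen") <- biomass_nitrogen
  class(reg) <- c("compound_registry", "data.frame")
  reg
}

reg_get <- function(registry, compound, field) {
  i <- match(compound, registry$compound)
  if (is.na(i)) stop("compound not in registry: ", compound)
  registry[[field]][i]
}

#' Molar carbon-to-nitrogen ratio of a medium
#'
#' Computes the mol-C/mol-N ratio of a medium given its composition in g/L.
#'
#' @param medium data frame (or list of lists) with columns `compound` and
#'   `conc` (g/L).
#' @param registry a [compound_registry()].
#' @return C/N ratio, mol/mol.
#' @export
cn_ratio <- function(medium, registry = compound_registry()) {
  if (!is.data.frame(medium)) {
    medium <- do.call(rbind, lapply(medium, function(x)
      data.frame(compound = x$compound, conc = x$conc)))
  }
  stopifnot(all(c("compound", "conc") %in% names(medium)))
  mols <- medium$conc / vapply(medium$compound, reg_get, 0, registry = registry,
                               field = "molar_mass")
  molC <- sum(mols * vapply(medium$compound, reg_get, 0, registry = registry,
                            field = "carbon"))
  molN <- sum(mols * vapply(medium$compound, reg_get, 0, registry = registry,
                            field = "nitrogen"))
  if (molC <= 0) stop("medium contains no carbon")
  if (molN <= 0) stop("infinite C/N: medium contains no nitrogen")
  molC / molN
}
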