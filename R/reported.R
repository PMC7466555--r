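# derived comparisons over condition-level summary tables (whole-batch
# titres, yields and volumetric rates per cultivation condition, and the
# adaptive-evolution course)

#' Read a condition summary table
#'
#' The bundled table holds whole-batch carotenoid and lipid titres, yields
#' on cell mass and on substrate, and volumetric rates for the reference
#' (REF), light-irradiated (LIG), peroxide-stressed (PER) and adapted
#' (ADA) cultivations.
#'
#' @param path TSV path; default: the bundled summary.
#' @return data frame with a `quantity` column and one column per
#'   condition.
#' @export
read_condition_summary <- function(path = system.file(
    "extdata", "condition_summary.tsv", package = "oleoflux",
    mustWork = TRUE)) {
  utils::read.delim(path, sep = "\t", header = TRUE)
}

#' Read the adaptive-evolution summary table
#'
#' One row per evolution cycle: selective peroxide level, passage count,
#' lag-phase duration at the start and end of the cycle and the maximal
#' specific growth rate before and after.
#'
#' @param path TSV path; default: the bundled summary.
#' @return data frame.
#' @export
read_ale_summary <- function(path = system.file(
    "extdata", "ale_summary.tsv", package = "oleoflux", mustWork = TRUE)) {
  utils::read.delim(path, sep = "\t", header = TRUE)
}

summary_value <- function(summary, quantity, condition) {
  i <- match(quantity, summary$quantity)
  if (is.na(i)) stop("no quantity ", quantity)
  summary[[condition]][i]
}

#' Derived condition comparisons
#'
#' Percentage yield increases of the stressed conditions over the
#' reference, the peroxide/reference lipid yield ratio, and the
#' adapted/peroxide carotenoid yield ratio.
#'
#' @param summary a [read_condition_summary()] table.
#' @return named list of derived statistics.
#' @export
condition_comparisons <- function(summary = read_condition_summary()) {
  v <- function(q, cond) summary_value(summary, q, cond)
  list(
    carotenoid_yield_increase_LIG_pct =
      percent_increase(v("carotenoid_yield_mg_gdcw", "LIG"),
                       v("carotenoid_yield_mg_gdcw", "REF")),
    lipid_yield_increase_LIG_pct =
      percent_increase(v("lipid_yield_g_gdcw", "LIG"),
                       v("lipid_yield_g_gdcw", "REF")),
    lipid_yield_ratio_PER_over_REF =
      fold_ratio(v("lipid_yield_g_gdcw", "PER"),
                 v("lipid_yield_g_gdcw", "REF")),
    carotenoid_yield_ratio_ADA_over_PER =
      fold_ratio(v("carotenoid_yield_mg_gdcw", "ADA"),
                 v("carotenoid_yield_mg_gdcw", "PER"))
  )
}

#' Derived adaptive-evolution statistics
#'
#' Lag-phase fold reduction and growth-rate improvement per cycle.
#'
#' @param ale a [read_ale_summary()] table.
#' @return data frame with one row per cycle: `lag_fold_reduction`,
#'   `mu_increase_pct`.
#' @export
ale_statistics <- function(ale = read_ale_summary()) {
  data.frame(
    cycle = ale$cycle,
    lag_fold_reduction = ale$lag_start_h / ale$lag_end_h,
    mu_increase_pct = percent_increase(ale$mu_max_end_h, ale$mu_max_start_h)
  )
}
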