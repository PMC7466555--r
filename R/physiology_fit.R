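#' Fit the phase-resolved physiology of a batch cultivation
#'
#' The main entry point of the physiology module: segments the batch into
#' growth phases, estimates the specific growth rate, specific conversion
#' rates, product yields and the carbon balance per phase, and whole-batch
#' yields.
#'
#' @param series a [cultivation_series()].
#' @param registry a [compound_registry()].
#' @param medium_nitrogen available nitrogen in the medium, mol-N/L (see
#'   [segment_phases()]).
#' @param biomass_n_fraction nitrogen content of biomass, mol-N/gDCW.
#' @param depletion_threshold xylose depletion threshold, g/L.
#' @param criterion P1/P2 boundary criterion, see [segment_phases()].
#' @param method rate estimator, see [specific_rate()].
#' @return object of class `physiology_fit` with components `series`,
#'   `phases`, `rates` (list of [phase_rates()] per phase), `whole_batch`
#'   (yields over the full batch) and `carbon` (per-phase carbon balances).
#' @export
fit_physiology <- function(series, registry = compound_registry(),
                           medium_nitrogen = NULL,
                           biomass_n_fraction = 0.0075,
                           depletion_threshold = 0.5,
                           criterion = "earlier",
                           method = "endpoint") {
  phases <- segment_phases(series, medium_nitrogen = medium_nitrogen,
                           biomass_n_fraction = biomass_n_fraction,
                           depletion_threshold = depletion_threshold,
                           criterion = criterion)
  rates <- lapply(seq_len(nrow(phases)), function(i)
    phase_rates(series, phases[i, ], registry, method = method))
  names(rates) <- phases$label
  carbon <- lapply(rates, function(r)
    tryCatch(carbon_balance(r, registry), error = function(e)
      list(recovery = NA_real_, flag = conditionMessage(e))))
  out <- list(
    series = series, phases = phases, rates = rates,
    whole_batch = yields_and_q(series, phase = NULL, registry),
    carbon = carbon, registry = registry
  )
  class(out) <- "physiology_fit"
  out
}

#' @export
print.physiology_fit <- function(x, ...) {
  cat("Batch physiology fit:", x$series$condition_label, "\n")
  for (i in seq_len(nrow(x$phases))) {
    p <- x$phases[i, ]
    cat(sprintf("  %s [%6.1f, %6.1f] h  limitation: %s  mu = %.4g 1/h\n",
                p$label, p$t_start, p$t_end, p$limitation,
                x$rates[[p$label]]$mu))
  }
  invisible(x)
}

#' @export
summary.physiology_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$rates), function(ph) {
    r <- object$rates[[ph]]
    xyl <- r$r$xylose
    data.frame(
      phase = ph,
      t_start = r$phase$t_start, t_end = r$phase$t_end,
      mu_h = r$mu,
      r_xyl_mmol = if (!is.null(xyl) && xyl$direction == "uptake")
        xyl$rate else 0,
      r_car_mg = r$r_car, r_lip_g = r$r_lip,
      Y_biomass = r$yield_biomass,
      carbon_recovery = object$carbon[[ph]]$recovery,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(table = tab, whole_batch = object$whole_batch),
            class = "summary.physiology_fit")
}

#' @export
print.summary.physiology_fit <- function(x, ...) {
  cat("Per-phase rates:\n")
  tab <- x$table
  tab$mu_h <- signif(tab$mu_h, 3)
  tab$r_xyl_mmol <- signif(tab$r_xyl_mmol, 3)
  tab$r_car_mg <- signif(tab$r_car_mg, 3)
  tab$r_lip_g <- signif(tab$r_lip_g, 3)
  tab$Y_biomass <- round(tab$Y_biomass, 2)
  tab$carbon_recovery <- round(tab$carbon_recovery, 2)
  print(tab, row.names = FALSE)
  cat("\nWhole-batch yields:\n")
  wb <- x$whole_batch
  wb$Y <- round(wb$Y, 2); wb$Y_S <- round(wb$Y_S, 2)
  wb$q <- signif(wb$q, 3)
  print(wb, row.names = FALSE)
  invisible(x)
}

#' @export
coef.physiology_fit <- function(object, ...) {
  stats::setNames(vapply(object$rates, `[[`, 0, "mu"), names(object$rates))
}

#' @export
predict.physiology_fit <- function(object, times = NULL, ...) {
  s <- object$series$samples
  if (is.null(times)) times <- s$time_h
  # piecewise-exponential DCW prediction from the per-phase fits
  out <- numeric(length(times))
  for (i in seq_len(nrow(object$phases))) {
    p <- object$phases[i, ]
    mu <- object$rates[[p$label]]$mu
    x0 <- series_at(s, "dcw_g_l", p$t_start)
    sel <- times >= p$t_start - 1e-9 & times <= p$t_end + 1e-9
    out[sel] <- x0 * exp(mu * (times[sel] - p$t_start))
  }
  out
}

#' Write the rates table and physiology report of a fit
#'
#' Emits a long-format TSV (one row per phase and quantity) and a JSON
#' report with phases, rates, yields and carbon balances.
#'
#' @param fit a [fit_physiology()] result.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report list.
#' @export
write_physiology_report <- function(fit, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(fit, "physiology_fit"))
  sm <- summary(fit)$table
  long <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i) {
    row <- sm[i, ]
    qn <- c("mu_h", "r_xyl_mmol", "r_car_mg", "r_lip_g", "Y_biomass",
            "carbon_recovery")
    data.frame(condition = fit$series$condition_label,
               phase = row$phase, quantity = qn,
               value = as.numeric(row[qn]), stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv_path)) {
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report <- list(
    condition = fit$series$condition_label,
    phases = fit$phases,
    rates = summary(fit)$table,
    whole_batch = fit$whole_batch,
    carbon = fit$carbon
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}

#' Derived comparisons between cultivation conditions
#'
#' Computes the standard derived statistics from a condition-level summary
#' table of titres, yields and rates (columns: `quantity`, one column per
#' condition): percentage increases of product yields between conditions,
#' fold ratios, and evolution-experiment statistics (lag-phase fold
#' reduction, growth-rate increase).
#'
#' @param a,b numeric scalars (value under condition a and reference b).
#' @return `percent_increase`: percentage increase of `a` over `b`;
#'   `fold_ratio`: `a / b`.
#' @export
percent_increase <- function(a, b) 100 * (a - b) / b

#' @rdname percent_increase
#' @export
fold_ratio <- function(a, b) a / b
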