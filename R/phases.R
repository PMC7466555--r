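# growth-phase segmentation and specific-rate estimation for batch series

# linear interpolation of a measured column at time t
series_at <- function(samples, col, t) {
  y <- samples[[col]]
  if (is.null(y)) return(NA_real_)
  ok <- !is.na(y)
  stats::approx(samples$time_h[ok], y[ok], xout = t, rule = 2)$y
}

# logarithmic mean of two positive biomass values (exact average biomass of
# an exponential segment; reduces to the arithmetic mean as x1 -> x2)
log_mean <- function(x1, x2) {
  if (x1 <= 0 || x2 <= 0) stop("log-mean requires positive biomass")
  if (abs(x1 - x2) < 1e-12 * max(x1, x2)) return((x1 + x2) / 2)
  (x2 - x1) / log(x2 / x1)
}

#' Segment a batch cultivation into growth phases
#'
#' Detects the three canonical phases of oleaginous-yeast batch growth on
#' xylose: unlimited exponential growth (P1), nitrogen-limited growth on
#' xylose (P2), and polyol (xylitol/arabitol) consumption after xylose
#' depletion (P3). The P1/P2 boundary is located either from nitrogen
#' exhaustion (cumulative nitrogen incorporated into biomass reaching the
#' nitrogen available in the medium), from the breakpoint of a two-piece
#' continuous log-linear fit of DCW against time, or — the default — the
#' earlier of the two. The P2/P3 boundary is the interpolated time at which
#' xylose falls below the depletion threshold.
#'
#' @param series a [cultivation_series()].
#' @param medium_nitrogen available nitrogen in the medium, mol-N/L
#'   (e.g. `1.95 / molar_mass("(NH4)2SO4") * 2` for 1.95 g/L ammonium
#'   sulfate). If `NULL` the nitrogen criterion is skipped.
#' @param biomass_n_fraction nitrogen content of biomass, mol-N/gDCW.
#'   Default 0.0075 (protein-dominated biomass).
#' @param depletion_threshold xylose concentration (g/L) below which the
#'   primary carbon source counts as depleted. Default 0.5.
#' @param criterion P1/P2 boundary criterion: `"earlier"` (default),
#'   `"nitrogen"`, or `"breakpoint"`.
#' @return object of class `growth_phases`: a data frame with columns
#'   `label`, `t_start`, `t_end`, `limitation`.
#' @export
segment_phases <- function(series, medium_nitrogen = NULL,
                           biomass_n_fraction = 0.0075,
                           depletion_threshold = 0.5,
                           criterion = c("earlier", "nitrogen", "breakpoint")) {
  stopifnot(inherits(series, "cultivation_series"))
  criterion <- match.arg(criterion)
  s <- series$samples
  if (nrow(s) < 3L) stop("need at least 3 samples spanning growth")
  if (max(s$dcw_g_l) < 1.1 * s$dcw_g_l[1]) {
    stop("no growth detected: max DCW < 1.1 x initial DCW")
  }
  t0 <- s$time_h[1]; t_end <- s$time_h[nrow(s)]

  t_nitrogen <- NA_real_
  if (!is.null(medium_nitrogen)) {
    dcw_limit <- s$dcw_g_l[1] + medium_nitrogen / biomass_n_fraction
    t_nitrogen <- series_crossing_time(s, "dcw_g_l", dcw_limit, rising = TRUE)
  } else if (!is.null(s$nh4_g_l)) {
    # residual ammonium measured: exhausted when below 2% of initial
    t_nitrogen <- series_crossing_time(s, "nh4_g_l", 0.02 * s$nh4_g_l[1])
  }
  t_break <- if (criterion != "nitrogen") loglinear_breakpoint(s) else NA_real_
  t_p12 <- switch(criterion,
    nitrogen = t_nitrogen,
    breakpoint = t_break,
    earlier = suppressWarnings(min(t_nitrogen, t_break, na.rm = TRUE))
  )
  if (!is.finite(t_p12)) t_p12 <- NA_real_

  t_p23 <- series_crossing_time(s, "xylose_g_l", depletion_threshold)

  cuts <- c(t_p12, t_p23)
  cuts <- cuts[is.finite(cuts) & cuts > t0 & cuts < t_end]
  # phases are contiguous and ordered; drop a xylose-depletion cut that
  # precedes the nitrogen switch (cannot happen in a well-formed batch)
  cuts <- sort(unique(cuts))
  labs <- c("P1", "P2", "P3")[seq_len(length(cuts) + 1L)]
  lims <- c("none", "nitrogen", "nitrogen+carbon-switch")[seq_along(labs)]
  if (length(cuts) == 1L && is.finite(t_p23) && !is.finite(t_p12)) {
    # single boundary that is a carbon switch, not a nitrogen switch
    lims <- c("none", "nitrogen+carbon-switch")
  }
  bounds <- c(t0, cuts, t_end)
  out <- data.frame(
    label = labs,
    t_start = bounds[-length(bounds)],
    t_end = bounds[-1],
    limitation = lims,
    stringsAsFactors = FALSE
  )
  class(out) <- c("growth_phases", "data.frame")
  out
}

# breakpoint of a continuous two-piece linear fit of ln(DCW) on time,
# minimising total SSE over interior candidate breakpoints
loglinear_breakpoint <- function(samples) {
  ok <- samples$dcw_g_l > 0
  t <- samples$time_h[ok]; y <- log(samples$dcw_g_l[ok])
  n <- length(t)
  if (n < 5L) return(NA_real_)
  cand <- t[3:(n - 2)]
  sse <- vapply(cand, function(tb) {
    fit <- stats::lm(y ~ t + pmax(t - tb, 0))
    sum(stats::residuals(fit)^2)
  }, 0)
  tb <- cand[which.min(sse)]
  # require a real slope drop, otherwise report no breakpoint
  fit <- stats::lm(y ~ t + pmax(t - tb, 0))
  slope2_delta <- stats::coef(fit)[3]
  fit0 <- stats::lm(y ~ t)
  if (is.na(slope2_delta) || slope2_delta > -0.1 * abs(stats::coef(fit0)[2]) ||
      min(sse) > 0.9 * sum(stats::residuals(fit0)^2)) {
    return(NA_real_)
  }
  tb
}

# samples inside a phase interval
phase_window <- function(samples, phase) {
  tol <- 1e-9
  samples[samples$time_h >= phase$t_start - tol &
          samples$time_h <= phase$t_end + tol, , drop = FALSE]
}

# first/last measured sample inside the phase; rates are computed between
# measured samples (not interpolated boundary values) so that difference
# quotients with the log-mean biomass stay exact on exponential segments
phase_endpoints <- function(samples, phase) {
  w <- phase_window(samples, phase)
  if (nrow(w) >= 2L) {
    list(t1 = w$time_h[1], t2 = w$time_h[nrow(w)],
         s1 = w[1, , drop = FALSE], s2 = w[nrow(w), , drop = FALSE])
  } else {
    # fewer than two in-phase samples: fall back to interpolated bounds
    grab <- function(t) {
      cols <- setdiff(names(samples), "time_h")
      out <- as.data.frame(as.list(stats::setNames(
        vapply(cols, function(cc) series_at(samples, cc, t), 0), cols)))
      out$time_h <- t
      out
    }
    list(t1 = phase$t_start, t2 = phase$t_end,
         s1 = grab(phase$t_start), s2 = grab(phase$t_end))
  }
}

#' Specific growth rate within a phase
#'
#' Least-squares slope of `ln(DCW)` on time over the samples inside the
#' phase interval.
#'
#' @param series a [cultivation_series()].
#' @param phase one row of a [segment_phases()] result (or a list with
#'   `t_start` and `t_end`).
#' @return specific growth rate, 1/h.
#' @export
estimate_mu <- function(series, phase) {
  stopifnot(inherits(series, "cultivation_series"))
  s <- phase_window(series$samples, phase)
  s <- s[s$dcw_g_l > 0, , drop = FALSE]
  if (nrow(s) < 3L) stop("fewer than 3 in-phase samples with DCW > 0")
  unname(stats::coef(stats::lm(log(dcw_g_l) ~ time_h, data = s))[2])
}

compound_column <- function(compound) {
  switch(compound,
    xylose = "xylose_g_l", xylitol = "xylitol_g_l",
    arabitol = "arabitol_g_l", glucose = "glucose_g_l",
    stop("no concentration column mapped for compound: ", compound))
}

#' Specific conversion rate of a compound within a phase
#'
#' Computes `(delta concentration / delta time) / mean biomass` over a phase,
#' in molar units. The mean biomass is the logarithmic mean of the DCW at the
#' phase endpoints (exact for exponential growth). Consumption is reported as
#' positive uptake and secretion as positive production, with a direction
#' flag.
#'
#' @param series a [cultivation_series()].
#' @param phase one row of a [segment_phases()] result.
#' @param compound compound name present in the registry.
#' @param registry a [compound_registry()].
#' @param method `"endpoint"` (default): difference quotient over the
#'   first/last in-phase samples divided by the log-mean biomass;
#'   `"regression"`: slope of concentration against biomass over all
#'   in-phase samples times the phase growth rate. Both are exact for
#'   noise-free exponential segments; the regression pools all samples and
#'   is much less sensitive to concentration noise.
#' @export
specific_rate <- function(series, phase, compound,
                          registry = compound_registry(),
                          method = c("endpoint", "regression")) {
  stopifnot(inherits(series, "cultivation_series"))
  method <- match.arg(method)
  col <- compound_column(compound)
  s <- series$samples
  if (is.null(s[[col]])) stop("series lacks column ", col)
  mm <- reg_get(registry, compound, "molar_mass")
  signed <- specific_rate_mass(series, phase, col, method) / mm * 1000
  list(
    rate = abs(signed),
    direction = if (signed < 0) "uptake" else if (signed > 0) "production" else "none",
    signed = signed
  )
}

# signed specific conversion rate in g (or mg) per gDCW per h for any
# measured column
specific_rate_mass <- function(series, phase, col,
                               method = c("endpoint", "regression")) {
  method <- match.arg(method)
  s <- series$samples
  ep <- phase_endpoints(s, phase)
  x1 <- ep$s1$dcw_g_l; x2 <- ep$s2$dcw_g_l
  if (x1 <= 0 || x2 <= 0) stop("zero biomass in interval")
  if (method == "regression") {
    w <- phase_window(s, phase)
    w <- w[is.finite(w[[col]]) & w$dcw_g_l > 0, , drop = FALSE]
    # need samples and real biomass change, else fall back to endpoints
    if (nrow(w) >= 3L && (max(w$dcw_g_l) - min(w$dcw_g_l)) >
          0.15 * mean(w$dcw_g_l)) {
      mu <- stats::coef(stats::lm(log(dcw_g_l) ~ time_h, data = w))[2]
      slope <- stats::coef(stats::lm(w[[col]] ~ w$dcw_g_l))[2]
      return(unname(slope * mu))
    }
  }
  dt <- ep$t2 - ep$t1
  (ep$s2[[col]] - ep$s1[[col]]) / dt / log_mean(x1, x2)
}

#' Product yields and volumetric rates over a phase or whole batch
#'
#' For carotenoid (mg) and lipid (g) titres: yield on cell mass
#' `Y = delta product / delta DCW`, yield on substrate
#' `Y_S = delta product / total consumed carbon substrate (g)`, and
#' volumetric rate `q = delta product / delta time`. With `phase = NULL`
#' the whole batch (first to last sample) is used.
#'
#' @param series a [cultivation_series()].
#' @param phase one row of a [segment_phases()] result, or `NULL`.
#' @param registry a [compound_registry()].
#' @return data frame with one row per product and columns `product`,
#'   `delta_product`, `Y`, `Y_S`, `q`, `Y_flag`.
#' @export
yields_and_q <- function(series, phase = NULL, registry = compound_registry()) {
  s <- series$samples
  if (is.null(phase)) {
    phase <- list(t_start = s$time_h[1], t_end = s$time_h[nrow(s)])
  }
  ep <- phase_endpoints(s, phase)
  dx <- ep$s2$dcw_g_l - ep$s1$dcw_g_l
  dt <- ep$t2 - ep$t1
  substrates <- c("xylose_g_l", "xylitol_g_l", "arabitol_g_l", "glucose_g_l")
  dsub <- 0
  for (sc in substrates) {
    if (!is.null(s[[sc]])) {
      d <- ep$s1[[sc]] - ep$s2[[sc]]
      if (is.finite(d) && d > 0) dsub <- dsub + d   # consumed only
    }
  }
  rows <- lapply(c(carotenoid = "carotenoid_mg_l", lipid = "lipid_g_l"),
                 function(col) {
    if (is.null(s[[col]])) return(NULL)
    dp <- ep$s2[[col]] - ep$s1[[col]]
    flag <- if (dx <= 0) "dDCW<=0: Y undefined" else ""
    data.frame(
      delta_product = dp,
      Y = if (dx > 0) dp / dx else NA_real_,
      Y_S = if (dsub > 0) dp / dsub else NA_real_,
      q = dp / dt,
      Y_flag = flag,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  out <- cbind(product = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Assemble the full rate set for one phase
#'
#' @param series a [cultivation_series()].
#' @param phase one row of a [segment_phases()] result.
#' @param registry a [compound_registry()].
#' @param method rate estimator passed to [specific_rate()].
#' @return object of class `rate_set`.
#' @export
phase_rates <- function(series, phase, registry = compound_registry(),
                        method = "endpoint") {
  s <- series$samples
  ep <- phase_endpoints(s, phase)
  mu <- tryCatch(estimate_mu(series, phase), error = function(e) {
    # fall back to endpoint slope when fewer than 3 samples fall inside
    log(ep$s2$dcw_g_l / ep$s1$dcw_g_l) / (ep$t2 - ep$t1)
  })
  compounds <- c("xylose", "xylitol", "arabitol", "glucose")
  r <- list()
  for (cp in compounds) {
    col <- compound_column(cp)
    if (!is.null(s[[col]])) {
      r[[cp]] <- specific_rate(series, phase, cp, registry, method = method)
    }
  }
  x1 <- ep$s1$dcw_g_l; x2 <- ep$s2$dcw_g_l
  xbar <- log_mean(x1, x2)
  dt <- ep$t2 - ep$t1
  spec_prod <- function(col) {
    if (is.null(s[[col]])) return(NA_real_)
    specific_rate_mass(series, phase, col, method = method)
  }
  r_car <- spec_prod("carotenoid_mg_l")   # mg/gDCW/h
  r_lip <- spec_prod("lipid_g_l")         # g/gDCW/h
  co2 <- if (!is.null(s$co2_mmol_l_h)) {
    # the off-gas channel is an instantaneous volumetric rate, so the
    # specific rate is estimated pointwise (exact for proportional growth)
    w <- phase_window(s, phase)
    w <- w[w$dcw_g_l > 0 & is.finite(w$co2_mmol_l_h), , drop = FALSE]
    if (nrow(w)) mean(w$co2_mmol_l_h / w$dcw_g_l) else NA_real_
  } else NA_real_
  y <- yields_and_q(series, phase, registry)
  out <- list(
    phase = phase, mu = mu, r = r, r_car = r_car, r_lip = r_lip,
    r_co2 = co2, yields = y, mean_dcw = xbar,
    yield_biomass = {
      dsub <- sum(vapply(compounds, function(cp) {
        col <- compound_column(cp)
        if (is.null(s[[col]])) return(0)
        d <- ep$s1[[col]] - ep$s2[[col]]
        if (is.finite(d) && d > 0) d else 0
      }, 0))
      if (dsub > 0) (x2 - x1) / dsub else NA_real_
    }
  )
  class(out) <- "rate_set"
  out
}

#' Carbon balance of a phase rate set
#'
#' Fraction of consumed substrate carbon recovered in biomass, secreted
#' polyols, intracellular lipid and carotenoid, and CO2. Lipid carbon uses
#' the average triacylglyceride formula and carotenoid carbon the
#' beta-carotene formula from the registry; non-product biomass carbon uses
#' the registry's biomass carbon content. Lipid and carotenoid mass is
#' subtracted from the DCW term so product carbon is not double-counted.
#'
#' @param rateset a [phase_rates()] result.
#' @param registry a [compound_registry()].
#' @param biomass_carbon carbon content of non-lipid biomass, g-C/gDCW;
#'   defaults to the registry attribute.
#' @return list with `recovery` (fraction) and `flag` (`"co2_less"` when no
#'   CO2 rate was available).
#' @export
carbon_balance <- function(rateset, registry = compound_registry(),
                           biomass_carbon = NULL) {
  stopifnot(inherits(rateset, "rate_set"))
  if (is.null(biomass_carbon)) biomass_carbon <- attr(registry, "biomass_carbon")
  mmolC <- function(compound, mmol) mmol * reg_get(registry, compound, "carbon")
  c_in <- 0; c_out <- 0
  for (cp in names(rateset$r)) {
    rr <- rateset$r[[cp]]
    if (rr$direction == "uptake") c_in <- c_in + mmolC(cp, rr$rate)
    if (rr$direction == "production") c_out <- c_out + mmolC(cp, rr$rate)
  }
  if (c_in <= 0) stop("no substrate consumption in rate set")
  r_lip <- if (is.finite(rateset$r_lip)) max(rateset$r_lip, 0) else 0
  r_car_g <- if (is.finite(rateset$r_car)) max(rateset$r_car, 0) / 1000 else 0
  mu_rest <- rateset$mu - r_lip - r_car_g
  c_out <- c_out + mu_rest * biomass_carbon / 12.011 * 1000
  c_out <- c_out + r_lip * reg_get(registry, "lipid", "carbon") /
    reg_get(registry, "lipid", "molar_mass") * 1000
  c_out <- c_out + r_car_g * reg_get(registry, "carotenoid", "carbon") /
    reg_get(registry, "carotenoid", "molar_mass") * 1000
  flag <- ""
  if (is.finite(rateset$r_co2)) {
    c_out <- c_out + rateset$r_co2
  } else {
    flag <- "co2_less"
  }
  list(recovery = c_out / c_in, flag = flag)
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("Rate set for %s [%.1f, %.1f] h\n",
              x$phase$label %||% "phase", x$phase$t_start, x$phase$t_end))
  cat(sprintf("  mu = %.4g 1/h; mean DCW = %.3g g/L\n", x$mu, x$mean_dcw))
  for (cp in names(x$r)) {
    cat(sprintf("  %-9s %-10s %.3g mmol/gDCW/h\n", cp, x$r[[cp]]$direction,
                x$r[[cp]]$rate))
  }
  if (is.finite(x$r_car)) cat(sprintf("  r_CAR = %.3g mg/gDCW/h\n", x$r_car))
  if (is.finite(x$r_lip)) cat(sprintf("  r_LIP = %.3g g/gDCW/h\n", x$r_lip))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
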