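# synthetic-data generator: three-phase batch kinetics and labelled-standard
# proteomics with stored ground truth
#
# The cultivation generator integrates a deterministic mass balance with
# exhaustion-triggered phase switches (nitrogen first, then xylose) and
# computes the CO2 evolution as the closing term of the carbon balance, so
# noise-free output is exactly carbon-closed. Measurement noise is
# multiplicative log-normal per channel.

#' Configuration of the synthetic cultivation generator
#'
#' Defaults mirror the reference batch condition: 70 g/L xylose with
#' nitrogen set for a molar C/N of ~80, a P1 specific growth rate of
#' 0.060 1/h with xylose uptake 1.74 mmol/gDCW/h, nitrogen-limited P2
#' (0.020 1/h, 0.41 mmol/gDCW/h), and slow polyol-consuming P3
#' (0.005 1/h). About 30% of consumed xylose carbon is secreted as
#' arabitol plus xylitol (2:1 by mass).
#'
#' @param xylose_g_l initial xylose, g/L.
#' @param ammonium_sulfate_g_l initial (NH4)2SO4, g/L.
#' @param x0 inoculum dry mass, g/L.
#' @param t_final simulated batch length, h.
#' @param sample_interval_h off-line sampling interval, h.
#' @param euler_step integration step, h (<= 0.1).
#' @param biomass_n_fraction nitrogen incorporated per gram biomass,
#'   mol-N/gDCW; the default equals the measured nitrogen-excess protein
#'   content (0.48 g/gDCW at 16% N), which places nitrogen exhaustion
#'   after ~23 g/L xylose consumed in the default medium.
#' @param mu,r_xyl per-phase growth and xylose uptake (P1, P2); `mu[3]` is
#'   the P3 growth rate.
#' @param r_xlt_p3,r_abt_p3 P3 polyol consumption rates, mmol/gDCW/h.
#' @param y_xlt,y_abt secretion yields, g polyol per g xylose (P1 and P2).
#' @param r_car per-phase specific carotenoid production, mg/gDCW/h.
#' @param r_lip per-phase specific lipid production, g/gDCW/h.
#' @param car0,lip0 initial intracellular contents (mg/gDCW, g/gDCW).
#' @param unmeasured_fraction fraction of consumed carbon routed to an
#'   unmeasured product instead of CO2 (0 = carbon-closed output).
#' @param depletion_threshold xylose level (g/L) triggering the P2/P3
#'   switch.
#' @param cv_dcw,cv_conc,cv_titre multiplicative noise CVs for DCW, HPLC
#'   concentrations and product titres (defaults 2%, 3%, 5%).
#' @param mu_decay optional first-order decay of the P2 growth rate (1/h);
#'   0 keeps the plain step change.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(xylose_g_l = 70, ammonium_sulfate_g_l = 1.95,
                             x0 = 0.1, t_final = 192, sample_interval_h = 24,
                             euler_step = 0.05,
                             biomass_n_fraction = 0.00548,
                             mu = c(0.060, 0.020, 0.005),
                             r_xyl = c(1.74, 0.41),
                             r_xlt_p3 = 0.025, r_abt_p3 = 0.055,
                             y_xlt = 0.10, y_abt = 0.20,
                             r_car = c(0.042, 0.0105, 0.009),
                             r_lip = c(0.0108, 0.010, 0.0019),
                             car0 = 0.5, lip0 = 0.18,
                             unmeasured_fraction = 0,
                             depletion_threshold = 0.5,
                             cv_dcw = 0.02, cv_conc = 0.03, cv_titre = 0.05,
                             mu_decay = 0) {
  if (xylose_g_l <= 0) stop("config needs a positive substrate concentration")
  stopifnot(all(mu >= 0), all(r_xyl >= 0), y_xlt >= 0, y_abt >= 0,
            euler_step <= 0.1, unmeasured_fraction >= 0,
            unmeasured_fraction < 1)
  structure(as.list(environment()), class = "generator_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# carbon bookkeeping constants (mmol C per unit)
GEN_C <- list(
  xyl_per_g = 5 / 150.13 * 1000,       # mmol C per g xylose
  polyol_per_g = 5 / 152.146 * 1000,   # mmol C per g xylitol/arabitol
  biomass_per_g = 0.48 / 12.011 * 1000,
  lipid_per_g = 57 / 885.453 * 1000,
  car_per_g = 40 / 536.888 * 1000
)

#' Generate a synthetic batch cultivation
#'
#' Simulates the three-phase batch by forward Euler integration with
#' exhaustion-triggered phase switches, samples it at the configured
#' interval, applies multiplicative measurement noise, and returns the
#' series together with the ground truth (noise-free series, switch times
#' and true per-phase rates).
#'
#' @param config a [generator_config()].
#' @param seed RNG seed for the measurement noise.
#' @param noise logical; `FALSE` returns the noise-free series.
#' @return list with `series` (a [cultivation_series()]) and `truth`.
#' @export
generate_cultivation <- function(config = generator_config(), seed = 42,
                                 noise = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  cg <- config
  dt <- cg$euler_step
  n_steps <- ceiling(cg$t_final / dt)
  mm_as <- molar_mass("(NH4)2SO4")
  n_avail <- cg$ammonium_sulfate_g_l / mm_as * 2   # mol N / L
  # state
  X <- cg$x0; S <- cg$xylose_g_l; XLT <- 0; ABT <- 0
  CAR <- cg$car0 * cg$x0; LIP <- cg$lip0 * cg$x0
  NH4 <- cg$ammonium_sulfate_g_l
  n_used <- 0
  phase <- 1L
  t_n <- NA_real_; t_dep <- NA_real_; consumed_at_n <- NA_real_
  t <- 0
  rows <- vector("list", n_steps + 1L)
  co2_rate <- 0
  store <- function(i, t) {
    rows[[i]] <<- c(time_h = t, dcw_g_l = X, xylose_g_l = S,
                    xylitol_g_l = XLT, arabitol_g_l = ABT,
                    carotenoid_mg_l = CAR, lipid_g_l = LIP,
                    co2_mmol_l_h = co2_rate, nh4_g_l = NH4)
  }
  mm_xyl <- 150.13
  for (i in seq_len(n_steps + 1L)) {
    # instantaneous rates for the current phase
    if (phase <= 2L) {
      mu_t <- cg$mu[phase]
      if (phase == 2L && cg$mu_decay > 0) {
        mu_t <- mu_t * exp(-cg$mu_decay * (t - t_n))
      }
      # a nonzero unmeasured fraction inflates total consumption: the
      # measured pools are fed by the (1 - f) share that is metabolised
      # to quantified products, the rest leaves the carbon balance
      q_xyl_met <- cg$r_xyl[phase] * mm_xyl / 1000 * X   # g/L/h
      q_xyl <- min(q_xyl_met / (1 - cg$unmeasured_fraction), S / dt)
      q_xyl_met <- q_xyl * (1 - cg$unmeasured_fraction)
      q_xlt <- cg$y_xlt * q_xyl_met
      q_abt <- cg$y_abt * q_xyl_met
      q_xlt_in <- 0; q_abt_in <- 0
      r_car_t <- cg$r_car[phase]; r_lip_t <- cg$r_lip[phase]
      c_in <- q_xyl_met * GEN_C$xyl_per_g
    } else {
      depleted <- (XLT + ABT) < 0.05
      mu_t <- if (depleted) 0 else cg$mu[3]
      q_xyl <- 0; q_xlt <- 0; q_abt <- 0
      q_xlt_in <- if (depleted) 0 else
        min(cg$r_xlt_p3 * 152.146 / 1000 * X, XLT / dt)
      q_abt_in <- if (depleted) 0 else
        min(cg$r_abt_p3 * 152.146 / 1000 * X, ABT / dt)
      r_car_t <- if (depleted) 0 else cg$r_car[3]
      r_lip_t <- if (depleted) 0 else cg$r_lip[3]
      c_in <- (q_xlt_in + q_abt_in) * GEN_C$polyol_per_g
    }
    dX <- mu_t * X
    d_lip <- r_lip_t * X
    d_car <- r_car_t * X            # mg/L/h
    c_out_fixed <- (dX - d_lip - d_car / 1000) * GEN_C$biomass_per_g +
      d_lip * GEN_C$lipid_per_g + d_car / 1000 * GEN_C$car_per_g +
      (q_xlt + q_abt) * GEN_C$polyol_per_g
    co2_rate <- max(c_in - c_out_fixed, 0)
    store(i, t)
    if (i == n_steps + 1L) break
    # integrate: biomass advances exactly (exponential step); pools use
    # the exact integral of X over the step (delta X / mu), so sampled
    # noise-free output is closed to machine precision
    X_new <- X * exp(mu_t * dt)
    intX <- if (mu_t > 0) (X_new - X) / mu_t else X * dt
    per_x <- function(q) if (X > 0) q / X * intX else 0
    S <- max(S - per_x(q_xyl), 0)
    XLT <- max(XLT + per_x(q_xlt - q_xlt_in), 0)
    ABT <- max(ABT + per_x(q_abt - q_abt_in), 0)
    CAR <- CAR + per_x(d_car)
    LIP <- LIP + per_x(d_lip)
    n_used <- n_used + (X_new - X) * cg$biomass_n_fraction   # mol N /L
    X <- X_new
    NH4 <- max(cg$ammonium_sulfate_g_l - n_used * mm_as / 2, 0)
    t <- t + dt
    if (phase == 1L && n_used >= n_avail) {
      phase <- 2L; t_n <- t
      consumed_at_n <- cg$xylose_g_l - S
    }
    if (phase <= 2L && S <= cg$depletion_threshold) {
      if (is.na(t_n)) { t_n <- t }   # degenerate: carbon ran out first
      phase <- 3L; t_dep <- t
    }
  }
  sim <- as.data.frame(do.call(rbind, rows))
  keep <- sim$time_h %% cg$sample_interval_h < dt / 2 |
    cg$sample_interval_h - sim$time_h %% cg$sample_interval_h < dt / 2
  clean <- sim[keep, , drop = FALSE]
  clean <- clean[!duplicated(round(clean$time_h / cg$sample_interval_h)), ]
  rownames(clean) <- NULL
  noisy <- clean
  if (noise) {
    noisy <- with_seed(seed, {
      sdlog <- function(cv) sqrt(log(1 + cv^2))
      jitter_col <- function(x, cv) x * exp(stats::rnorm(length(x), 0,
                                                         sdlog(cv)))
      out <- clean
      out$dcw_g_l <- jitter_col(out$dcw_g_l, cg$cv_dcw)
      for (cc in c("xylose_g_l", "xylitol_g_l", "arabitol_g_l", "nh4_g_l")) {
        out[[cc]] <- jitter_col(out[[cc]], cg$cv_conc)
      }
      for (cc in c("carotenoid_mg_l", "lipid_g_l", "co2_mmol_l_h")) {
        out[[cc]] <- jitter_col(out[[cc]], cg$cv_titre)
      }
      out
    })
  }
  series <- cultivation_series(noisy, condition_label = "SYN-REF",
                               replicate = 1L)
  y_biomass <- cg$mu[1:2] / (cg$r_xyl * mm_xyl / 1000)
  truth <- list(
    t_nitrogen = t_n, t_xylose_depletion = t_dep,
    xylose_consumed_at_nitrogen = consumed_at_n,
    mu = cg$mu, r_xyl = cg$r_xyl,
    r_xlt_p3 = cg$r_xlt_p3, r_abt_p3 = cg$r_abt_p3,
    yield_biomass = y_biomass,
    y_xlt = cg$y_xlt, y_abt = cg$y_abt,
    r_car = cg$r_car, r_lip = cg$r_lip,
    medium_nitrogen_mol = n_avail,
    biomass_n_fraction = cg$biomass_n_fraction,
    clean_series = cultivation_series(clean, condition_label = "SYN-REF-clean",
                                      replicate = 1L),
    config = cg, seed = seed
  )
  list(series = series, truth = truth)
}

#' Configuration of the synthetic proteome generator
#'
#' @param n_proteins number of quantified proteins (default 3000).
#' @param conditions condition labels (>= 2).
#' @param replicates replicates per condition (default 3).
#' @param meanlog,sdlog log-normal parameters of base intensities.
#' @param cv multiplicative measurement noise CV on each channel.
#' @param affected list of affected sets, each
#'   `list(proteins = <ids or count>, log2fc = <effect>, condition =
#'   <label>)`; effects apply to the light channel of that condition.
#' @return list of class `proteome_config`.
#' @export
proteome_config <- function(n_proteins = 3000,
                            conditions = c("N_excess", "N_limited"),
                            replicates = 3,
                            meanlog = 10, sdlog = 1.5, cv = 0.2,
                            affected = list(list(proteins = 100, log2fc = 2,
                                                 condition = "N_limited"))) {
  stopifnot(length(conditions) >= 2, replicates >= 1)
  structure(as.list(environment()), class = "proteome_config")
}

#' Generate a synthetic labelled-standard proteomics table
#'
#' Draws log-normal base abundances per protein, applies the configured
#' log2 effects to the affected sets in their target conditions, and emits
#' light/heavy intensity pairs where the heavy channel is the common 1:1
#' internal standard (base intensity, no condition effect) and both
#' channels carry multiplicative log-normal noise.
#'
#' @param config a [proteome_config()].
#' @param seed RNG seed.
#' @return list with `intensities` (data frame: protein_id, condition,
#'   replicate, light_intensity, heavy_intensity) and `truth` (base mass
#'   fractions, affected protein ids and effects).
#' @export
generate_proteome <- function(config = proteome_config(), seed = 42) {
  stopifnot(inherits(config, "proteome_config"))
  cg <- config
  ids <- sprintf("P%04d", seq_len(cg$n_proteins))
  # resolve affected sets; reject conflicting overlaps
  effects <- list()
  assigned <- list()
  next_free <- 1L
  for (aset in cg$affected) {
    if (!aset$condition %in% cg$conditions) {
      stop("affected set targets unknown condition: ", aset$condition)
    }
    prot <- aset$proteins
    if (is.numeric(prot) && length(prot) == 1L) {
      prot <- ids[seq.int(next_free, length.out = prot)]
      next_free <- next_free + length(prot)
    }
    key <- aset$condition
    overlap <- intersect(prot, names(assigned[[key]] %||% c()))
    if (length(overlap)) {
      conflicting <- assigned[[key]][overlap] != aset$log2fc
      if (any(conflicting)) {
        stop("overlapping affected sets with conflicting effects for ",
             key, ": ", paste(overlap[conflicting][1], collapse = ", "))
      }
    }
    assigned[[key]] <- c(assigned[[key]],
                         stats::setNames(rep(aset$log2fc, length(prot)), prot))
    effects[[length(effects) + 1L]] <- list(proteins = prot,
                                            log2fc = aset$log2fc,
                                            condition = aset$condition)
  }
  with_seed(seed, {
    base <- stats::rlnorm(cg$n_proteins, cg$meanlog, cg$sdlog)
    names(base) <- ids
    sdl <- sqrt(log(1 + cg$cv^2))
    rows <- list()
    for (cond in cg$conditions) {
      lfc <- rep(0, cg$n_proteins); names(lfc) <- ids
      fx <- assigned[[cond]]
      if (!is.null(fx)) lfc[names(fx)] <- fx
      mean_light <- base * 2^lfc
      for (rep_i in seq_len(cg$replicates)) {
        light <- mean_light * exp(stats::rnorm(cg$n_proteins, 0, sdl))
        heavy <- base * exp(stats::rnorm(cg$n_proteins, 0, sdl))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = ids, condition = cond, replicate = rep_i,
          light_intensity = light, heavy_intensity = heavy,
          stringsAsFactors = FALSE)
      }
    }
    intensities <- do.call(rbind, rows)
    rownames(intensities) <- NULL
    truth <- list(
      base_intensity = base,
      mass_fraction = base / sum(base),
      effects = effects,
      affected_by_condition = assigned,
      config = cg, seed = seed
    )
    list(intensities = intensities, truth = truth)
  })
}
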