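# constraint-based analyses: NGAM-maximising FBA, FVA, flux sampling,
# carbon-normalised comparison, cofactor shares and branch partitions

EXCHANGE_BY_COMPOUND <- c(
  xylose = "EX_xyl", xylitol = "EX_xlt", arabitol = "EX_abt",
  glucose = "EX_glc", glycerol = "EX_glyc", nh3 = "EX_nh3",
  o2 = "EX_o2", co2 = "EX_co2", biomass = "EX_biomass"
)

#' Measured-rate constraints for one growth phase
#'
#' @param mu fixed specific growth rate, 1/h.
#' @param uptake named vector of measured uptake rates (positive,
#'   mmol/gDCW/h) by compound name.
#' @param secretion named vector of measured secretion rates (positive,
#'   mmol/gDCW/h).
#' @param sd optional named vector of reported standard deviations used as
#'   tolerances.
#' @param tol_rel relative tolerance applied when no SD is given
#'   (default 5%).
#' @param secretion_mode `"fixed"` (rate within value +/- tolerance) or
#'   `"upper"` (rate anywhere in `[0, value + tolerance]`).
#' @return object of class `phase_constraints`.
#' @export
phase_constraints <- function(mu, uptake = c(), secretion = c(), sd = c(),
                              tol_rel = 0.05,
                              secretion_mode = c("fixed", "upper")) {
  secretion_mode <- match.arg(secretion_mode)
  stopifnot(is.finite(mu), mu >= 0, all(uptake >= 0), all(secretion >= 0))
  structure(list(mu = mu, uptake = uptake, secretion = secretion, sd = sd,
                 tol_rel = tol_rel, secretion_mode = secretion_mode),
            class = "phase_constraints")
}

constraint_tol <- function(constraints, compound, value) {
  s <- constraints$sd[compound]
  s <- if (length(s) == 1 && is.finite(s)) s else 0
  max(s, constraints$tol_rel * abs(value))
}

#' Apply phase constraints to a model
#'
#' Fixes the growth rate and bounds each measured exchange within its
#' tolerance; uptake is encoded as negative exchange flux.
#'
#' @param model a [core_model()].
#' @param constraints a [phase_constraints()].
#' @return bounded model, with the constrained exchange ids recorded in
#'   `attr(, "measured")`.
#' @export
apply_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "core_model"),
            inherits(constraints, "phase_constraints"))
  measured <- character(0)
  model <- set_bounds(model, "EX_biomass", lb = constraints$mu,
                      ub = constraints$mu)
  measured <- "EX_biomass"
  for (cp in names(constraints$uptake)) {
    ex <- EXCHANGE_BY_COMPOUND[cp]
    if (is.na(ex) || !ex %in% names(model$reactions)) {
      stop("no exchange reaction for constrained compound: ", cp)
    }
    v <- constraints$uptake[[cp]]
    tol <- constraint_tol(constraints, cp, v)
    model <- set_bounds(model, ex, lb = -(v + tol), ub = -(max(v - tol, 0)))
    measured <- c(measured, ex)
  }
  # polyol-consuming phase: enable the arabitol catabolic lump (shut by
  # default to keep the production/catabolism pair from cycling)
  if ("arabitol" %in% names(constraints$uptake) &&
      "ABTCAT" %in% names(model$reactions)) {
    model <- set_bounds(model, "ABTCAT", ub = 1000)
  }
  for (cp in names(constraints$secretion)) {
    ex <- EXCHANGE_BY_COMPOUND[cp]
    if (is.na(ex) || !ex %in% names(model$reactions)) {
      stop("no exchange reaction for constrained compound: ", cp)
    }
    v <- constraints$secretion[[cp]]
    tol <- constraint_tol(constraints, cp, v)
    lo <- if (constraints$secretion_mode == "fixed") max(v - tol, 0) else 0
    model <- set_bounds(model, ex, lb = lo, ub = v + tol)
    measured <- c(measured, ex)
  }
  attr(model, "measured") <- measured
  model
}

#' Flux balance analysis maximising non-growth ATP maintenance
#'
#' Solves `max v_NGAM` subject to steady state, bounds, the fixed growth
#' rate and the measured exchange windows, then selects a unique flux
#' vector by a parsimonious secondary step (minimum total absolute flux at
#' the NGAM optimum). On infeasibility the measured constraints are relaxed
#' one at a time to name the conflicting set.
#'
#' @param model a [core_model()].
#' @param constraints a [phase_constraints()], or `NULL` if the model is
#'   already bounded.
#' @return object of class `flux_solution` with fields `flux` (named),
#'   `objective_value` (mmol ATP/gDCW/h), `status`, and `iis_hint` on
#'   infeasibility.
#' @export
maximize_ngam <- function(model, constraints = NULL) {
  orig <- model
  if (!is.null(constraints)) model <- apply_constraints(model, constraints)
  sol <- lp_optimize_reaction(model, model$ngam_reaction_id, maximize = TRUE)
  if (sol$status != "optimal") {
    hint <- character(0)
    measured <- attr(model, "measured") %||% character(0)
    for (ex in measured) {
      relaxed <- model
      relaxed$reactions[[ex]]$lb <- orig$reactions[[ex]]$lb
      relaxed$reactions[[ex]]$ub <- orig$reactions[[ex]]$ub
      if (ex == "EX_biomass") {
        relaxed$reactions[[ex]]$lb <- 0
        relaxed$reactions[[ex]]$ub <- 1000
      }
      s2 <- lp_optimize_reaction(relaxed, model$ngam_reaction_id)
      if (s2$status == "optimal") hint <- c(hint, ex)
    }
    out <- list(flux = NULL, objective_value = NA_real_, status = sol$status,
                iis_hint = hint, model = model)
    class(out) <- "flux_solution"
    return(out)
  }
  ngam_opt <- sol$value
  p <- pfba_min_total_flux(model, fix_reaction = model$ngam_reaction_id,
                           fix_value = ngam_opt)
  flux <- if (p$status == "optimal") unlist(p$flux) else sol$solution
  out <- list(flux = flux, objective_value = ngam_opt, status = "optimal",
              iis_hint = character(0), model = model)
  class(out) <- "flux_solution"
  out
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  NGAM objective: %.4g mmol ATP/gDCW/h\n", x$objective_value))
    nz <- sum(abs(x$flux) > 1e-9)
    cat(sprintf("  %d of %d reactions carry flux\n", nz, length(x$flux)))
  } else if (length(x$iis_hint)) {
    cat("  conflicting measured constraints:",
        paste(x$iis_hint, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under the model's current bounds.
#'
#' @param model a bounded [core_model()] (e.g. after [apply_constraints()]
#'   and fixing the NGAM floor).
#' @param reactions reaction ids (default all).
#' @return data frame with columns `reaction`, `min`, `max`, plus the
#'   optimal solutions as attribute `"vertices"` (matrix, one row per LP).
#' @export
fva <- function(model, reactions = names(model$reactions)) {
  S <- stoich_matrix(model)
  b <- reaction_bounds(model)
  verts <- list()
  warm <- NULL
  res <- lapply(reactions, function(rid) {
    obj <- as.numeric(names(model$reactions) == rid)
    lo <- solve_lp(obj, S, lb = b$lb, ub = b$ub, maximize = FALSE,
                   warm = warm)
    if (lo$status == "optimal") warm <<- attr(lo, "warm")
    hi <- solve_lp(obj, S, lb = b$lb, ub = b$ub, maximize = TRUE,
                   warm = warm)
    if (hi$status == "optimal") warm <<- attr(hi, "warm")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for ", rid, " (", lo$status, "/",
           hi$status, ")")
    }
    verts[[length(verts) + 1L]] <<- lo$solution
    verts[[length(verts) + 1L]] <<- hi$solution
    c(lo$value, hi$value)
  })
  out <- data.frame(reaction = reactions,
                    min = vapply(res, `[`, 0, 1),
                    max = vapply(res, `[`, 0, 2),
                    stringsAsFactors = FALSE)
  attr(out, "vertices") <- do.call(rbind, verts)
  out
}

#' Random flux sampling at a fraction of the maximal NGAM
#'
#' Constrains the NGAM reaction to at least `ngam_fraction` of its maximum,
#' then samples the resulting flux polytope with an artificial-centering
#' hit-and-run walk seeded from the FVA vertex solutions. Deterministic for
#' a fixed seed.
#'
#' @param model a [core_model()].
#' @param constraints a [phase_constraints()], or `NULL`.
#' @param ngam_fraction NGAM floor as a fraction of the maximum
#'   (default 0.95).
#' @param n number of samples (default 5000).
#' @param seed RNG seed.
#' @param thin record every `thin`-th step (default 10).
#' @param warmup_per_dim discarded warm-up steps per polytope dimension
#'   (default 100).
#' @return object of class `flux_ensemble`: list with `samples`
#'   (n x reactions matrix), `ngam_fraction`, `n`, `seed`, `fva` ranges and
#'   `degenerate` flag.
#' @export
sample_fluxes <- function(model, constraints = NULL, ngam_fraction = 0.95,
                          n = 5000, seed = 1L, thin = 10,
                          warmup_per_dim = 100) {
  base <- maximize_ngam(model, constraints)
  if (base$status != "optimal") stop("NGAM maximisation not optimal; cannot sample")
  bounded <- base$model
  bounded <- set_bounds(bounded, bounded$ngam_reaction_id,
                        lb = ngam_fraction * base$objective_value)
  rng <- fva(bounded)
  verts <- attr(rng, "vertices")
  width <- rng$max - rng$min
  degenerate <- max(width) < 1e-6
  rxn_ids <- names(bounded$reactions)
  if (degenerate) {
    warning("sampling polytope has zero volume; returning FVA vertex solutions")
    samples <- matrix(rep(colMeans(verts), each = n), nrow = n,
                      dimnames = list(NULL, rxn_ids))
    out <- list(samples = samples, ngam_fraction = ngam_fraction, n = n,
                seed = seed, fva = rng, degenerate = TRUE)
    class(out) <- "flux_ensemble"
    return(out)
  }
  S <- stoich_matrix(bounded)
  b <- reaction_bounds(bounded)
  N <- MASS::Null(t(S))      # orthonormal basis of {v : S v = 0}
  if (ncol(N) == 0) stop("model has an empty null space")
  A <- verts %*% N           # warm-up points in null-space coordinates
  k <- ncol(N)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  center <- colMeans(A)
  cur <- A[1, ]
  n_steps <- warmup_per_dim * k + n * thin
  samples <- matrix(NA_real_, n, length(rxn_ids),
                    dimnames = list(NULL, rxn_ids))
  recorded <- 0L
  tol <- 1e-9
  for (step in seq_len(n_steps)) {
    w <- A[sample.int(nrow(A), 1L), ]
    d <- w - center
    nd <- sqrt(sum(d * d))
    if (nd < 1e-12) next
    d <- d / nd
    dv <- as.numeric(N %*% d)
    v <- as.numeric(N %*% cur)
    lo <- -Inf; hi <- Inf
    act <- abs(dv) > 1e-10
    if (any(act)) {
      t1 <- (b$lb[act] - v[act]) / dv[act]
      t2 <- (b$ub[act] - v[act]) / dv[act]
      lo <- max(pmin(t1, t2))
      hi <- min(pmax(t1, t2))
    }
    if (!is.finite(lo) || !is.finite(hi) || hi - lo < tol) next
    lo <- min(lo, 0); hi <- max(hi, 0)
    theta <- stats::runif(1, lo, hi)
    cur <- cur + theta * d
    center <- center + (cur - center) / (nrow(A) + step)
    if (step > warmup_per_dim * k && (step - warmup_per_dim * k) %% thin == 0) {
      recorded <- recorded + 1L
      samples[recorded, ] <- as.numeric(N %*% cur)
      if (recorded == n) break
    }
  }
  if (recorded < n) samples <- samples[seq_len(recorded), , drop = FALSE]
  out <- list(samples = samples, ngam_fraction = ngam_fraction, n = n,
              seed = seed, fva = rng, degenerate = FALSE)
  class(out) <- "flux_ensemble"
  out
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf("Flux ensemble: %d samples x %d reactions (NGAM >= %.0f%% of max%s)\n",
              nrow(x$samples), ncol(x$samples), 100 * x$ngam_fraction,
              if (x$degenerate) "; degenerate polytope" else ""))
  invisible(x)
}

#' Normalise fluxes by total carbon uptake
#'
#' Divides every flux by the total carbon uptake rate (C-mmol/gDCW/h: the
#' sum over consumed exchange metabolites of uptake rate times carbon atoms
#' per molecule), so phases with different substrate mixes are comparable.
#' The absolute substrate uptake rates are kept alongside.
#'
#' @param solution a `flux_solution` (or a named flux vector).
#' @param model the [core_model()] the fluxes belong to (defaults to the
#'   model stored in the solution).
#' @return list with `normalized` (named fluxes per C-mmol),
#'   `carbon_uptake` (C-mmol/gDCW/h) and `absolute_uptake` (named,
#'   mmol/gDCW/h).
#' @export
normalize_by_carbon <- function(solution, model = NULL) {
  if (inherits(solution, "flux_solution")) {
    if (is.null(model)) model <- solution$model
    flux <- solution$flux
  } else {
    flux <- solution
  }
  stopifnot(inherits(model, "core_model"), !is.null(flux))
  carbon <- met_carbon_counts(model)
  uptake <- c()
  total_c <- 0
  for (ex in exchange_reactions(model)) {
    v <- flux[[ex]]
    if (is.null(v) || is.na(v) || v >= -1e-9) next
    met <- names(model$reactions[[ex]]$mets)
    nc <- carbon[[met]]
    if (is.na(nc) || nc == 0) next
    uptake[ex] <- -v
    total_c <- total_c + (-v) * nc
  }
  if (total_c <= 1e-12) stop("no carbon uptake in solution")
  list(normalized = unlist(flux) / total_c, carbon_uptake = total_c,
       absolute_uptake = uptake)
}

met_carbon_counts <- function(model) {
  out <- vapply(model$metabolites$formula, function(f) {
    if (!nzchar(f)) return(NA_real_)
    cc <- parse_formula(f)
    if ("C" %in% names(cc)) cc[["C"]] else 0
  }, 0, USE.NAMES = FALSE)
  stats::setNames(out, model$metabolites$id)
}

#' Producer and consumer shares of a cofactor
#'
#' Classifies every reaction by its signed cofactor stoichiometry times
#' flux and reports each reaction's fraction of total production and total
#' consumption.
#'
#' @param solution a `flux_solution`.
#' @param cofactor metabolite id (e.g. `"nadph_c"`).
#' @param model model; defaults to the one stored in the solution.
#' @return object of class `cofactor_shares` with `producers`, `consumers`
#'   (named fraction vectors), `total_turnover` and `flag`.
#' @export
cofactor_shares <- function(solution, cofactor, model = NULL) {
  if (is.null(model)) model <- solution$model
  stopifnot(inherits(model, "core_model"))
  if (!cofactor %in% model$metabolites$id) stop("unknown metabolite: ", cofactor)
  rate <- vapply(model$reactions, function(r) {
    s <- r$mets[match(cofactor, names(r$mets))]
    if (is.na(s)) 0 else s * (solution$flux[[r$id]] %||% 0)
  }, 0)
  prod <- rate[rate > 1e-9]
  cons <- -rate[rate < -1e-9]
  turnover <- sum(prod)
  if (turnover < 1e-9) {
    return(structure(list(cofactor = cofactor, producers = numeric(0),
                          consumers = numeric(0), total_turnover = 0,
                          flag = "zero turnover"),
                     class = "cofactor_shares"))
  }
  structure(list(cofactor = cofactor,
                 producers = sort(prod / sum(prod), decreasing = TRUE),
                 consumers = sort(cons / sum(cons), decreasing = TRUE),
                 total_turnover = turnover, flag = ""),
            class = "cofactor_shares")
}

#' @export
print.cofactor_shares <- function(x, ...) {
  cat("Cofactor shares for", x$cofactor, "\n")
  if (nzchar(x$flag)) { cat(" ", x$flag, "\n"); return(invisible(x)) }
  cat(sprintf("  turnover: %.4g mmol/gDCW/h\n", x$total_turnover))
  cat("  producers:\n")
  for (i in seq_along(x$producers)) {
    cat(sprintf("    %-12s %5.1f%%\n", names(x$producers)[i],
                100 * x$producers[i]))
  }
  invisible(x)
}

#' Carbon partition at a branch-point metabolite
#'
#' Fractional split of the flux through a metabolite node over its
#' consuming reactions (or producing reactions with `mode = "sources"`),
#' accounting for reaction direction.
#'
#' @param solution a `flux_solution`.
#' @param metabolite metabolite id.
#' @param mode `"consumers"` (default) or `"sources"`.
#' @param model model; defaults to the one stored in the solution.
#' @return object of class `branch_partition`: named fractions summing
#'   to 1.
#' @export
branch_partition <- function(solution, metabolite,
                             mode = c("consumers", "sources"), model = NULL) {
  mode <- match.arg(mode)
  if (is.null(model)) model <- solution$model
  if (!metabolite %in% model$metabolites$id) stop("unknown metabolite: ",
                                                  metabolite)
  rate <- vapply(model$reactions, function(r) {
    s <- r$mets[match(metabolite, names(r$mets))]
    if (is.na(s)) 0 else s * (solution$flux[[r$id]] %||% 0)
  }, 0)
  flow <- if (mode == "consumers") -rate[rate < -1e-9] else rate[rate > 1e-9]
  if (!length(flow) || sum(flow) < 1e-9) {
    stop("no flux through node ", metabolite)
  }
  structure(list(metabolite = metabolite, mode = mode,
                 fractions = sort(flow / sum(flow), decreasing = TRUE),
                 total = sum(flow)),
            class = "branch_partition")
}

#' @export
print.branch_partition <- function(x, ...) {
  cat(sprintf("Branch partition at %s (%s, total %.4g mmol/gDCW/h)\n",
              x$metabolite, x$mode, x$total))
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %-12s %5.1f%%\n", names(x$fractions)[i],
                100 * x$fractions[i]))
  }
  invisible(x)
}

#' Compare carbon-normalised fluxes between phases
#'
#' @param solutions named list of `flux_solution` objects (one per phase),
#'   all on the same model.
#' @return data frame of normalised fluxes per phase plus pairwise ratio
#'   columns `ratio_<a>_<b>` for consecutive phases.
#' @export
compare_phases <- function(solutions) {
  stopifnot(length(solutions) >= 2)
  ids <- lapply(solutions, function(s) names(s$flux))
  if (!all(vapply(ids, identical, TRUE, ids[[1]]))) {
    stop("solutions come from mismatched models")
  }
  norm <- lapply(solutions, function(s) normalize_by_carbon(s)$normalized)
  out <- data.frame(reaction = ids[[1]], stringsAsFactors = FALSE)
  for (ph in names(norm)) out[[ph]] <- unname(norm[[ph]])
  phs <- names(norm)
  for (i in seq_len(length(phs) - 1)) {
    a <- phs[i + 1]; b <- phs[i]
    out[[paste0("ratio_", a, "_", b)]] <- ifelse(
      abs(out[[b]]) > 1e-12, out[[a]] / out[[b]], NA_real_)
  }
  out
}

#' Arabitol isoform preference under phase constraints
#'
#' Runs NGAM-maximising FBA with both isoform routes open, with only the
#' L-route, and with only the D-route, and reports objective and route
#' fluxes.
#'
#' @param model a [core_model()] containing both arabitol routes.
#' @param constraints a [phase_constraints()].
#' @return data frame with one row per scenario: `scenario`, `status`,
#'   `ngam`, `flux_L`, `flux_D`.
#' @export
isoform_preference <- function(model, constraints) {
  stopifnot(all(c("LAROUTE", "DAROUTE") %in% names(model$reactions)))
  run <- function(label, close = character(0)) {
    m <- model
    for (id in close) m <- set_bounds(m, id, lb = 0, ub = 0)
    s <- maximize_ngam(m, constraints)
    data.frame(scenario = label, status = s$status,
               ngam = if (s$status == "optimal") s$objective_value else NA_real_,
               flux_L = if (s$status == "optimal") s$flux[["LAROUTE"]] else NA_real_,
               flux_D = if (s$status == "optimal") s$flux[["DAROUTE"]] else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(run("both_open"),
        run("L_only", close = "DAROUTE"),
        run("D_only", close = "LAROUTE"))
}
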