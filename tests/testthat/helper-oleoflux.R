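# shared fixtures: a hand-sized toy model, a brute-force LP oracle, and
# small series builders

# toy network: fixed substrate uptake feeding two ATP-yielding routes and
# an NGAM sink; every interesting value is hand-computable
toy_model <- function(uptake = 1, mu_fix = NULL) {
  mets <- data.frame(
    id = c("s_e", "s_c", "atp_c", "adp_c", "biomass_e"),
    name = c("substrate", "substrate", "ATP", "ADP", "biomass"),
    compartment = c("e", "c", "c", "c", "e"),
    formula = c("C6H12O6", "C6H12O6", "", "", ""),
    charge = 0, stringsAsFactors = FALSE
  )
  rxn <- function(id, mets, lb = 0, ub = 10, pseudo = TRUE) {
    list(id = id, name = id, mets = mets, lb = lb, ub = ub,
         subsystem = "toy", genes = character(0), pseudo = pseudo)
  }
  rxns <- list(
    rxn("EX_s", c(s_e = -1), lb = -uptake, ub = -uptake),
    rxn("St", c(s_e = -1, s_c = 1)),
    rxn("CAT", c(s_c = -1, adp_c = -2, atp_c = 2)),   # 2 ATP per substrate
    rxn("CAT2", c(s_c = -1, adp_c = -1, atp_c = 1)),  # inferior route
    rxn("NGAM", c(atp_c = -1, adp_c = 1)),
    rxn("BIOMASS", c(s_c = -1, atp_c = -1, adp_c = 1, biomass_e = 1)),
    rxn("EX_biomass", c(biomass_e = -1))
  )
  m <- core_model(mets, rxns, "BIOMASS", "NGAM")
  if (!is.null(mu_fix)) {
    m <- set_bounds(m, "EX_biomass", lb = mu_fix, ub = mu_fix)
  }
  m
}

# brute-force LP oracle: enumerate basic solutions (n - m variables pinned
# at a bound, remainder solved from the equalities) and keep the feasible
# optimum; independent of the simplex implementation
brute_force_lp <- function(obj, S, lb, ub, maximize = TRUE, tol = 1e-8) {
  n <- length(obj)
  keep <- rowSums(abs(S)) > 0
  S <- S[keep, , drop = FALSE]
  m <- qr(S)$rank
  best <- NULL
  free_sets <- utils::combn(n, min(m, n), simplify = FALSE)
  for (fs in free_sets) {
    pinned <- setdiff(seq_len(n), fs)
    grid <- expand.grid(rep(list(c(1, 2)), length(pinned)))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[pinned] <- ifelse(unlist(grid[g, ]) == 1, lb[pinned], ub[pinned])
      A <- S[, fs, drop = FALSE]
      rhs <- -S[, pinned, drop = FALSE] %*% v[pinned]
      sol <- tryCatch(qr.solve(A, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[fs] <- sol
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      val <- sum(obj * v)
      if (is.null(best) || (maximize && val > best$value) ||
          (!maximize && val < best$value)) {
        best <- list(value = val, solution = v)
      }
    }
  }
  best
}

brute_force_fva <- function(model, reactions = names(model$reactions)) {
  S <- stoich_matrix(model)
  b <- reaction_bounds(model)
  do.call(rbind, lapply(reactions, function(rid) {
    obj <- as.numeric(names(model$reactions) == rid)
    lo <- brute_force_lp(obj, S, b$lb, b$ub, maximize = FALSE)
    hi <- brute_force_lp(obj, S, b$lb, b$ub, maximize = TRUE)
    data.frame(reaction = rid, min = lo$value, max = hi$value)
  }))
}

# constant-biomass series with a linearly changing concentration column
linear_series <- function(times, dcw, conc, col = "xylose_g_l") {
  df <- data.frame(time_h = times, dcw_g_l = dcw)
  df[[col]] <- conc
  if (col != "xylose_g_l") df$xylose_g_l <- 50
  cultivation_series(df)
}

# phase row helper
phase_row <- function(t_start, t_end, label = "P1") {
  data.frame(label = label, t_start = t_start, t_end = t_end,
             limitation = "none", stringsAsFactors = FALSE)
}

# reference-condition constraint sets (true generator rates) and matching
# biomass compositions
ref_phase_constraints <- function() {
  list(
    P1 = phase_constraints(0.060, uptake = c(xylose = 1.74),
                           secretion = c(xylitol = 0.172, arabitol = 0.343)),
    P2 = phase_constraints(0.020, uptake = c(xylose = 0.41),
                           secretion = c(xylitol = 0.040, arabitol = 0.081)),
    P3 = phase_constraints(0.005, uptake = c(xylitol = 0.025,
                                             arabitol = 0.055))
  )
}

ref_phase_models <- function(model = load_model(core_model_path())) {
  list(
    P1 = set_biomass_composition(model, biomass_composition(0.48, 0.18, 0.66)),
    P2 = set_biomass_composition(model, biomass_composition(0.24, 0.38, 0.90)),
    P3 = set_biomass_composition(model, biomass_composition(0.24, 0.38, 1.10))
  )
}

ref_phase_solutions <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cons <- ref_phase_constraints()
      mods <- ref_phase_models()
      cache <<- lapply(names(cons), function(ph)
        maximize_ngam(mods[[ph]], cons[[ph]]))
      names(cache) <<- names(cons)
    }
    cache
  }
})
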