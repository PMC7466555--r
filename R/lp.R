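# linear-programming layer for flux analyses
#
# FBA problems are box-bounded ("lb <= v <= ub") with equality mass
# balances S v = 0; they are passed unchanged to the bounded-variable
# revised simplex in simplex.R.

#' Solve a bounded linear programme
#'
#' Maximise (or minimise) `obj' v` subject to `S v = rhs`, `lb <= v <= ub`.
#'
#' @param obj objective coefficients.
#' @param S equality constraint matrix.
#' @param rhs equality right-hand side (default zero).
#' @param lb,ub variable bounds (finite).
#' @param maximize direction.
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `solution` and `value`.
#' @export
solve_lp <- function(obj, S, rhs = NULL, lb, ub, maximize = TRUE,
                     warm = NULL) {
  if (is.null(rhs)) rhs <- numeric(nrow(S))
  bounded_simplex(obj, S, rhs, lb, ub, maximize = maximize, warm = warm)
}

# maximise flux through a single reaction of a bounded model
lp_optimize_reaction <- function(model, reaction, maximize = TRUE) {
  S <- stoich_matrix(model)
  b <- reaction_bounds(model)
  obj <- as.numeric(names(model$reactions) == reaction)
  sol <- solve_lp(obj, S, lb = b$lb, ub = b$ub, maximize = maximize)
  sol$solution <- stats::setNames(sol$solution, names(model$reactions))
  sol
}

# minimise total absolute flux subject to the model's constraints and,
# optionally, a fixed objective reaction value (parsimonious FBA step)
pfba_min_total_flux <- function(model, fix_reaction = NULL, fix_value = NULL) {
  S <- stoich_matrix(model)
  b <- reaction_bounds(model)
  n <- ncol(S)
  if (!is.null(fix_reaction)) {
    i <- match(fix_reaction, names(model$reactions))
    b$lb[i] <- fix_value
    b$ub[i] <- max(fix_value, b$ub[i])
    b$ub[i] <- fix_value
  }
  # split v = p - q with p, q >= 0
  p_ub <- pmax(b$ub, 0)
  q_ub <- pmax(-b$lb, 0)
  Ssplit <- cbind(S, -S)
  lb2 <- rep(0, 2 * n)
  ub2 <- c(p_ub, q_ub)
  # a strictly positive lower bound pins v to the p half (and vice versa),
  # so box bounds on the halves encode the original box exactly
  pos <- b$lb > 0
  neg <- b$ub < 0
  lb2[which(pos)] <- b$lb[pos]
  ub2[n + which(pos)] <- 0
  lb2[n + which(neg)] <- -b$ub[neg]
  ub2[which(neg)] <- 0
  obj <- rep(1, 2 * n)
  sol <- solve_lp(obj, Ssplit, lb = lb2, ub = ub2, maximize = FALSE)
  if (sol$status != "optimal") {
    return(list(status = sol$status, flux = NULL, total_flux = NA_real_))
  }
  v <- sol$solution[seq_len(n)] - sol$solution[n + seq_len(n)]
  list(status = "optimal",
       flux = as.list(stats::setNames(v, names(model$reactions))),
       total_flux = sol$value)
}
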