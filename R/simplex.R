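# bounded-variable two-phase revised simplex
#
# FBA problems are box-bounded equality-constrained LPs; this solver works
# on that form directly (nonbasic variables rest at a finite bound, so no
# big-M shifts are needed). The basis system is re-solved from scratch each
# iteration, trading speed for numerical robustness at core-model scale.

#' Solve a box-bounded equality-constrained linear programme
#'
#' Maximise or minimise `obj' v` subject to `A v = b` and `lb <= v <= ub`
#' by a two-phase revised simplex with bounded variables (Dantzig pricing
#' with a Bland fallback against cycling).
#'
#' @param obj objective coefficients (length n).
#' @param A equality constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds.
#' @param maximize direction (default `TRUE`).
#' @param tol feasibility/optimality tolerance.
#' @param warm optional warm start: the `"warm"` attribute of a previous
#'   solution of the same feasible region (objective may differ); phase 1
#'   is skipped when the warm basis is still feasible.
#' @return list with `status`, `solution`, `value`, and attribute `"warm"`.
#' @export
bounded_simplex <- function(obj, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, warm = NULL) {
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(ub - lb > -tol))
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # drop numerically empty rows
  keep <- rowSums(abs(A)) > 0 | abs(b) > 0
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A)
  if (m == 0L) {
    v <- ifelse(cc < 0, ub, lb)
    return(list(status = "optimal", solution = v, value = sum(obj * v)))
  }

  # phase-1 artificials: columns n+1..n+m with bounds [0, BIG]
  BIG <- 1e30
  status <- ifelse(abs(lb) <= abs(ub), 1L, 2L)  # 1 at lb, 2 at ub
  vN <- ifelse(status == 1L, lb, ub)
  r <- b - as.numeric(A %*% vN)
  Aall <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(BIG, m))
  basis <- n + seq_len(m)
  stat <- c(status, rep(0L, m))   # 0 = basic
  stat[basis] <- 0L
  x <- c(vN, abs(r))
  x[basis] <- abs(r)

  run_phase <- function(cost, x, basis, stat, max_iter) {
    it <- 0L
    bland <- FALSE
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(ok = FALSE, reason = "iteration limit",
                                     x = x, basis = basis, stat = stat))
      B <- Aall[, basis, drop = FALSE]
      xB <- tryCatch(solve(B, b - Aall[, stat > 0L, drop = FALSE] %*%
                             x[stat > 0L]),
                     error = function(e) NULL)
      if (is.null(xB)) return(list(ok = FALSE, reason = "singular basis",
                                   x = x, basis = basis, stat = stat))
      x[basis] <- as.numeric(xB)
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(ok = FALSE, reason = "singular basis",
                                  x = x, basis = basis, stat = stat))
      nb <- which(stat > 0L)
      d <- cost[nb] - as.numeric(crossprod(Aall[, nb, drop = FALSE], y))
      improving <- (stat[nb] == 1L & d < -tol) | (stat[nb] == 2L & d > tol)
      if (!any(improving)) {
        return(list(ok = TRUE, x = x, basis = basis, stat = stat,
                    value = sum(cost * x)))
      }
      cand <- nb[improving]
      j <- if (bland) min(cand) else cand[which.max(abs(d[improving]))]
      s <- if (stat[j] == 1L) 1 else -1      # direction of change of x_j
      w <- as.numeric(solve(B, Aall[, j]))
      # basic variables move by -t*s*w; find blocking ratio (vectorised)
      tmax <- uball[j] - lball[j]            # bound flip of entering var
      leave <- 0L; leave_to <- 0L
      delta <- -s * w
      xb <- x[basis]
      tk <- rep(Inf, m)
      up <- delta > tol
      dn <- delta < -tol
      tk[up] <- (uball[basis[up]] - xb[up]) / delta[up]
      tk[dn] <- (lball[basis[dn]] - xb[dn]) / delta[dn]
      kmin <- which.min(tk)
      if (length(kmin) && tk[kmin] < tmax - tol) {
        tmax <- tk[kmin]
        leave <- kmin
        leave_to <- if (up[kmin]) 2L else 1L
      }
      if (!is.finite(tmax) || tmax > 1e29) {
        return(list(ok = FALSE, reason = "unbounded", x = x, basis = basis,
                    stat = stat))
      }
      tmax <- max(tmax, 0)
      x[basis] <- x[basis] + tmax * delta
      x[j] <- x[j] + s * tmax
      if (leave == 0L) {
        stat[j] <- if (stat[j] == 1L) 2L else 1L   # bound flip
        x[j] <- if (stat[j] == 1L) lball[j] else uball[j]
      } else {
        out_var <- basis[leave]
        stat[out_var] <- leave_to
        x[out_var] <- if (leave_to == 1L) lball[out_var] else uball[out_var]
        basis[leave] <- j
        stat[j] <- 0L
      }
      if (it %% 200L == 0L) bland <- TRUE  # switch to Bland if stalling
    }
  }

  max_iter <- 200L * (n + m)
  # warm start: reuse a feasible basis of the same region, skip phase 1
  if (!is.null(warm) && length(warm$basis) == m &&
      length(warm$stat) == n + m) {
    wb <- warm$basis; ws <- warm$stat
    uball[n + seq_len(m)] <- 0     # artificials stay pinned under warm start
    xw <- numeric(n + m)
    xw[ws == 1L] <- lball[ws == 1L]
    xw[ws == 2L] <- uball[ws == 2L]
    B <- Aall[, wb, drop = FALSE]
    xB <- tryCatch(solve(B, b - Aall[, ws > 0L, drop = FALSE] %*% xw[ws > 0L]),
                   error = function(e) NULL)
    if (!is.null(xB)) {
      xw[wb] <- as.numeric(xB)
      feas <- all(xw >= lball - 1e-7) && all(xw <= pmin(uball, BIG) + 1e-7)
      if (feas) {
        cost2 <- c(cc, rep(0, m))
        ph2 <- run_phase(cost2, xw, wb, ws, max_iter)
        if (ph2$ok) {
          v <- ph2$x[seq_len(n)]
          v <- pmin(pmax(v, lb), ub)
          out <- list(status = "optimal", solution = v, value = sum(obj * v))
          attr(out, "warm") <- list(basis = ph2$basis, stat = ph2$stat)
          return(out)
        }
        if (identical(ph2$reason, "unbounded")) {
          return(list(status = "unbounded", solution = rep(NA_real_, n),
                      value = NA_real_))
        }
      }
      uball[n + seq_len(m)] <- BIG   # reset for cold start
    }
  }
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, x, basis, stat, max_iter)
  if (!ph1$ok) {
    return(list(status = if (identical(ph1$reason, "unbounded"))
      "infeasible" else "numerical", solution = rep(NA_real_, n),
      value = NA_real_))
  }
  if (ph1$value > 1e-6) {
    return(list(status = "infeasible", solution = rep(NA_real_, n),
                value = NA_real_))
  }
  # pin artificials to zero so they never re-enter
  x <- ph1$x; basis <- ph1$basis; stat <- ph1$stat
  uball[n + seq_len(m)] <- 0
  x[n + seq_len(m)][stat[n + seq_len(m)] > 0L] <- 0
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, x, basis, stat, max_iter)
  if (!ph2$ok) {
    if (identical(ph2$reason, "unbounded")) {
      return(list(status = "unbounded", solution = rep(NA_real_, n),
                  value = NA_real_))
    }
    return(list(status = "numerical", solution = rep(NA_real_, n),
                value = NA_real_))
  }
  v <- ph2$x[seq_len(n)]
  v <- pmin(pmax(v, lb), ub)
  out <- list(status = "optimal", solution = v, value = sum(obj * v))
  attr(out, "warm") <- list(basis = ph2$basis, stat = ph2$stat)
  out
}
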