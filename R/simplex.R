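# Bounded-variable two-phase primal simplex.
#
# Solves   optimize  obj' v
#          subject to  A v = rhs,   lb <= v <= ub
# which is exactly the standard form of flux balance problems (S v = 0 with
# finite flux bounds), so no inequality rows are ever needed: objective-level
# constraints are imposed by tightening the bound of the objective reaction's
# own flux variable.
#
# Bland's smallest-index rule is used for both the entering and the leaving
# choice, which guarantees termination (no cycling) and makes the selected
# optimal vertex reproducible run-to-run for identical input. Problems here
# are tiny (tens of rows), so the basis is refactorised densely with solve()
# at every iteration in exchange for numerical robustness.

#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 50000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  # clip inverted-by-rounding bounds
  ub <- pmax(ub, lb)

  cost <- if (sense == "max") -obj else obj

  # Nonbasic structural variables start at the finite bound nearest zero.
  start_at_ub <- abs(ub) < abs(lb) & is.finite(ub)
  start_at_ub[!is.finite(lb)] <- TRUE
  x_struct <- ifelse(start_at_ub, ub, lb)
  x_struct[!is.finite(x_struct)] <- 0

  resid <- rhs - drop(A %*% x_struct)
  art_sign <- ifelse(resid >= 0, 1, -1)

  Afull <- cbind(A, diag(art_sign, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  nvar <- n + m
  art_idx <- seq.int(n + 1L, nvar)
  is_art <- c(rep(FALSE, n), rep(TRUE, m))

  basis <- art_idx
  at_ub <- c(start_at_ub, rep(FALSE, m))

  current_x <- function(basis, at_ub) {
    x <- ifelse(at_ub, ubf, lbf)
    x[!is.finite(x)] <- 0
    x[basis] <- 0
    nb <- setdiff(seq_len(nvar), basis)
    rhs_b <- rhs - drop(Afull[, nb, drop = FALSE] %*% x[nb])
    B <- Afull[, basis, drop = FALSE]
    x[basis] <- solve(B, rhs_b)
    x
  }

  run_phase <- function(phase_cost, basis, at_ub, allow_enter) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit", basis = basis, at_ub = at_ub))
      }
      x <- current_x(basis, at_ub)
      B <- Afull[, basis, drop = FALSE]
      y <- solve(t(B), phase_cost[basis])
      nb <- setdiff(seq_len(nvar), basis)
      nb <- nb[allow_enter[nb] & (ubf[nb] - lbf[nb]) > tol]
      if (length(nb) == 0L) {
        return(list(status = "optimal", basis = basis, at_ub = at_ub, x = x))
      }
      d <- phase_cost[nb] - drop(crossprod(Afull[, nb, drop = FALSE], y))
      improving <- (!at_ub[nb] & d < -tol) | (at_ub[nb] & d > tol)
      if (!any(improving)) {
        return(list(status = "optimal", basis = basis, at_ub = at_ub, x = x))
      }
      j <- min(nb[improving])                       # Bland: smallest entering index
      dir_sign <- if (at_ub[j]) -1 else 1
      w <- solve(B, Afull[, j])
      g <- dir_sign * w

      # step limits: entering variable's own opposite bound, then each basic
      step_own <- ubf[j] - lbf[j]
      lim_idx <- j
      lim_val <- step_own
      bi <- basis
      xb <- x[basis]
      dec <- g > tol     # basic value decreases toward its lower bound
      inc <- g < -tol    # basic value increases toward its upper bound
      if (any(dec)) {
        steps <- (xb[dec] - lbf[bi[dec]]) / g[dec]
        lim_idx <- c(lim_idx, bi[dec])
        lim_val <- c(lim_val, steps)
      }
      if (any(inc)) {
        steps <- (ubf[bi[inc]] - xb[inc]) / (-g[inc])
        lim_idx <- c(lim_idx, bi[inc])
        lim_val <- c(lim_val, steps)
      }
      lim_val[lim_val < 0] <- 0                     # degeneracy guard
      step <- min(lim_val)
      if (!is.finite(step)) {
        return(list(status = "unbounded", basis = basis, at_ub = at_ub))
      }
      blocking <- lim_idx[lim_val <= step + tol]
      leave <- min(blocking)                        # Bland: smallest leaving index
      if (leave == j) {
        at_ub[j] <- !at_ub[j]                       # bound-to-bound flip
      } else {
        pos <- match(leave, basis)
        at_ub[leave] <- g[pos] < 0                  # leaves at the bound it hit
        basis[pos] <- j
      }
    }
  }

  # Phase 1: drive artificials to zero; artificials never re-enter.
  p1_cost <- c(rep(0, n), rep(1, m))
  allow1 <- !is_art
  res1 <- run_phase(p1_cost, basis, at_ub, allow1)
  if (res1$status != "optimal") {
    return(list(status = "numerical_failure", objective = NA_real_, x = rep(NA_real_, n)))
  }
  x1 <- res1$x
  if (sum(x1[art_idx]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }

  # Phase 2: artificials pinned at zero, real cost.
  ubf[art_idx] <- 0
  p2_cost <- c(cost, rep(0, m))
  res2 <- run_phase(p2_cost, res1$basis, res1$at_ub, allow1)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (res2$status != "optimal") {
    return(list(status = "numerical_failure", objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- res2$x[seq_len(n)]
  objective <- sum(obj * x)
  list(status = "optimal", objective = objective, x = x)
}
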