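# Internal linear-programming solver.
#
# All flux LPs in the package are small, dense, bounded-variable
# problems
#   max/min  c' v   s.t.  S v = 0,  A v (<=|>=) rhs,  lb <= v <= ub.
# They are reduced to standard equality form (shift v = lb + x, fold
# finite upper bounds and extra inequalities into slack/surplus rows)
# and solved by a two-phase tableau simplex with Bland's anti-cycling
# rule. Dense and O(iterations * m * n), so intended for the toy/medium
# networks this package works with; see the vignette for the scale
# limitation.

#' Two-phase simplex for min c'x s.t. A x = b, x >= 0
#' @noRd
simplex_core <- function(cc, A, b, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1 tableau: [A | I_art | b]
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(numeric(n), rep(1, m))
  pivot <- function(Tb, r, s) {
    Tb[r, ] <- Tb[r, ] / Tb[r, s]
    for (i in seq_len(nrow(Tb))) if (i != r && abs(Tb[i, s]) > 0)
      Tb[i, ] <- Tb[i, ] - Tb[i, s] * Tb[r, ]
    Tb
  }
  run_phase <- function(Tb, basis, cost, active_cols) {
    bland_after <- 500L  # Dantzig is fast; Bland guarantees termination
    for (iter in seq_len(max_iter)) {
      y <- cost[basis] %*% Tb[, seq_len(ncol(Tb) - 1L), drop = FALSE]
      red <- cost[active_cols] - y[active_cols]
      enter_rel <- which(red < -tol)
      if (!length(enter_rel))
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      s <- if (iter <= bland_after)
        active_cols[enter_rel[which.min(red[enter_rel])]]  # most negative
      else
        active_cols[min(enter_rel)]                        # Bland
      col <- Tb[, s]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]         # Bland on ties
      basis[r] <- s
      Tb <- pivot(Tb, r, s)
    }
    list(Tb = Tb, basis = basis, status = "iteration_limit")
  }

  p1 <- run_phase(Tb, basis, cost1, seq_len(n + m))
  if (p1$status != "optimal") return(list(status = p1$status))
  obj1 <- sum(p1$Tb[, ncol(p1$Tb)][match(which(p1$basis > n), seq_len(m))],
              na.rm = TRUE)
  obj1 <- sum(cost1[p1$basis] * p1$Tb[, ncol(p1$Tb)])
  if (obj1 > 1e-7) return(list(status = "infeasible"))
  Tb <- p1$Tb; basis <- p1$basis

  # drive remaining artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    s <- which(abs(Tb[r, seq_len(n)]) > tol)[1]
    if (is.na(s)) drop_rows <- c(drop_rows, r)
    else { basis[r] <- s; Tb <- pivot(Tb, r, s) }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  Tb <- Tb[, c(seq_len(n), ncol(Tb)), drop = FALSE]

  cost2 <- cc
  p2 <- run_phase(Tb, basis, cost2, seq_len(n))
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- numeric(n)
  x[p2$basis] <- p2$Tb[, ncol(p2$Tb)]
  list(status = "optimal", x = x, objective = sum(cc * x))
}

#' @noRd
solve_lp <- function(obj, Aeq = NULL, beq = NULL, lb, ub,
                     A = NULL, dir = NULL, rhs = NULL,
                     maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_, flux = NULL))
  lb <- pmin(lb, ub)

  rows <- list(); rhs_all <- numeric(0); slack_sign <- numeric(0)
  add <- function(a, b, sense) {
    rows[[length(rows) + 1L]] <<- a
    rhs_all[length(rhs_all) + 1L] <<- b
    slack_sign[length(slack_sign) + 1L] <<-
      switch(sense, le = 1, ge = -1, eq = 0)
  }
  span <- ub - lb
  for (j in which(is.finite(span))) {
    a <- numeric(n); a[j] <- 1
    add(a, span[j], "le")
  }
  if (!is.null(Aeq)) {
    Aeq <- matrix(as.numeric(Aeq), ncol = n)
    shift <- as.numeric(Aeq %*% lb)
    for (i in seq_len(nrow(Aeq))) add(Aeq[i, ], beq[i] - shift[i], "eq")
  }
  if (!is.null(A)) {
    A <- matrix(as.numeric(A), ncol = n)
    shift <- as.numeric(A %*% lb)
    for (i in seq_len(nrow(A)))
      add(A[i, ], rhs[i] - shift[i], if (dir[i] == "<=") "le" else "ge")
  }
  m <- length(rows)
  n_slack <- sum(slack_sign != 0)
  Afull <- matrix(0, m, n + n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    Afull[i, seq_len(n)] <- rows[[i]]
    if (slack_sign[i] != 0) {
      k <- k + 1L
      Afull[i, n + k] <- slack_sign[i]
    }
  }
  cc <- c(if (maximize) -obj else obj, numeric(n_slack))
  res <- simplex_core(cc, Afull, rhs_all, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, flux = NULL))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), flux = v)
}
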