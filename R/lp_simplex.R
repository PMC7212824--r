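# Dense two-phase primal simplex for small linear programs
#   min c'x  s.t.  A x (<=|>=|=) b,  x >= 0
# Deterministic: Dantzig entering rule with a permanent switch to
# Bland's rule after a stall, lowest-basis-index ratio tie-break.
# Problem sizes here are tiny (55 variables, ~150 rows), so a dense
# tableau is the simplest reliable choice; no LP library is assumed.

simplex_lp <- function(cvec, A, b, ctype,
                       maxit = 50000L, tol = 1e-9, feas_tol = 1e-7) {
  n <- length(cvec)
  stopifnot(ncol(A) == n, nrow(A) == length(b), length(ctype) == length(b))

  # drop/validate degenerate zero rows, then equilibrate rows
  scale <- apply(abs(A), 1, max)
  zero <- scale == 0
  if (any(zero)) {
    ok <- (ctype[zero] == "<=" & b[zero] >= -tol) |
      (ctype[zero] == ">=" & b[zero] <= tol) |
      (ctype[zero] == "=" & abs(b[zero]) <= tol)
    if (!all(ok)) return(list(status = "infeasible", x = NULL, value = NA_real_))
    A <- A[!zero, , drop = FALSE]; b <- b[!zero]; ctype <- ctype[!zero]
    scale <- scale[!zero]
  }
  m <- nrow(A)
  if (m == 0L) {
    # only x >= 0: optimum at 0 unless some cost is negative (unbounded)
    if (any(cvec < -tol)) return(list(status = "unbounded", x = NULL, value = NA_real_))
    return(list(status = "optimal", x = numeric(n), value = 0))
  }
  A <- A / scale; b <- b / scale
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip]
  ctype[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[ctype[flip]]

  ineq <- ctype != "="
  n_slack <- sum(ineq)
  need_art <- ctype == ">=" | ctype == "="
  n_art <- sum(need_art)
  ncols <- n + n_slack + n_art

  tab <- matrix(0, m, ncols + 1L)
  tab[, 1:n] <- A
  tab[, ncols + 1L] <- b
  slack_col <- integer(m); art_col <- integer(m)
  sc <- n
  for (i in seq_len(m)) {
    if (ineq[i]) {
      sc <- sc + 1L
      slack_col[i] <- sc
      tab[i, sc] <- if (ctype[i] == "<=") 1 else -1
    }
  }
  ac <- n + n_slack
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (ctype[i] == "<=") {
      basis[i] <- slack_col[i]
    } else {
      ac <- ac + 1L
      art_col[i] <- ac
      tab[i, ac] <- 1
      basis[i] <- ac
    }
  }
  art_cols <- art_col[art_col > 0L]
  eligible <- rep(TRUE, ncols)

  run_phase <- function(tab, basis, cost, eligible) {
    cB <- cost[basis]
    r <- c(cost, 0) - drop(cB %*% tab)
    it <- 0L; stall <- 0L; bland <- FALSE
    last_obj <- -r[ncols + 1L]
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "error", tab = tab, basis = basis,
                                  msg = "iteration limit"))
      rr <- r[1:ncols]
      rr[!eligible] <- Inf
      if (bland) {
        cand <- which(rr < -tol)
        if (!length(cand)) break
        pc <- cand[1]
      } else {
        pc <- which.min(rr)
        if (rr[pc] >= -tol) break
      }
      col <- tab[, pc]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", tab = tab, basis = basis))
      }
      ratio <- tab[pos, ncols + 1L] / col[pos]
      pr <- pos[ratio <= min(ratio) + tol]
      if (length(pr) > 1L) pr <- pr[which.min(basis[pr])]
      piv <- tab[pr, pc]
      tab[pr, ] <- tab[pr, ] / piv
      fac <- tab[, pc]; fac[pr] <- 0
      tab <- tab - outer(fac, tab[pr, ])
      r <- r - r[pc] * tab[pr, ]
      basis[pr] <- pc
      obj <- -r[ncols + 1L]
      if (obj < last_obj - 1e-12) { stall <- 0L; last_obj <- obj } else stall <- stall + 1L
      if (!bland && stall > 200L) bland <- TRUE
    }
    list(status = "ok", tab = tab, basis = basis, obj = -r[ncols + 1L])
  }

  # phase 1: drive artificial variables to zero
  if (n_art > 0L) {
    cost1 <- numeric(ncols); cost1[art_cols] <- 1
    p1 <- run_phase(tab, basis, cost1, eligible)
    if (p1$status != "ok") {
      return(list(status = if (p1$status == "unbounded") "error" else p1$status,
                  x = NULL, value = NA_real_))
    }
    tab <- p1$tab; basis <- p1$basis
    if (p1$obj > feas_tol * max(1, max(b))) {
      return(list(status = "infeasible", x = NULL, value = NA_real_,
                  phase1 = p1$obj))
    }
    # pivot remaining basic artificials out (or drop redundant rows)
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      j <- which(abs(tab[i, 1:(n + n_slack)]) > 1e-7)
      j <- j[!(j %in% basis)]
      if (length(j)) {
        pc <- j[1]
        piv <- tab[i, pc]
        tab[i, ] <- tab[i, ] / piv
        fac <- tab[, pc]; fac[i] <- 0
        tab <- tab - outer(fac, tab[i, ])
        basis[i] <- pc
      } else {
        drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows)) {
      tab <- tab[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(tab)
    }
    eligible[art_cols] <- FALSE
  }

  cost2 <- c(cvec, numeric(ncols - n))
  p2 <- run_phase(tab, basis, cost2, eligible)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  if (p2$status != "ok") {
    return(list(status = "error", x = NULL, value = NA_real_, msg = p2$msg))
  }
  tab <- p2$tab; basis <- p2$basis
  x <- numeric(n)
  bvals <- tab[, ncols + 1L]
  struct <- basis <= n
  x[basis[struct]] <- bvals[struct]
  x[x < 0 & x > -1e-9] <- 0
  list(status = "optimal", x = x, value = sum(cvec * x))
}

# Expand an lp_problem's two-sided rows into (A, b, ctype) form,
# optionally dropping labeled constraints.
lp_canonicalize <- function(problem, drop_labels = character(0)) {
  keep <- !(problem$label %in% drop_labels)
  A <- problem$A[keep, , drop = FALSE]
  lb <- problem$lb[keep]; ub <- problem$ub[keep]
  rows <- list(); b <- numeric(0); ctype <- character(0)
  for (i in seq_len(nrow(A))) {
    if (is.finite(lb[i]) && is.finite(ub[i]) && lb[i] == ub[i]) {
      rows[[length(rows) + 1L]] <- A[i, ]; b <- c(b, lb[i]); ctype <- c(ctype, "=")
    } else {
      if (is.finite(ub[i])) {
        rows[[length(rows) + 1L]] <- A[i, ]; b <- c(b, ub[i]); ctype <- c(ctype, "<=")
      }
      if (is.finite(lb[i])) {
        rows[[length(rows) + 1L]] <- A[i, ]; b <- c(b, lb[i]); ctype <- c(ctype, ">=")
      }
    }
  }
  list(A = do.call(rbind, rows), b = b, ctype = ctype)
}

# Minimize (or maximize) an arbitrary linear functional over the
# feasible set of an lp_problem.
solve_lp <- function(problem, objective, drop_labels = character(0),
                     maximize = FALSE) {
  can <- lp_canonicalize(problem, drop_labels)
  if (is.null(can$A)) can$A <- matrix(0, 0, length(objective))
  obj <- if (maximize) -objective else objective
  res <- simplex_lp(obj, can$A, can$b, can$ctype)
  if (res$status == "optimal" && maximize) res$value <- -res$value
  res
}
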