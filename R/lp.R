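# Dense two-phase simplex with Bland's rule for the small linear programs of
# the recruitment module (a handful of variables and constraints per solve).
# Bland's rule guarantees termination on the degenerate tableaus that arise
# when several fascicles sit exactly at the activation ceiling.
#
#   minimize c'x  subject to  A_ub x <= b_ub, A_eq x = b_eq, x >= 0.

lp_solve_small <- function(cvec, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                           max_iter = 1000L, tol = 1e-9) {
  n <- length(cvec)
  A <- NULL; b <- NULL
  n_slack <- if (is.null(A_ub)) 0L else nrow(A_ub)
  if (n_slack > 0L) {
    A <- cbind(A_ub, diag(n_slack))
    b <- b_ub
  }
  if (!is.null(A_eq)) {
    Aeq <- if (n_slack > 0L) cbind(A_eq, matrix(0, nrow(A_eq), n_slack)) else A_eq
    A <- rbind(A, Aeq)
    b <- c(b, b_eq)
  }
  if (is.null(A)) return(list(status = "ok", x = rep(0, n), value = 0))
  m <- nrow(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ntot <- ncol(A)

  # phase 1: un-flipped inequality rows start basic in their slack; only
  # equality and flipped rows need an artificial variable
  slack_ok <- seq_len(m) <= n_slack & !neg
  need_art <- which(!slack_ok)
  Ap <- if (length(need_art)) cbind(A, diag(m)[, need_art, drop = FALSE]) else A
  basis <- integer(m)
  basis[slack_ok] <- n + which(slack_ok)
  basis[need_art] <- ntot + seq_along(need_art)
  cost1 <- c(rep(0, ntot), rep(1, length(need_art)))
  res <- simplex_core(Ap, b, cost1, basis, max_iter, tol)
  if (res$status != "ok") return(list(status = res$status, x = NULL, value = NA_real_))
  if (res$value > 1e-7 * max(1, max(abs(b)))) return(list(status = "infeasible", x = NULL, value = NA_real_))

  # drive remaining artificials out of the basis where possible
  Ap <- res$A; bp <- res$b; basis <- res$basis
  for (i in seq_len(m)) {
    if (basis[i] > ntot) {
      piv <- which(abs(Ap[i, seq_len(ntot)]) > tol)
      piv <- piv[!(piv %in% basis)]
      if (length(piv)) {
        j <- piv[1L]
        pv <- Ap[i, j]
        Ap[i, ] <- Ap[i, ] / pv
        bp[i] <- bp[i] / pv
        for (r in seq_len(m)) if (r != i && abs(Ap[r, j]) > 0) {
          bp[r] <- bp[r] - Ap[r, j] * bp[i]
          Ap[r, ] <- Ap[r, ] - Ap[r, j] * Ap[i, ]
        }
        basis[i] <- j
      }
    }
  }
  # rows still basic in an artificial are redundant constraints: drop them
  red_rows <- which(basis > ntot)
  if (length(red_rows)) {
    Ap <- Ap[-red_rows, , drop = FALSE]
    bp <- bp[-red_rows]
    basis <- basis[-red_rows]
    if (nrow(Ap) == 0L) {
      x <- numeric(ntot)
      return(list(status = "ok", x = x[seq_len(n)], value = 0))
    }
  }
  cost2 <- c(cvec, rep(0, ntot - n))
  res2 <- simplex_core(Ap[, seq_len(ntot), drop = FALSE], bp, cost2, basis,
                       max_iter, tol)
  if (res2$status != "ok") return(list(status = res2$status, x = NULL, value = NA_real_))
  x <- numeric(ntot)
  x[res2$basis[res2$basis <= ntot]] <- res2$b[res2$basis <= ntot]
  list(status = "ok", x = x[seq_len(n)], value = sum(cvec * x[seq_len(n)]))
}

# Tableau simplex iterations with Bland's anti-cycling rule; the caller
# provides a canonical basic feasible tableau.
simplex_core <- function(A, b, cost, basis, max_iter, tol) {
  m <- nrow(A); ntot <- ncol(A)
  # reduce so basic columns are unit: assume caller provides a valid basic
  # feasible tableau (phase-1 start is the identity on artificials)
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    # reduced costs: c_j - cb' A_j
    y <- crossprod(A, cb)
    red <- cost - as.numeric(y)
    red[basis] <- 0
    enter <- which(red < -tol)
    if (!length(enter)) {
      return(list(status = "ok", A = A, b = b, basis = basis,
                  value = sum(cb * b)))
    }
    j <- min(enter)  # Bland: smallest index enters
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland: smallest basis index leaves
    pv <- A[i, j]
    A[i, ] <- A[i, ] / pv
    b[i] <- b[i] / pv
    for (r in seq_len(m)) if (r != i && abs(A[r, j]) > tol * 1e-3) {
      b[r] <- b[r] - A[r, j] * b[i]
      A[r, ] <- A[r, ] - A[r, j] * A[i, ]
    }
    b[b < 0 & b > -1e-11] <- 0
    basis[i] <- j
  }
  list(status = "not_converged")
}
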