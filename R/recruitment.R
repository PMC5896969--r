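# Muscle recruitment: distributing the net joint moment demand over the
# redundant hip-spanning fascicles.
#
# The equilibrium system is C f = d with C the (m x n) moment-arm matrix
# (m hip degrees of freedom, n fascicles, n >= m in the redundant case),
# f >= 0 the fascicle forces and N > 0 the instantaneous strengths. Two
# criteria are provided: the third-power polynomial criterion (PN), which
# minimizes sum((f_i/N_i)^p), and the strict min/max criterion (MM), which
# minimizes the largest activation max(f_i/N_i) and is the infinite-power
# limit of the polynomial family.

#' Recruitment problem
#'
#' @param C Moment-arm / equilibrium matrix, m x n (m degrees of freedom,
#'   n fascicles).
#' @param d Demand vector (length m), N m.
#' @param N Instantaneous fascicle strengths (length n), N; must be positive.
#' @return A `recruitment_problem`.
#' @export
recruitment_problem <- function(C, d, N) {
  C <- rbind(C)
  d <- as.numeric(d)
  N <- as.numeric(N)
  if (nrow(C) != length(d)) stop("nrow(C) must match length(d)")
  if (ncol(C) != length(N)) stop("ncol(C) must match length(N)")
  if (any(!is.finite(N)) || any(N <= 0)) stop("strengths N must be positive")
  if (any(!is.finite(C)) || any(!is.finite(d))) stop("C and d must be finite")
  structure(list(C = C, d = d, N = N), class = "recruitment_problem")
}

recruitment_solution <- function(f, N, status, criterion_value, C, d) {
  structure(
    list(f = as.numeric(f), activations = as.numeric(f) / N, status = status,
         criterion_value = criterion_value,
         residual = if (status == "ok") max(abs(C %*% f - d)) else NA_real_),
    class = "recruitment_solution")
}

#' @export
print.recruitment_solution <- function(x, ...) {
  cat(sprintf("<recruitment_solution> status %s | max activation %.3f | criterion %.4g\n",
              x$status, if (length(x$activations)) max(x$activations) else NA, x$criterion_value))
  invisible(x)
}

# Phase-1 LP feasibility check of {C f = d, 0 <= f <= cap}.
lp_feasible <- function(C, d, cap = NULL) {
  n <- ncol(C)
  A1 <- NULL; b1 <- NULL
  if (!is.null(cap) && any(is.finite(cap))) {
    fin <- which(is.finite(cap))
    A1 <- diag(n)[fin, , drop = FALSE]
    b1 <- cap[fin]
  }
  sol <- lp_solve_small(rep(0, n), A_ub = A1, b_ub = b1, A_eq = C, b_eq = d)
  sol$status == "ok"
}

#' Polynomial muscle recruitment
#'
#' Minimizes the p-th power polynomial criterion `sum((f_i / N_i)^p)` subject
#' to the equilibrium constraints `C f = d` and `f >= 0` (and, when
#' `bounded = TRUE`, to the muscle-model strength caps `f_i <= cap_i`). The
#' convex program is solved exactly through its smooth dual: fascicle
#' activations follow `a_i = max(0, (M' lambda)_i / p)^(1/(p-1))` (clipped at
#' the cap when bounded) with `M = C diag(N)`, and the m-dimensional dual
#' vector `lambda` is found by a damped Newton iteration, warm-started by
#' BFGS. By default the caps are off: overload (activation above 1) is
#' admitted and visible in the solution, and the solution is then invariant
#' under a uniform rescaling of all strengths.
#'
#' @param prob A [recruitment_problem()].
#' @param p Criterion power, `>= 2` (default 3).
#' @param bounded Enforce `f_i <= cap_i` as hard constraints (default FALSE).
#' @param cap Upper bounds in N when `bounded`; default the strengths `N`.
#' @param tol Relative equilibrium tolerance (default 1e-9).
#' @return A `recruitment_solution` with forces `f`, `activations = f/N`,
#'   `status` in `ok`, `infeasible`, `not_converged`, and the criterion value.
#' @export
recruit_polynomial <- function(prob, p = 3, bounded = FALSE, cap = prob$N, tol = 1e-9) {
  stopifnot(inherits(prob, "recruitment_problem"))
  if (p < 2) stop("p must be >= 2")
  C <- prob$C; d <- prob$d; N <- prob$N
  m <- nrow(C); n <- ncol(C)
  dscale <- max(abs(d), 1e-12)
  if (max(abs(d)) == 0)
    return(recruitment_solution(rep(0, n), N, "ok", 0, C, d))

  M <- C * rep(N, each = m)          # M = C diag(N), activations a = f/N
  u <- if (bounded) cap / N else rep(Inf, n)

  solve_power <- function(pw, lam, Mx, ux) {
    a_of <- function(mm) {
      a <- ifelse(mm > 0, (mm / pw)^(1 / (pw - 1)), 0)
      pmin(a, ux)
    }
    gfun <- function(lam) {          # dual objective (to maximize)
      mm <- drop(crossprod(Mx, lam))
      a <- a_of(mm)
      sum(a^pw - mm * a) + sum(lam * d)
    }
    grad <- function(lam) d - drop(Mx %*% a_of(drop(crossprod(Mx, lam))))
    ws <- stats::optim(lam, fn = function(l) -gfun(l), gr = function(l) -grad(l),
                       method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    lam <- ws$par
    # damped Newton polish on the dual
    for (it in seq_len(100L)) {
      mm <- drop(crossprod(Mx, lam))
      a <- a_of(mm)
      g <- d - drop(Mx %*% a)
      if (max(abs(g)) <= tol * dscale) break
      interior <- mm > 0 & a < ux
      da <- numeric(n)
      da[interior] <- 1 / (pw * (pw - 1) * pmax(a[interior], 1e-12)^(pw - 2))
      H <- Mx %*% (t(Mx) * da)
      step <- tryCatch(solve(H + 1e-12 * max(diag(H), 1e-12) * diag(m), g),
                       error = function(e) g)
      g0 <- gfun(lam)
      alpha <- 1
      repeat {
        lam_try <- lam + alpha * step
        if (gfun(lam_try) > g0 - 1e-14 * abs(g0)) { lam <- lam_try; break }
        alpha <- alpha / 2
        if (alpha < 1e-12) { lam <- lam + 1e-12 * step; break }
      }
    }
    list(lam = lam, a = a_of(drop(crossprod(Mx, lam))))
  }

  # Newton on the primal KKT system restricted to the active support:
  # quadratic cleanup of the dual solution (kept within the support and off
  # the bounds; falls back to the input on any degeneracy)
  kkt_polish <- function(a, pw, Mx, ux) {
    for (outer in 1:4) {
      amax_ <- max(a)
      if (amax_ <= 0) return(a)
      fixed <- is.finite(ux) & a >= ux * (1 - 1e-9)
      S <- which(!fixed & a > 1e-10 * amax_)
      if (!length(S)) return(a)
      d_eff <- d - if (any(fixed)) drop(Mx[, fixed, drop = FALSE] %*% ux[fixed]) else 0
      aS <- a[S]
      MS <- Mx[, S, drop = FALSE]
      lamS <- tryCatch(solve(tcrossprod(MS) + 1e-12 * diag(m),
                             drop(MS %*% (pw * aS^(pw - 1)))),
                       error = function(e) NULL)
      if (is.null(lamS)) return(a)
      ok_inner <- FALSE
      for (it in 1:40) {
        r1 <- pw * aS^(pw - 1) - drop(crossprod(MS, lamS))
        r2 <- drop(MS %*% aS) - d_eff
        if (max(abs(r2)) <= 1e-12 * dscale && max(abs(r1)) <= 1e-10 * max(abs(r1) + 1))
          { ok_inner <- TRUE; break }
        Dm <- pw * (pw - 1) * aS^(pw - 2)
        J <- rbind(cbind(diag(Dm, length(S)), -t(MS)), cbind(MS, matrix(0, m, m)))
        step <- tryCatch(solve(J, -c(r1, r2)), error = function(e) NULL)
        if (is.null(step)) break
        alpha <- 1
        aN <- aS + step[seq_along(S)]
        while (any(aN <= 0) && alpha > 1e-8) {
          alpha <- alpha / 2
          aN <- aS + alpha * step[seq_along(S)]
        }
        if (any(aN <= 0)) break
        aS <- aN
        lamS <- lamS + alpha * step[length(S) + seq_len(m)]
        if (alpha == 1 && max(abs(r2)) < 1e-9 * dscale) { ok_inner <- TRUE }
      }
      a_new <- a
      a_new[S] <- aS
      a_new[fixed] <- ux[fixed]
      a_new[setdiff(seq_len(n), c(S, which(fixed)))] <- 0
      if (is.finite(ux[1]) || any(is.finite(ux))) a_new <- pmin(a_new, ux)
      # accept only if feasibility improved
      if (max(abs(Mx %*% a_new - d)) <= max(abs(Mx %*% a - d)) + 1e-12) a <- a_new
      if (ok_inner) return(a)
    }
    a
  }

  # the p = 3 dual is well conditioned in raw units
  lam <- tryCatch(solve(tcrossprod(M) + 1e-10 * diag(m), d), error = function(e) d * 0)
  res <- solve_power(min(p, 3), lam, M, u)
  a <- kkt_polish(res$a, min(p, 3), M, u)
  if (p > 3) {
    # continuation over a ladder of powers, with the strengths rescaled so
    # the working activations are O(1): high-power duals degenerate when the
    # activations are far from 1, and the unbounded solution is invariant
    # under the rescaling
    s <- max(res$a, 1e-9)
    Ms <- M * s
    us <- u / s
    ae <- res$a / s
    for (pw in setdiff(sort(unique(c(pmin(p, c(5, 9, 17)), p))), min(p, 3))) {
      mhat <- pw * pmax(ae, 1e-9)^(pw - 1)
      lam <- tryCatch(solve(tcrossprod(Ms) + 1e-10 * diag(m), drop(Ms %*% mhat)),
                      error = function(e) lam)
      res <- solve_power(pw, lam, Ms, us)
      cand1 <- kkt_polish(res$a, pw, Ms, us)
      # the previous power's profile, re-polished at this power, guards
      # against a suboptimal dual solve (true optima are monotone in p)
      cand2 <- kkt_polish(ae, pw, Ms, us)
      val <- function(x) if (max(abs(Ms %*% x - d)) <= 1e-6 * dscale)
        sum(x^pw) else Inf
      ae <- if (val(cand2) < val(cand1)) cand2 else cand1
    }
    a <- ae * s
  }
  f <- a * N
  if (max(abs(C %*% f - d)) > 1e-6 * dscale) {
    status <- if (bounded && !lp_feasible(C, d, cap)) "infeasible" else "not_converged"
    return(recruitment_solution(f, N, status, sum(a^p), C, d))
  }
  recruitment_solution(f, N, "ok", sum(a^p), C, d)
}

# One min/max LP level: minimize the common activation ceiling t of the free
# fascicles, with fixed fascicle forces already subtracted from the demand.
# Returns t*, a solution, and the solver status.
minmax_level <- function(C, d, N, tmax) {
  n <- ncol(C)
  A1 <- cbind(diag(n), -N)
  b1 <- rep(0, n)
  if (is.finite(tmax)) {
    A1 <- rbind(A1, c(rep(0, n), 1))
    b1 <- c(b1, tmax)
  }
  sol <- lp_solve_small(c(rep(0, n), 1), A_ub = A1, b_ub = b1,
                        A_eq = cbind(C, 0), b_eq = d)
  if (sol$status != "ok") return(list(status = sol$status))
  list(status = "ok", t = sol$x[n + 1L], f = sol$x[seq_len(n)])
}

# Minimal force of fascicle i over {C f = d, 0 <= f <= ub}.
lp_min_component <- function(C, d, ub, i) {
  n <- ncol(C)
  obj <- rep(0, n); obj[i] <- 1
  sol <- lp_solve_small(obj, A_ub = diag(n), b_ub = ub, A_eq = C, b_eq = d)
  if (sol$status != "ok") return(NA_real_)
  sol$value
}

#' Strict min/max muscle recruitment
#'
#' The infinite-power limit of the polynomial criterion, solved
#' lexicographically as in the strict min/max recruitment literature: a
#' linear program minimizes the largest activation `max(f_i / N_i)`; the
#' fascicles that cannot be below that ceiling in any optimal solution are
#' fixed at it, their contribution is removed from the demand, and the
#' procedure recurses on the remaining fascicles. The result is the
#' characteristic broad co-activation of min/max recruitment. With
#' `bounded = TRUE` (the default) activation 1 is a hard ceiling -- no
#' fascicle may exceed its strength -- so demands beyond capacity make the
#' program infeasible (a failed, "unsuccessful" solve).
#'
#' @inheritParams recruit_polynomial
#' @param bounded Enforce the activation ceiling (default TRUE).
#' @return A `recruitment_solution`; `criterion_value` is the top-level
#'   minimax activation.
#' @export
recruit_minmax <- function(prob, bounded = TRUE, cap = prob$N) {
  stopifnot(inherits(prob, "recruitment_problem"))
  C <- prob$C; d <- prob$d; N <- prob$N
  m <- nrow(C); n <- ncol(C)
  if (max(abs(d)) == 0)
    return(recruitment_solution(rep(0, n), N, "ok", 0, C, d))
  tmax_all <- if (bounded) min(cap / N) else Inf

  f <- rep(NA_real_, n)
  free <- rep(TRUE, n)
  d_eff <- d
  tstar1 <- NA_real_
  dscale <- max(abs(d))
  for (level in seq_len(n)) {
    idx <- which(free)
    if (max(abs(d_eff)) <= 1e-9 * dscale) {  # residual demand exhausted
      f[idx] <- 0
      break
    }
    lev <- minmax_level(C[, idx, drop = FALSE], d_eff, N[idx], tmax_all)
    if (lev$status != "ok" || !is.finite(lev$t))
      return(recruitment_solution(rep(NA_real_, n), N,
                                  if (level == 1L && lev$status != "ok") lev$status
                                  else "not_converged",
                                  tstar1, C, d))
    if (level == 1L) tstar1 <- lev$t
    if (lev$t <= 1e-12) {  # remaining demand met with zero force
      f[idx] <- 0
      break
    }
    ub <- lev$t * (1 + 1e-9) * N[idx] + 1e-12
    # fascicles that cannot be below the ceiling are fixed at it
    necessary <- logical(length(idx))
    for (k in seq_along(idx)) {
      mn <- lp_min_component(C[, idx, drop = FALSE], d_eff, ub, k)
      necessary[k] <- is.finite(mn) && mn >= (1 - 1e-7) * lev$t * N[idx[k]]
    }
    if (!any(necessary) || all(necessary)) {
      f[idx] <- lev$f
      break
    }
    fixed_now <- idx[necessary]
    f[fixed_now] <- lev$t * N[fixed_now]
    free[fixed_now] <- FALSE
    d_eff <- drop(d_eff - C[, fixed_now, drop = FALSE] %*% (lev$t * N[fixed_now]))
    if (!any(free)) break
  }
  f[is.na(f)] <- 0
  if (max(abs(C %*% f - d)) > 1e-6 * max(abs(d), 1e-12))
    return(recruitment_solution(f, N, "not_converged", tstar1, C, d))
  recruitment_solution(f, N, "ok", tstar1, C, d)
}
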