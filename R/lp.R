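#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex for problems of the form
#' \deqn{\max\ c^\top x \quad \text{s.t.}\quad A x \;\{=,\le,\ge\}\; b,\quad
#'   l \le x \le u,}
#' the canonical shape of flux balance analysis and its variants. The solver
#' keeps variables at either of their bounds when nonbasic (bounded-variable
#' simplex), uses Bland's rule throughout so degenerate problems cannot cycle,
#' and returns the dual solution: one dual value per constraint row (for a
#' metabolite mass-balance row this is the shadow price) and one reduced cost
#' per variable.
#'
#' Sign convention for duals: `y[i]` is the derivative of the optimal objective
#' with respect to `rhs[i]`, i.e. \eqn{y_i = \partial Z^*/\partial b_i}. For a
#' mass-balance row \eqn{S_i v = 0} a negative dual means that a free external
#' supply of metabolite *i* would raise the objective (the metabolite is
#' limiting).
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m` x `n`), dense or a `Matrix` sparse matrix.
#' @param rhs right-hand sides, length `m`.
#' @param dir character vector of `"="`, `"<="`, `">="` per row (default all
#'   `"="`).
#' @param lb,ub variable bounds, length `n`. Every variable must have at least
#'   one finite bound.
#' @param maximize logical; `FALSE` minimizes.
#' @param tol optimality tolerance on reduced costs.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution, length `n`), `objective`, `y` (row duals, length `m`),
#'   `reduced_costs` (length `n`), `dual_objective` and `iterations`. For
#'   non-optimal statuses the numeric fields are `NA`.
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 4, 0 <= x <= 3
#' lp_solve(c(1, 1), matrix(c(1, 1), 1, 2), 4, "<=", c(0, 0), c(3, 3))$objective
#' @export
lp_solve <- function(obj, A, rhs, dir = rep("=", length(rhs)), lb, ub,
                     maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(lp_result("infeasible", n, m))
  }
  if (any(is.infinite(lb) & is.infinite(ub))) {
    stop("lp_solve requires every variable to have at least one finite bound")
  }
  cvec <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  # slacks turn inequality rows into equalities
  n_slack <- sum(dir != "=")
  Aext <- cbind(A, matrix(0, m, n_slack))
  lbe <- c(lb, numeric(n_slack))
  ube <- c(ub, numeric(n_slack))
  k <- n
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    k <- k + 1
    Aext[i, k] <- 1
    if (dir[i] == "<=") {
      lbe[k] <- 0; ube[k] <- Inf
    } else {
      lbe[k] <- -Inf; ube[k] <- 0
    }
  }
  cvec <- c(cvec, numeric(n_slack))
  res <- simplex_bounded(cvec, Aext, as.numeric(rhs), lbe, ube, tol = tol)
  if (res$status != "optimal") {
    return(lp_result(res$status, n, m, iterations = res$iterations))
  }
  x <- res$x[seq_len(n)]
  y <- res$y
  d <- res$d[seq_len(n)]
  objective <- sum(cvec[seq_len(n)] * x)
  # Lagrangian dual value: b'y + sum_j max_{l<=x<=u} d_j x_j
  dpos <- pmax(res$d, 0); dneg <- pmin(res$d, 0)
  contrib <- dpos * ifelse(is.finite(ube), ube, 0) +
    dneg * ifelse(is.finite(lbe), lbe, 0)
  dual_obj <- sum(res$y * rhs) + sum(contrib)
  if (!maximize) {
    objective <- -objective
    y <- -y
    d <- -d
    dual_obj <- -dual_obj
  }
  list(status = "optimal", x = x, objective = objective, y = y,
       reduced_costs = d, dual_objective = dual_obj,
       iterations = res$iterations)
}

lp_result <- function(status, n, m, iterations = 0L) {
  list(status = status, x = rep(NA_real_, n), objective = NA_real_,
       y = rep(NA_real_, m), reduced_costs = rep(NA_real_, n),
       dual_objective = NA_real_, iterations = iterations)
}

# Bounded-variable two-phase primal simplex on max c'x, Ax = b, l <= x <= u.
# All variables must have at least one finite bound. Bland's rule for both
# entering and leaving variables guarantees finite termination.
simplex_bounded <- function(cvec, A, b, lb, ub, tol = 1e-9,
                            max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)

  # nonbasic start: the finite bound closest to zero
  start_at_lower <- ifelse(is.finite(lb) & is.finite(ub),
                           abs(lb) <= abs(ub), is.finite(lb))
  xval <- ifelse(start_at_lower, lb, ub)

  resid <- b - as.numeric(A %*% xval)
  sgn <- ifelse(resid >= 0, 1, -1)
  # one artificial per row, coefficient chosen so it starts feasible at |resid|
  Aall <- cbind(A, diag(sgn, m, m))
  lball <- c(lb, numeric(m))
  uball <- c(ub, rep(Inf, m))
  xall <- c(xval, abs(resid))
  at_lower <- c(start_at_lower, rep(TRUE, m))
  basis <- n + seq_len(m)

  phase1 <- c(numeric(n), rep(-1, m))
  st <- simplex_run(phase1, Aall, b, lball, uball, xall, at_lower, basis,
                    tol = tol, max_iter = max_iter)
  if (st$status == "iteration_limit") return(list(status = "infeasible",
                                                  iterations = st$iter))
  art <- n + seq_len(m)
  if (sum(st$xall[art]) > 1e-7) {
    return(list(status = "infeasible", iterations = st$iter))
  }
  # artificials are pinned at zero for phase 2 (may stay basic, degenerate)
  uball[art] <- 0
  st$xall[art] <- 0
  phase2 <- c(cvec, numeric(m))
  st2 <- simplex_run(phase2, Aall, b, lball, uball, st$xall, st$at_lower,
                     st$basis, tol = tol, max_iter = max_iter)
  if (st2$status != "optimal") {
    return(list(status = if (st2$status == "unbounded") "unbounded"
                else "infeasible",
                iterations = st$iter + st2$iter))
  }
  list(status = "optimal", x = st2$xall[seq_len(n)], y = st2$y,
       d = st2$d[seq_len(n)], iterations = st$iter + st2$iter)
}

simplex_run <- function(cvec, A, b, lb, ub, xall, at_lower, basis,
                        tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A)
  nall <- ncol(A)
  fixed <- (ub - lb) <= 1e-14
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "iteration_limit", iter = iter))
    }
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) {
      stop("simplex basis became singular; LP is numerically degenerate")
    }
    nb <- setdiff(seq_len(nall), basis)
    rhs_nb <- b - as.numeric(A[, nb, drop = FALSE] %*% xall[nb])
    xall[basis] <- as.numeric(Binv %*% rhs_nb)
    y <- as.numeric(crossprod(Binv, cvec[basis]))
    d <- cvec - as.numeric(crossprod(A, y))
    d[basis] <- 0

    elig <- logical(nall)
    elig[nb] <- (at_lower[nb] & d[nb] > tol) | (!at_lower[nb] & d[nb] < -tol)
    elig[fixed] <- FALSE
    if (!any(elig)) {
      return(list(status = "optimal", xall = xall, at_lower = at_lower,
                  basis = basis, y = y, d = d, iter = iter))
    }
    j <- which(elig)[1L]                       # Bland: smallest index
    s <- if (at_lower[j]) 1 else -1            # direction of change of x_j
    w <- as.numeric(Binv %*% A[, j])
    sw <- s * w

    lim <- rep(Inf, m)
    dec <- sw > 1e-10                          # basic value decreasing
    inc <- sw < -1e-10                         # basic value increasing
    lim[dec] <- (xall[basis[dec]] - lb[basis[dec]]) / sw[dec]
    lim[inc] <- (ub[basis[inc]] - xall[basis[inc]]) / (-sw[inc])
    lim[lim < 0] <- 0                          # numerical guard
    range_j <- ub[j] - lb[j]
    delta <- min(lim, range_j)
    if (!is.finite(delta)) {
      return(list(status = "unbounded", iter = iter))
    }
    if (range_j <= delta + 1e-12 && range_j <= min(lim)) {
      # bound flip: j runs to its opposite bound, basis unchanged
      xall[j] <- if (at_lower[j]) ub[j] else lb[j]
      at_lower[j] <- !at_lower[j]
      xall[basis] <- xall[basis] - delta * sw
    } else {
      cand <- which(abs(lim - delta) <= 1e-12)
      if (length(cand) == 0L) cand <- which.min(lim)
      p <- cand[which.min(basis[cand])]        # Bland tie-break on leaving
      leave <- basis[p]
      xall[j] <- xall[j] + s * delta
      xall[basis] <- xall[basis] - delta * sw
      if (sw[p] > 0) {                         # leaving variable hit lower
        xall[leave] <- lb[leave]; at_lower[leave] <- TRUE
      } else {
        xall[leave] <- ub[leave]; at_lower[leave] <- FALSE
      }
      basis[p] <- j
    }
  }
}
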