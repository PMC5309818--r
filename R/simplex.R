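# Bounded-variable primal simplex.
#
# Solves   min c'x   s.t.  A x = b,  l <= x <= u   (all bounds finite)
# with a two-phase method: phase 1 drives artificial variables out of the
# basis, phase 2 optimizes the true objective. Nonbasic variables sit at a
# finite bound; the ratio test handles bound flips. Bland's rule
# (smallest-index entering and leaving) guarantees termination on
# degenerate problems, which steady-state flux cones produce routinely.
# The basis system is re-solved densely each iteration; problem sizes in
# this package are tens of columns, where refactorization is both cheap
# and numerically safest.

simplex_bounded <- function(A, b, obj, lb, ub, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  if (is.null(max_iter)) max_iter <- 200L * (n + m + 10L)

  # start structural variables nonbasic at the bound of smaller magnitude
  start_at_lower <- abs(lb) <= abs(ub)
  x0 <- ifelse(start_at_lower, lb, ub)
  r <- as.numeric(b - A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(art_sign, m, m))
  N <- n + m
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, abs(r) + 1)          # loose caps; artificials start inside
  status <- c(ifelse(start_at_lower, "L", "U"), rep("B", m))
  basis <- (n + 1L):N

  value_of <- function(j) if (status[j] == "L") lbe[j] else ube[j]

  run_phase <- function(cost) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return("maxiter")
      nonbasic <- which(status != "B")
      xN <- vapply(nonbasic, value_of, 0)
      B <- Aext[, basis, drop = FALSE]
      rhs <- b - Aext[, nonbasic, drop = FALSE] %*% xN
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) return("singular")
      xB <- as.numeric(xB)
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return("singular")
      d <- cost[nonbasic] - as.numeric(t(Aext[, nonbasic, drop = FALSE]) %*% y)
      movable <- ube[nonbasic] > lbe[nonbasic]   # fixed variables cannot move
      improving <- movable & ((status[nonbasic] == "L" & d < -tol) |
                                (status[nonbasic] == "U" & d > tol))
      if (!any(improving)) {
        return(list(xB = xB, nonbasic = nonbasic, xN = xN))
      }
      # Bland: smallest variable index among improving candidates
      q_pos <- nonbasic[improving][which.min(nonbasic[improving])]
      qi <- match(q_pos, nonbasic)
      dirn <- if (status[q_pos] == "L") 1 else -1  # movement of x_q
      alpha <- as.numeric(solve(B, Aext[, q_pos]))  # xB changes by -alpha*t*dirn
      # ratio test: basic variables hitting a bound, or q flipping bounds
      t_best <- ube[q_pos] - lbe[q_pos]
      leave <- 0L  # 0 means bound flip
      for (k in seq_len(m)) {
        chg <- -alpha[k] * dirn
        if (chg < -tol) {
          tk <- (lbe[basis[k]] - xB[k]) / chg
        } else if (chg > tol) {
          tk <- (ube[basis[k]] - xB[k]) / chg
        } else next
        if (tk < -1e-11) tk <- 0
        if (tk < t_best - 1e-12 ||
            (tk < t_best + 1e-12 && leave > 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k
        }
      }
      if (!is.finite(t_best)) return("unbounded")
      if (leave == 0L) {
        # bound flip: q moves to its opposite bound, basis unchanged
        status[q_pos] <<- if (status[q_pos] == "L") "U" else "L"
      } else {
        new_val <- xB[leave] - alpha[leave] * dirn * t_best
        p <- basis[leave]
        status[p] <<- if (abs(new_val - lbe[p]) < abs(new_val - ube[p])) "L" else "U"
        status[q_pos] <<- "B"
        basis[leave] <<- q_pos
      }
    }
  }

  extract <- function(sol) {
    x <- numeric(N)
    x[sol$nonbasic] <- sol$xN
    x[basis] <- sol$xB
    x
  }

  # phase 1: minimize the artificial mass
  p1 <- run_phase(c(rep(0, n), rep(1, m)))
  if (is.character(p1)) return(list(status = p1))
  x <- extract(p1)
  if (sum(x[(n + 1L):N]) > 1e-7) return(list(status = "infeasible"))

  # pin artificials and optimize the real objective
  ube[(n + 1L):N] <- 0
  p2 <- run_phase(c(obj, rep(0, m)))
  if (is.character(p2)) return(list(status = p2))
  x <- extract(p2)[1:n]
  list(status = "optimal", x = x, objective = sum(obj * x))
}
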