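# Dense two-phase simplex for small bounded linear programs.
# Solves: maximize c'v  subject to  A v = b,  lb <= v <= ub  (finite bounds).
# Bland's rule throughout, so it cannot cycle; problem sizes here are a few
# dozen variables (toy metabolic models), where a dense tableau is plenty.

LP_TOL <- 1e-9

#' Solve a small bounded linear program
#'
#' @param obj objective coefficients (length n), maximized.
#' @param A constraint matrix (m x n) of equalities `A v = b`.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds, `lb <= ub`.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and the solution `x` (length n, `NA` unless optimal).
#' @keywords internal
#' @export
solve_lp <- function(obj, A, b, lb, ub) {
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + LP_TOL)) stop("lower bound exceeds upper bound")

  # shift to x = v - lb in [0, u]; add slack rows x_i + s_i = u_i
  u <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  nx <- n; ns <- n
  Arows <- rbind(cbind(A, matrix(0, m, ns)),
                 cbind(diag(nx), diag(ns)))
  rhs <- c(b2, u)
  flip <- rhs < 0
  Arows[flip, ] <- -Arows[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  nrow_t <- m + n

  # artificials only for the first m rows; slacks start basic for the u rows
  # (u rows were never flipped since u >= 0)
  na <- m
  Tab <- cbind(Arows, rbind(diag(na), matrix(0, n, na)), rhs)
  basis <- c(nx + ns + seq_len(na), nx + seq_len(ns))
  art_cols <- nx + ns + seq_len(na)
  ncols <- nx + ns + na

  pivot <- function(Tab, r, cidx) {
    Tab[r, ] <- Tab[r, ] / Tab[r, cidx]
    for (i in seq_len(nrow(Tab))) {
      if (i != r && abs(Tab[i, cidx]) > 0) {
        Tab[i, ] <- Tab[i, ] - Tab[i, cidx] * Tab[r, ]
      }
    }
    Tab
  }

  run_phase <- function(Tab, basis, cost, allowed) {
    # maximize cost'x; returns list(Tab, basis, status)
    repeat {
      cb <- cost[basis]
      red <- as.vector(cb %*% Tab[, seq_len(ncols), drop = FALSE]) - cost
      ent <- which(allowed & red < -LP_TOL)
      if (!length(ent)) return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(ent)  # Bland
      col <- Tab[, j]
      pos <- which(col > LP_TOL)
      if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[pos, ncols + 1] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + LP_TOL]
      r <- cand[which.min(basis[cand])]  # Bland tie-break
      Tab <- pivot(Tab, r, j)
      basis[r] <- j
    }
  }

  # phase 1: maximize -(sum of artificials)
  cost1 <- c(rep(0, nx + ns), rep(-1, na))
  allowed1 <- rep(TRUE, ncols)
  ph1 <- run_phase(Tab, basis, cost1, allowed1)
  Tab <- ph1$Tab; basis <- ph1$basis
  obj1 <- sum(cost1[basis] * Tab[, ncols + 1])
  if (obj1 < -1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))

  # drive any degenerate basic artificials out of the basis
  for (i in seq_len(nrow_t)) {
    if (basis[i] %in% art_cols) {
      j <- which(abs(Tab[i, seq_len(nx + ns)]) > LP_TOL)
      if (length(j)) {
        Tab <- pivot(Tab, i, j[1])
        basis[i] <- j[1]
      }
      # else: redundant all-zero row; artificial stays basic at 0, harmless
    }
  }

  # phase 2
  cost2 <- c(obj, rep(0, ns), rep(0, na))
  allowed2 <- c(rep(TRUE, nx + ns), rep(FALSE, na))
  ph2 <- run_phase(Tab, basis, cost2, allowed2)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", objective = Inf, x = rep(NA_real_, n)))
  Tab <- ph2$Tab; basis <- ph2$basis

  xfull <- numeric(ncols)
  xfull[basis] <- Tab[, ncols + 1]
  v <- xfull[seq_len(nx)] + lb
  list(status = "optimal", objective = sum(obj * v), x = v)
}
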