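# Dense bounded-variable two-phase primal simplex. Problems here are
# desk-scale (tens of variables), so the basis inverse is recomputed each
# iteration and Bland's rule guards against cycling; the solver is fully
# deterministic, which the flux contracts rely on.

# Maximize c'x subject to A x = b, 0 <= x <= w (w may be Inf).
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
simplex_core <- function(A, b, c, w, tol = 1e-8, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  # flip rows so b >= 0, then append artificial columns
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  A_full <- cbind(A, diag(m))
  w_full <- c(w, rep(Inf, m))
  art <- n + seq_len(m)
  basis <- art
  x <- c(rep(0, n), b)           # nonbasic structurals at lower bound 0
  at_upper <- rep(FALSE, n + m)  # nonbasic bound status

  run_phase <- function(cost, allow_enter) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return("iteration limit")
      B_inv <- tryCatch(solve(A_full[, basis, drop = FALSE]),
                        error = function(e) NULL)
      if (is.null(B_inv)) return("singular basis")
      y <- drop(crossprod(B_inv, cost[basis]))
      nonbasic <- setdiff(which(allow_enter), basis)
      if (length(nonbasic) == 0) return("optimal")
      d <- cost[nonbasic] - drop(y %*% A_full[, nonbasic, drop = FALSE])
      enter_ok <- (!at_upper[nonbasic] & d > tol) |
                  (at_upper[nonbasic] & d < -tol)
      if (!any(enter_ok)) return("optimal")
      j <- nonbasic[enter_ok][1]         # Bland: smallest index
      from_upper <- at_upper[j]
      dir <- drop(B_inv %*% A_full[, j])
      if (from_upper) dir <- -dir
      # ratio test: entering increases by t (decreases from upper bound)
      row_t <- rep(Inf, m)
      row_up <- rep(FALSE, m)
      for (i in seq_len(m)) {
        if (dir[i] > tol) {
          row_t[i] <- max(x[basis[i]], 0) / dir[i]
        } else if (dir[i] < -tol && is.finite(w_full[basis[i]])) {
          row_t[i] <- max(w_full[basis[i]] - x[basis[i]], 0) / (-dir[i])
          row_up[i] <- TRUE
        }
      }
      t_row <- suppressWarnings(min(row_t))
      if (!is.finite(min(t_row, w_full[j]))) return("unbounded")
      leave <- 0L; leave_to_upper <- FALSE
      if (t_row <= w_full[j] + tol) {
        tied <- which(row_t <= t_row + tol)
        leave <- tied[which.min(basis[tied])]   # Bland: smallest variable index
        leave_to_upper <- row_up[leave]
        t_limit <- max(row_t[leave], 0)
      } else {
        t_limit <- w_full[j]                     # bound flip, basis unchanged
      }
      x[basis] <<- x[basis] - dir * t_limit
      x[j] <<- if (from_upper) w_full[j] - t_limit else t_limit
      if (leave == 0L) {
        at_upper[j] <<- !from_upper   # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        x[out] <<- if (leave_to_upper) w_full[out] else 0
        at_upper[out] <<- leave_to_upper
        basis[leave] <<- j
        at_upper[j] <<- FALSE
      }
    }
  }

  # Phase I: drive artificials to zero
  if (sum(b) > 0) {
    cost1 <- c(rep(0, n), rep(-1, m))
    st <- run_phase(cost1, allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
    if (st != "optimal") return(list(status = "infeasible"))
    if (sum(x[art]) > 1e-6) return(list(status = "infeasible"))
  }
  w_full[art] <- 0
  x[art] <- 0
  cost2 <- c(c, rep(0, m))
  st <- run_phase(cost2, allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
  if (st == "unbounded") return(list(status = "unbounded"))
  if (st != "optimal") return(list(status = "infeasible"))
  list(status = "optimal", x = x[seq_len(n)], value = sum(c * x[seq_len(n)]))
}

# Maximize objective'v subject to S v = 0, lb <= v <= ub, plus optional
# extra rows ge_mat v >= ge_rhs. Returns list(value, solution) or NULL when
# infeasible/unbounded.
solve_flux_lp <- function(S, lb, ub, objective, ge_mat = NULL, ge_rhs = NULL,
                          tol = 1e-8) {
  n <- length(lb)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  A <- S
  b <- as.numeric(-S %*% lb)
  cvec <- objective
  w <- ub - lb
  if (!is.null(ge_mat)) {
    ge_mat <- matrix(ge_mat, ncol = n)
    # g'v >= r  ->  g'x - s = r - g'l, slack s in [0, Inf)
    k <- nrow(ge_mat)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(ge_mat, -diag(k)))
    b <- c(b, ge_rhs - as.numeric(ge_mat %*% lb))
    cvec <- c(cvec, rep(0, k))
    w <- c(w, rep(Inf, k))
  }
  res <- simplex_core(A, b, cvec, w, tol = tol)
  if (res$status != "optimal") return(NULL)
  v <- res$x[seq_len(n)] + lb
  list(value = sum(objective * v), solution = v)
}
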