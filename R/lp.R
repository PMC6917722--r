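# Dense bounded-variable two-phase primal simplex with Bland's rule.
# Solves max/min obj'x subject to A x = b, lb <= x <= ub. Entirely
# deterministic: entering variable is the smallest eligible index, leaving
# variable the smallest basic index among the tightest ratios, so repeated
# runs give identical vertices. Intended for the desk-scale problems this
# package works with (hundreds of variables); not a genome-scale solver.
.lpSolveDense <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                          tol = 1e-9, max_iter = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  if (m == 0L) {
    # pure box problem
    cc <- if (sense == "max") obj else -obj
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, ifelse(is.finite(lb), lb, 0)))
    if (any(!is.finite(x[cc != 0])))
      return(list(status = "unbounded", x = NULL, objval = NA_real_))
    return(list(status = "optimal", x = x, objval = sum(obj * x)))
  }
  cc <- if (sense == "max") as.numeric(obj) else -as.numeric(obj)
  if (is.null(max_iter)) max_iter <- 500L * (n + m + 10L)

  # nonbasic start values: finite bound nearest zero; free variables at 0
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    lj <- lb[j]; uj <- ub[j]
    x0[j] <- if (is.finite(lj) && is.finite(uj)) {
      if (abs(lj) <= abs(uj)) lj else uj
    } else if (is.finite(lj)) lj else if (is.finite(uj)) uj else 0
  }
  r <- b - as.vector(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  Ae <- cbind(A, diag(sg, m, m))
  N <- n + m
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  basis <- (n + 1L):N
  # nonbasic status codes: 1 at lower bound, 2 at upper bound, 3 free (at 0)
  stat <- integer(N)
  for (j in seq_len(N)) {
    stat[j] <- if (is.finite(lbe[j]) && x[j] <= lbe[j]) 1L
      else if (is.finite(ube[j]) && x[j] >= ube[j]) 2L else 3L
  }

  run_phase <- function(cvec, x, basis, stat, allow) {
    in_basis <- logical(N); in_basis[basis] <- TRUE
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "maxiter"))
      B <- Ae[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      y <- as.vector(crossprod(Binv, cvec[basis]))
      enter <- 0L; dir <- 0
      for (j in seq_len(N)) {
        if (in_basis[j] || !allow[j]) next
        dj <- cvec[j] - sum(y * Ae[, j])
        if (stat[j] == 1L && dj > tol) { enter <- j; dir <- 1; break }
        if (stat[j] == 2L && dj < -tol) { enter <- j; dir <- -1; break }
        if (stat[j] == 3L && abs(dj) > tol) { enter <- j; dir <- sign(dj); break }
      }
      if (enter == 0L)
        return(list(status = "optimal", x = x, basis = basis, stat = stat))
      w <- as.vector(Binv %*% Ae[, enter])      # x_B(t) = x_B - t*dir*w
      tmax <- if (is.finite(lbe[enter]) && is.finite(ube[enter]))
        ube[enter] - lbe[enter] else Inf
      tk <- rep(Inf, m)
      for (k in seq_len(m)) {
        g <- dir * w[k]; bk <- basis[k]
        if (g > tol && is.finite(lbe[bk])) tk[k] <- (x[bk] - lbe[bk]) / g
        else if (g < -tol && is.finite(ube[bk])) tk[k] <- (x[bk] - ube[bk]) / g
      }
      tk[tk < 0] <- 0
      tstar <- min(tmax, tk)
      if (!is.finite(tstar)) return(list(status = "unbounded"))
      cand <- which(tk <= tstar + tol)
      leave <- if (length(cand)) cand[which.min(basis[cand])] else 0L
      x[basis] <- x[basis] - tstar * dir * w
      x[enter] <- x[enter] + tstar * dir
      if (leave == 0L) {
        stat[enter] <- if (dir > 0) 2L else 1L
        x[enter] <- if (dir > 0) ube[enter] else lbe[enter]
      } else {
        lv <- basis[leave]
        g <- dir * w[leave]
        stat[lv] <- if (g > 0) 1L else 2L
        x[lv] <- if (g > 0) lbe[lv] else ube[lv]
        basis[leave] <- enter
        in_basis[lv] <- FALSE; in_basis[enter] <- TRUE
        stat[enter] <- 0L
      }
    }
  }

  p1 <- run_phase(c(rep(0, n), rep(-1, m)), x, basis, stat, rep(TRUE, N))
  if (p1$status %in% c("maxiter", "singular"))
    stop("LP solver failure in phase 1 (", p1$status, "); m=", m, " n=", n)
  if (sum(p1$x[(n + 1L):N]) > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  x <- p1$x; basis <- p1$basis; stat <- p1$stat
  ube[(n + 1L):N] <- 0                 # pin artificials; they may stay basic at 0
  x[(n + 1L):N] <- 0
  stat[setdiff((n + 1L):N, basis)] <- 1L
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  p2 <- run_phase(c(cc, rep(0, m)), x, basis, stat, allow2)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  if (p2$status != "optimal")
    stop("LP solver failure in phase 2 (", p2$status, "); m=", m, " n=", n)
  xv <- p2$x[seq_len(n)]
  list(status = "optimal", x = xv, objval = sum(obj * xv))
}
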