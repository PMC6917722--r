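# Brute-force LP oracle: enumerate the basic feasible solutions (vertices)
# of {v : S v = 0, lb <= v <= ub} by fixing n - rank(S) variables at a
# bound and solving for the rest. Independent of the package's simplex;
# only usable for small models (<= ~15 reactions).
vertexOracleLP <- function(obj, A, lb, ub, sense = "max", tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  best <- NULL; bestx <- NULL
  better <- function(a, b) if (sense == "max") a > b else a < b
  subsets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (J in subsets) {
    free <- setdiff(seq_len(n), J)
    AF <- A[, free, drop = FALSE]
    qrAF <- qr(AF)
    if (qrAF$rank < r) next
    # all 2^k lower/upper patterns at once: columns of VJ are bound choices
    if (k > 0) {
      pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
      VJ <- matrix(ifelse(t(pat), ub[J], lb[J]), nrow = k)
      RHS <- -A[, J, drop = FALSE] %*% VJ
    } else {
      VJ <- matrix(0, 0, 1); RHS <- matrix(0, nrow(A), 1)
    }
    sol <- qr.coef(qrAF, RHS)
    sol[is.na(sol)] <- 0
    resid <- AF %*% sol - RHS
    for (p in seq_len(ncol(RHS))) {
      if (max(abs(resid[, p])) > tol) next
      v <- numeric(n)
      if (k > 0) v[J] <- VJ[, p]
      v[free] <- sol[, p]
      if (any(v < lb - tol) || any(v > ub + tol)) next
      val <- sum(obj * v)
      if (is.null(best) || better(val, best)) { best <- val; bestx <- v }
    }
  }
  list(objval = best, x = bestx)
}

vertexOracleModel <- function(model, objective = NULL, sense = "max") {
  obj <- objectiveCoefficients(model)
  if (!is.null(objective)) {
    if (is.character(objective)) {
      obj <- stats::setNames(rep(1, length(objective)), objective)
    } else obj <- objective
  }
  rx <- reactions(model)
  cc <- numeric(nrow(rx))
  cc[match(names(obj), rx$id)] <- unname(obj)
  res <- vertexOracleLP(cc, as.matrix(stoichiometricMatrix(model)),
                        rx$lower_bound, rx$upper_bound, sense)
  if (!is.null(res$x)) names(res$x) <- rx$id
  res
}

# steady-state and bound satisfaction check for an optimal solution
expectSteadyState <- function(model, sol, tol = 1e-6) {
  expect_identical(solverStatus(sol), "optimal")
  v <- fluxes(sol)[reactions(model)$id]
  resid <- as.numeric(stoichiometricMatrix(model) %*% v)
  expect_lt(max(abs(resid)), length(v) * tol)
  rx <- reactions(model)
  expect_true(all(v >= rx$lower_bound - tol))
  expect_true(all(v <= rx$upper_bound + tol))
}

# Independent LP cross-check through scipy's HiGHS backend (python is part
# of the toolchain this package is developed against). Used where the
# co-model is too large for vertex enumeration.
scipyOracle <- function(model, objective = NULL, sense = "max") {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("python not on PATH")
  obj <- objectiveCoefficients(model)
  if (is.character(objective))
    obj <- stats::setNames(rep(1, length(objective)), objective)
  rx <- reactions(model)
  cc <- numeric(nrow(rx)); cc[match(names(obj), rx$id)] <- unname(obj)
  payload <- list(c = cc,
                  S = as.matrix(stoichiometricMatrix(model)),
                  lb = rx$lower_bound, ub = rx$upper_bound,
                  sense = sense)
  fin <- tempfile(fileext = ".json"); fout <- tempfile()
  jsonlite::write_json(payload, fin, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, numpy as np",
    "from scipy.optimize import linprog",
    sprintf("p = json.load(open('%s'))", fin),
    "c = np.asarray(p['c'], float)",
    "S = np.asarray(p['S'], float)",
    "sgn = -1.0 if p['sense'] == 'max' else 1.0",
    "bounds = list(zip(p['lb'], p['ub']))",
    "r = linprog(sgn * c, A_eq=S, b_eq=np.zeros(S.shape[0]),",
    "            bounds=bounds, method='highs')",
    sprintf("open('%s', 'w').write('%%r %%.12f' %% (r.status, sgn * r.fun if r.success else float('nan')))", fout)),
    script)
  res <- system2(py, script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("scipy oracle failed: ", paste(res, collapse = "\n"))
  parts <- strsplit(readLines(fout, warn = FALSE), " ")[[1]]
  unlink(c(fin, fout, script))
  list(status = parts[1], objval = as.numeric(parts[2]))
}
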